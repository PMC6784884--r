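# Homoeologue expression dominance and dosage compensation.
#
# Dominance between the two copies of a homoeologue pair is tested per
# sample with an exact conditional binomial test on replicate-summed
# counts: given n = countA + countB, countB ~ Binomial(n, p0) under the
# null of a shared rate, where p0 is set by the normalisation offsets
# (library size x gene length). Q-values are Benjamini-Hochberg over the
# full pair x sample family; a sample supports B-dominance when the RPKM
# fold change B/A meets the threshold and q is below the FDR cut-off.

#' Reads per kilobase of transcript per million mapped reads
#'
#' @param count read count.
#' @param gene_length gene length in bp.
#' @param library_size total mapped reads in the library.
#' @return RPKM = 1e9 * count / (gene_length * library_size).
#' @examples
#' rpkm(1000, 1000, 1e6)  # 1000
#' @export
rpkm <- function(count, gene_length, library_size) {
  if (any(gene_length <= 0)) stop("gene_length must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  1e9 * count / (gene_length * library_size)
}

#' Exact conditional binomial test for paired homoeologue counts
#'
#' Two-sided exact p-value that two counts share a common rate after
#' offset adjustment: conditional on n = countA + countB, countB is
#' Binomial(n, offsetB / (offsetA + offsetB)) under the null. The
#' two-sided p-value sums the probabilities of all outcomes no more likely
#' than the observed one (minimum-likelihood method). Both counts zero
#' gives p = 1 (nothing expressed, nothing to test).
#'
#' @param countA,countB non-negative integer counts (replicates summed).
#' @param offsetA,offsetB positive normalisation offsets (library size x
#'   gene length products for each side).
#' @return p-value in (0, 1].
#' @export
pair_test <- function(countA, countB, offsetA = 1, offsetB = 1) {
  if (length(countA) > 1L)
    return(mapply(pair_test, countA, countB, offsetA, offsetB))
  if (countA < 0 || countB < 0) stop("counts must be non-negative")
  if (offsetA <= 0 || offsetB <= 0) stop("offsets must be positive")
  n <- countA + countB
  if (n == 0) return(1)
  p0 <- offsetB / (offsetA + offsetB)
  probs <- dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= probs[countB + 1] * (1 + 1e-9)]))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment; a thin wrapper around
#' [stats::p.adjust()] kept as the package's single adjustment surface.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

# per-(pair, sample) statistics: replicate-summed counts, offsets
# (including the copy-number expectation), per-copy RPKM on each side,
# exact p-value
pair_sample_stats <- function(expr, copies = c(A = 1, B = 1), eps = 0.01) {
  stopifnot(all(c("pair_id", "sample", "replicate", "countA", "countB",
                  "lib_size", "lenA", "lenB") %in% names(expr)))
  key <- paste(expr$pair_id, expr$sample, sep = "\r")
  rows <- lapply(split(expr, key), function(e) {
    cA <- sum(e$countA); cB <- sum(e$countB)
    offA <- sum(e$lib_size * e$lenA) * copies[["A"]]
    offB <- sum(e$lib_size * e$lenB) * copies[["B"]]
    data.frame(pair_id = e$pair_id[1], sample = e$sample[1],
               countA = cA, countB = cB,
               rpkmA = mean(rpkm(e$countA, e$lenA, e$lib_size)),
               rpkmB = mean(rpkm(e$countB, e$lenB, e$lib_size)),
               p_value = pair_test(cA, cB, offA, offB),
               unexpressed = cA + cB == 0)
  })
  out <- do.call(rbind, rows)
  out$fc_b <- (out$rpkmB / copies[["B"]] + eps) /
    (out$rpkmA / copies[["A"]] + eps)
  rownames(out) <- NULL
  out
}

#' Classify homoeologue expression dominance
#'
#' Dominance is expression bias beyond what the genomic copy numbers
#' already explain, so both the fold change and the exact test are
#' computed on the per-copy scale: in an ABB accession a pair whose B
#' output is simply twice its A output (two B copies, one A copy) is not
#' dominant. A sample supports B-dominance when the per-copy fold change
#' (RPKM_B/nB) / (RPKM_A/nA) >= `fc_threshold` and the BH q-value
#' (computed over the whole pair x sample family) is at most
#' `fdr_threshold`; A-dominance is the mirror image. A pair is classified
#' dominant when at least `min_supporting` samples support one direction
#' and none support the other; pairs with support in both directions are
#' non_dominant and flagged mixed.
#'
#' @param expr long expression data.frame (see [simulate_expression()]).
#' @param constitution nominal constitution string setting the copy-number
#'   expectation; the default "AB" applies no copy adjustment.
#' @param fc_threshold fold-change threshold (per-copy RPKM scale,
#'   default 2).
#' @param fdr_threshold FDR threshold on BH q-values (default 0.001).
#' @param min_supporting minimum supporting samples (default 1).
#' @param eps RPKM pseudo-count used in fold changes.
#' @return data.frame, one row per pair: pair_id, class (A_dominant /
#'   B_dominant / non_dominant), n_support_A, n_support_B, min_q, mixed.
#'   The per-sample table (with p- and q-values) is attached as attribute
#'   `"per_sample"`.
#' @export
call_dominance <- function(expr, constitution = "AB", fc_threshold = 2,
                           fdr_threshold = 0.001, min_supporting = 1L,
                           eps = 0.01) {
  copies <- parse_constitution(constitution)
  if (copies[["A"]] == 0 || copies[["B"]] == 0)
    stop("dominance needs both subgenomes present in the constitution")
  ps <- pair_sample_stats(expr, copies = copies, eps = eps)
  ps$q_value <- adjust_fdr(ps$p_value)
  ps$support_B <- ps$fc_b >= fc_threshold & ps$q_value <= fdr_threshold
  ps$support_A <- (1 / ps$fc_b) >= fc_threshold &
    ps$q_value <= fdr_threshold
  calls <- do.call(rbind, lapply(split(ps, ps$pair_id), function(d) {
    nA <- sum(d$support_A); nB <- sum(d$support_B)
    class <- if (nA >= min_supporting && nB == 0L) "A_dominant"
      else if (nB >= min_supporting && nA == 0L) "B_dominant"
      else "non_dominant"
    data.frame(pair_id = d$pair_id[1], class = class,
               n_support_A = nA, n_support_B = nB,
               min_q = min(d$q_value), mixed = nA > 0L && nB > 0L)
  }))
  rownames(calls) <- NULL
  attr(calls, "per_sample") <- ps
  calls
}

#' Dosage-compensation summary against the genomic copy-number expectation
#'
#' Summarises the per-pair log2 RPKM ratio of the B to the A homoeologue
#' (RPKM averaged over samples and replicates, pseudo-count `eps` added to
#' both sides) over pairs expressed above `min_expr`, and compares the
#' median with the expectation log2(nB/nA) from the genomic constitution.
#' A compensation index below 1 means the observed ratio has shrunk
#' towards the diploid (1:1) state.
#'
#' @param expr long expression data.frame.
#' @param constitution nominal constitution string, e.g. "ABB".
#' @param min_expr minimum summed mean RPKM (A + B) for a pair to count as
#'   expressed.
#' @param eps RPKM pseudo-count.
#' @return list of class `dosage_summary`: n_pairs, median_log2,
#'   mean_log2, median_ratio, expected_log2, expected_ratio,
#'   compensation_index (median_log2 / expected_log2).
#' @export
dosage_summary <- function(expr, constitution, min_expr = 1, eps = 0.01) {
  nom <- parse_constitution(constitution)
  if (nom[["A"]] == 0 || nom[["B"]] == 0)
    stop("dosage summary needs both subgenomes present")
  per_pair <- do.call(rbind, lapply(split(expr, expr$pair_id),
                                    function(e) {
    data.frame(pair_id = e$pair_id[1],
               rpkmA = mean(rpkm(e$countA, e$lenA, e$lib_size)),
               rpkmB = mean(rpkm(e$countB, e$lenB, e$lib_size)))
  }))
  per_pair <- per_pair[per_pair$rpkmA + per_pair$rpkmB > min_expr, ]
  if (nrow(per_pair) == 0L) stop("no expressed pairs")
  lr <- log2((per_pair$rpkmB + eps) / (per_pair$rpkmA + eps))
  expected <- log2(nom[["B"]] / nom[["A"]])
  structure(list(n_pairs = nrow(per_pair),
                 median_log2 = median(lr), mean_log2 = mean(lr),
                 median_ratio = median((per_pair$rpkmB + eps) /
                                         (per_pair$rpkmA + eps)),
                 expected_log2 = expected,
                 expected_ratio = nom[["B"]] / nom[["A"]],
                 compensation_index = if (expected != 0)
                   median(lr) / expected else NA_real_),
            class = "dosage_summary")
}

#' @export
print.dosage_summary <- function(x, ...) {
  cat(sprintf(
    "Dosage summary over %d expressed pairs\n", x$n_pairs))
  cat(sprintf("  median log2(B/A) = %.3f (expected %.3f from genomic %s)\n",
              x$median_log2, x$expected_log2,
              sprintf("%g/1", x$expected_ratio)))
  cat(sprintf("  compensation index = %.3f\n", x$compensation_index))
  invisible(x)
}
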