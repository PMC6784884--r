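# Nei-Gojobori (1986) site/difference counting, Jukes-Cantor correction,
# and the fourfold-degenerate transversion rate (4dTv).
#
# The standard genetic code only; stop codons and ambiguity codes are
# rejected at validation time. Pairwise codon difference counts are
# averaged over all minimal substitution pathways with equal weights,
# excluding pathways that pass through a stop codon (the NG86 convention).

# package-local cache for codon tables and the 61x61 pathway matrix
.polysub_cache <- new.env(parent = emptyenv())

genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

sense_codons <- function() {
  gc <- genetic_code()
  names(gc)[gc != "*"]
}

translate_codon <- function(codon) {
  genetic_code()[[codon]]
}

is_stop <- function(codon) {
  genetic_code()[[codon]] == "*"
}

# all single-nucleotide sense neighbours of a codon, split by effect
codon_neighbours <- function() {
  if (!is.null(.polysub_cache$neighbours)) return(.polysub_cache$neighbours)
  gc <- genetic_code()
  nts <- c("A", "C", "G", "T")
  out <- lapply(sense_codons(), function(codon) {
    aa <- gc[[codon]]
    syn <- list(); nonsyn <- list()
    for (pos in 1:3) {
      for (nt in setdiff(nts, substr(codon, pos, pos))) {
        mut <- codon
        substr(mut, pos, pos) <- nt
        if (gc[[mut]] == "*") next
        row <- data.frame(codon = mut, position = pos)
        if (gc[[mut]] == aa) syn[[length(syn) + 1]] <- row
        else nonsyn[[length(nonsyn) + 1]] <- row
      }
    }
    empty <- data.frame(codon = character(), position = integer())
    list(syn = if (length(syn)) do.call(rbind, syn) else empty,
         nonsyn = if (length(nonsyn)) do.call(rbind, nonsyn) else empty)
  })
  names(out) <- sense_codons()
  .polysub_cache$neighbours <- out
  out
}

#' Synonymous and non-synonymous site counts of a codon (NG86)
#'
#' The synonymous site count of a codon is the sum over its three positions
#' of the fraction of possible single-nucleotide changes at that position
#' that are synonymous, with changes to stop codons excluded from the
#' denominator. Non-synonymous sites are 3 minus the synonymous count.
#'
#' @param codon a sense codon string, e.g. `"TTT"`.
#' @return Named numeric vector `c(syn = , nonsyn = )`, summing to 3.
#' @examples
#' ng86_sites("TTT")  # syn = 1/3
#' ng86_sites("TGG")  # syn = 0
#' @export
ng86_sites <- function(codon) {
  gc <- genetic_code()
  if (!codon %in% names(gc)) stop("invalid codon: ", codon)
  if (gc[[codon]] == "*") stop("stop codon has no NG86 sites: ", codon)
  if (is.null(.polysub_cache$sites)) {
    nts <- c("A", "C", "G", "T")
    tab <- vapply(sense_codons(), function(cd) {
      aa <- gc[[cd]]
      s <- 0
      for (pos in 1:3) {
        n_syn <- 0L; n_valid <- 0L
        for (nt in setdiff(nts, substr(cd, pos, pos))) {
          mut <- cd
          substr(mut, pos, pos) <- nt
          if (gc[[mut]] == "*") next
          n_valid <- n_valid + 1L
          if (gc[[mut]] == aa) n_syn <- n_syn + 1L
        }
        if (n_valid > 0L) s <- s + n_syn / n_valid
      }
      s
    }, 0)
    .polysub_cache$sites <- tab
  }
  s <- .polysub_cache$sites[[codon]]
  c(syn = s, nonsyn = 3 - s)
}

# total NG86 sites over a codon vector
ng86_sites_seq <- function(codons) {
  s <- sum(vapply(codons, function(cd) ng86_sites(cd)[["syn"]], 0))
  c(syn = s, nonsyn = 3 * length(codons) - s)
}

# permutations of 1..n for n <= 3
perms <- function(n) {
  switch(n,
         list(1L),
         list(c(1L, 2L), c(2L, 1L)),
         list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
              c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
}

# pathway-averaged synonymous/non-synonymous difference counts between two
# sense codons; pathways through stop codons are excluded; if every
# pathway is blocked, all are used with stop steps dropped (flagged)
codon_differences <- function(c1, c2) {
  gc <- genetic_code()
  if (c1 == c2) return(list(sd = 0, nd = 0, blocked = FALSE))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  paths <- lapply(perms(length(pos)), function(ord) {
    cur <- c1
    steps <- data.frame(syn = logical(0), stop = logical(0))
    for (p in pos[ord]) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      steps <- rbind(steps, data.frame(
        syn = gc[[nxt]] != "*" && gc[[cur]] != "*" &&
          gc[[nxt]] == gc[[cur]],
        stop = gc[[nxt]] == "*"))
      cur <- nxt
    }
    steps
  })
  valid <- !vapply(paths, function(s) any(s$stop), TRUE)
  blocked <- !any(valid)
  use <- if (blocked) paths else paths[valid]
  sd <- mean(vapply(use, function(s) sum(s$syn & !s$stop), 0))
  nd <- mean(vapply(use, function(s) sum(!s$syn & !s$stop), 0))
  list(sd = sd, nd = nd, blocked = blocked)
}

# lazily built 61x61 lookup of pathway-averaged differences
codon_diff_table <- function() {
  if (!is.null(.polysub_cache$diffs)) return(.polysub_cache$diffs)
  sense <- sense_codons()
  n <- length(sense)
  sd <- matrix(0, n, n, dimnames = list(sense, sense))
  nd <- sd
  blocked <- matrix(FALSE, n, n, dimnames = list(sense, sense))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      d <- codon_differences(sense[i], sense[j])
      sd[i, j] <- sd[j, i] <- d$sd
      nd[i, j] <- nd[j, i] <- d$nd
      blocked[i, j] <- blocked[j, i] <- d$blocked
    }
  }
  .polysub_cache$diffs <- list(sd = sd, nd = nd, blocked = blocked)
  .polysub_cache$diffs
}

split_codons <- function(seq) {
  if (nchar(seq) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

validate_alignment <- function(seqA, seqB) {
  if (nchar(seqA) != nchar(seqB)) stop("aligned sequences differ in length")
  if (grepl("[^ACGT]", seqA) || grepl("[^ACGT]", seqB))
    stop("only A/C/G/T allowed (no gaps or ambiguity codes)")
  ca <- split_codons(seqA)
  cb <- split_codons(seqB)
  gc <- genetic_code()
  if (any(gc[ca] == "*") || any(gc[cb] == "*"))
    stop("alignment contains stop codons")
  list(a = ca, b = cb)
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

#' NG86 Ka/Ks for one gap-free codon alignment
#'
#' Site counts are averaged over the two sequences; differences per
#' differing codon pair are averaged over all minimal substitution
#' pathways (stop-containing pathways excluded). Proportions are corrected
#' with the Jukes-Cantor formula `-(3/4) log(1 - 4p/3)`; a proportion at or
#' beyond 3/4 is flagged saturated and the corresponding rate is `NA`, as
#' is the Ka/Ks ratio when Ks is 0 or unavailable.
#'
#' @param seqA,seqB equal-length gap-free coding sequences (A/C/G/T, length
#'   a multiple of 3, no stop codons).
#' @return data.frame with one row: S_sites, N_sites, Sd, Nd, pS, pN, Ks,
#'   Ka, ka_ks, and logical flags saturated_syn, saturated_nonsyn,
#'   undefined_ratio, blocked_pathways.
#' @export
ng86_pair <- function(seqA, seqB) {
  cods <- validate_alignment(seqA, seqB)
  if (length(cods$a) < 10L)
    warning("fewer than 10 codons; estimates will be unstable")
  tab <- codon_diff_table()
  sA <- ng86_sites_seq(cods$a)
  sB <- ng86_sites_seq(cods$b)
  S <- (sA[["syn"]] + sB[["syn"]]) / 2
  N <- (sA[["nonsyn"]] + sB[["nonsyn"]]) / 2
  idx <- cbind(cods$a, cods$b)
  Sd <- sum(tab$sd[idx])
  Nd <- sum(tab$nd[idx])
  blocked <- any(tab$blocked[idx])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  sat_s <- !is.na(pS) && pS >= 0.75
  sat_n <- !is.na(pN) && pN >= 0.75
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  data.frame(S_sites = S, N_sites = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
             Ks = Ks, Ka = Ka, ka_ks = ratio,
             saturated_syn = sat_s, saturated_nonsyn = sat_n,
             undefined_ratio = is.na(ratio), blocked_pathways = blocked)
}

#' NG86 Ka/Ks for a table of codon alignments
#'
#' @param alignments data.frame with columns pair_id, seqA, seqB (as
#'   produced by [simulate_cds_pairs()] or [read_codon_pairs()]).
#' @return data.frame with one row per pair: pair_id plus the [ng86_pair()]
#'   and [fourdtv()] columns.
#' @export
kaks_table <- function(alignments) {
  stopifnot(all(c("pair_id", "seqA", "seqB") %in% names(alignments)))
  rows <- lapply(seq_len(nrow(alignments)), function(i) {
    kk <- ng86_pair(alignments$seqA[i], alignments$seqB[i])
    fd <- fourdtv(alignments$seqA[i], alignments$seqB[i])
    cbind(data.frame(pair_id = alignments$pair_id[i]), kk,
          data.frame(n_4d_sites = fd$n_4d_sites,
                     n_transversions = fd$n_transversions,
                     fourdtv = fd$fourdtv))
  })
  do.call(rbind, rows)
}

# codon prefixes whose third position is fourfold degenerate
fourfold_prefixes <- function() {
  c("TC", "CT", "CC", "CG", "AC", "GT", "GC", "GG")
}

#' Transversion rate at fourfold-degenerate third positions (4dTv)
#'
#' A third codon position is counted when both codons belong to a
#' fourfold-degenerate family (all four third-position nucleotides encode
#' the same amino acid) and the first two positions are identical between
#' the sequences. The statistic is the raw fraction of those positions
#' showing a purine-pyrimidine (transversion) difference. An HKY-style
#' distance correction is not applied.
#'
#' @inheritParams ng86_pair
#' @return list with `n_4d_sites`, `n_transversions` and `fourdtv` (the
#'   fraction, `NA` when no fourfold-degenerate site is shared).
#' @export
fourdtv <- function(seqA, seqB) {
  cods <- validate_alignment(seqA, seqB)
  pa <- substr(cods$a, 1, 2)
  pb <- substr(cods$b, 1, 2)
  use <- pa == pb & pa %in% fourfold_prefixes()
  a3 <- substr(cods$a[use], 3, 3)
  b3 <- substr(cods$b[use], 3, 3)
  purine <- function(x) x %in% c("A", "G")
  tv <- sum(a3 != b3 & purine(a3) != purine(b3))
  n <- sum(use)
  list(n_4d_sites = n, n_transversions = tv,
       fourdtv = if (n > 0) tv / n else NA_real_)
}

#' Contrast Ka/Ks distributions between expression-dominance classes
#'
#' Reports the median Ka/Ks per class and Welch's t-test p-values for each
#' class pair. Undefined or saturated ratios are excluded and their counts
#' reported; a class with fewer than two usable values is skipped with a
#' warning.
#'
#' @param kaks data.frame from [kaks_table()] with an added `class` column
#'   (A_dominant / B_dominant / non_dominant), or a named list of numeric
#'   Ka/Ks vectors.
#' @return list with `medians` (named, rounded to 3 decimals in the printed
#'   report), `n_used`, `n_excluded` and `tests` (data.frame class1,
#'   class2, p_value).
#' @export
compare_classes <- function(kaks) {
  if (is.data.frame(kaks)) {
    stopifnot(all(c("ka_ks", "class") %in% names(kaks)))
    groups <- split(kaks$ka_ks, kaks$class)
  } else {
    groups <- kaks
  }
  n_all <- vapply(groups, length, 0L)
  groups <- lapply(groups, function(x) x[is.finite(x)])
  n_used <- vapply(groups, length, 0L)
  usable <- n_used >= 2L
  if (any(!usable))
    warning("classes skipped (fewer than 2 usable ratios): ",
            paste(names(groups)[!usable], collapse = ", "))
  medians <- vapply(groups[usable], median, 0)
  cls <- names(groups)[usable]
  tests <- NULL
  if (length(cls) >= 2L) {
    cmb <- utils::combn(cls, 2)
    tests <- data.frame(class1 = cmb[1, ], class2 = cmb[2, ],
                        p_value = apply(cmb, 2, function(p) {
                          t.test(groups[[p[1]]], groups[[p[2]]])$p.value
                        }))
  }
  list(medians = medians, n_used = n_used, n_excluded = n_all - n_used,
       tests = tests)
}
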