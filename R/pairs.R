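# Homoeologue pair identification from tabular pairwise alignments.
#
# CIP (cumulative identity percentage) and CALP (cumulative alignment
# length percentage) follow the gene-alignment filtering convention: CIP is
# the summed identical columns over the summed HSP lengths, CALP the
# fraction of the query covered by the union of HSP query intervals.
# Retention thresholds are inclusive (CIP >= 60, CALP >= 60 by default).

# total length of the union of 0-based half-open intervals
interval_union_length <- function(start, end) {
  if (length(start) == 0L) return(0)
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  total <- 0
  cur_s <- start[1]; cur_e <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] > cur_e) {
      total <- total + (cur_e - cur_s)
      cur_s <- start[i]; cur_e <- end[i]
    } else {
      cur_e <- max(cur_e, end[i])
    }
  }
  total + (cur_e - cur_s)
}

#' Cumulative identity and alignment-length percentages of a hit
#'
#' @param hsps data.frame with one row per HSP: `query_start`, `query_end`
#'   (0-based half-open on the query), `aligned_length` (alignment columns)
#'   and `identical_columns`.
#' @param query_length query sequence length.
#' @return Named numeric vector `c(cip = , calp = )`, both percentages.
#'   CIP = 100 x sum(identical) / sum(aligned length); CALP = 100 x
#'   (length of the union of query intervals) / query length, so
#'   overlapping HSPs never push coverage above 100.
#' @examples
#' hsps <- data.frame(query_start = c(0, 400), query_end = c(300, 600),
#'                    aligned_length = c(300, 200),
#'                    identical_columns = c(240, 120))
#' compute_cip_calp(hsps, query_length = 1000)  # cip 72, calp 50
#' @export
compute_cip_calp <- function(hsps, query_length) {
  stopifnot(all(c("query_start", "query_end", "aligned_length",
                  "identical_columns") %in% names(hsps)))
  if (nrow(hsps) == 0L) stop("at least one HSP required")
  if (query_length <= 0) stop("query_length must be positive")
  if (sum(hsps$aligned_length) <= 0) stop("zero total aligned length")
  if (any(hsps$identical_columns > hsps$aligned_length |
            hsps$identical_columns < 0))
    stop("identical_columns must lie in [0, aligned_length]")
  if (any(hsps$query_start < 0 | hsps$query_end > query_length))
    stop("HSP query coordinates outside the declared length")
  cip <- 100 * sum(hsps$identical_columns) / sum(hsps$aligned_length)
  calp <- 100 * interval_union_length(hsps$query_start, hsps$query_end) /
    query_length
  c(cip = cip, calp = calp)
}

#' Read a BLAST tabular (outfmt 6) hit file
#'
#' Expects the standard 12 columns (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore). Identical column
#' counts are derived as `round(pident * length / 100)`; query coordinates
#' are converted to 0-based half-open.
#'
#' @param path file path.
#' @return data.frame of HSP rows.
#' @export
read_blast_hits <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("expected 12 outfmt-6 columns")
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  df
}

# per-(query, subject) CIP/CALP from outfmt-6-style rows
cip_calp_table <- function(hits, lengths) {
  stopifnot(all(c("qseqid", "sseqid", "pident", "length", "qstart",
                  "qend") %in% names(hits)))
  dup <- duplicated(hits)
  if (any(dup)) {
    warning(sum(dup), " duplicate hit row(s) merged")
    hits <- hits[!dup, , drop = FALSE]
  }
  qlen <- stats::setNames(lengths$length, lengths$gene)
  missing <- setdiff(unique(hits$qseqid), names(qlen))
  if (length(missing))
    stop("no length for query gene(s): ", paste(missing, collapse = ", "))
  key <- paste(hits$qseqid, hits$sseqid, sep = "\r")
  rows <- lapply(split(seq_len(nrow(hits)), key), function(ix) {
    h <- hits[ix, , drop = FALSE]
    hsps <- data.frame(query_start = h$qstart - 1L, query_end = h$qend,
                       aligned_length = h$length,
                       identical_columns = round(h$pident * h$length / 100))
    cc <- compute_cip_calp(hsps, qlen[[h$qseqid[1]]])
    data.frame(geneA = h$qseqid[1], geneB = h$sseqid[1],
               cip = cc[["cip"]], calp = cc[["calp"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call homoeologue pairs by CIP/CALP filtering and reciprocal best match
#'
#' Candidates passing both inclusive thresholds are ranked per gene
#' (primary key CIP, secondary CALP, ties broken by partner identifier for
#' determinism); a pair is emitted only when the two genes are each
#' other's best candidate, giving a 1:1 partial matching. Pairs present in
#' the optional synteny table are flagged `syntenic`.
#'
#' @param hits outfmt-6-style data.frame of A-vs-B HSP rows (queries from
#'   subgenome A, subjects from subgenome B), e.g. from
#'   [read_blast_hits()] or [simulate_alignment_hits()].
#' @param lengths data.frame with columns `gene`, `length` (query lengths).
#' @param cip_threshold,calp_threshold inclusive retention thresholds in
#'   percent.
#' @param synteny optional two-column data.frame of syntenic gene pairs
#'   (geneA, geneB).
#' @return data.frame: geneA, geneB, cip, calp, syntenic.
#' @export
call_pairs <- function(hits, lengths, cip_threshold = 60,
                       calp_threshold = 60, synteny = NULL) {
  tab <- cip_calp_table(hits, lengths)
  tab <- tab[tab$cip >= cip_threshold & tab$calp >= calp_threshold, ,
             drop = FALSE]
  if (nrow(tab) == 0L)
    return(data.frame(geneA = character(), geneB = character(),
                      cip = numeric(), calp = numeric(),
                      syntenic = logical()))
  best_of <- function(df, by, partner) {
    df <- df[order(df[[by]], -df$cip, -df$calp, df[[partner]]), ]
    df[!duplicated(df[[by]]), c(by, partner)]
  }
  bA <- best_of(tab, "geneA", "geneB")
  bB <- best_of(tab, "geneB", "geneA")
  keyA <- paste(bA$geneA, bA$geneB)
  keyB <- paste(bB$geneA, bB$geneB)
  keep <- intersect(keyA, keyB)
  out <- tab[paste(tab$geneA, tab$geneB) %in% keep, , drop = FALSE]
  out <- out[order(out$geneA), , drop = FALSE]
  out$syntenic <- if (is.null(synteny)) FALSE else
    paste(out$geneA, out$geneB) %in% paste(synteny$geneA, synteny$geneB)
  rownames(out) <- NULL
  out
}
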