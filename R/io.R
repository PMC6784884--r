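# Readers and writers for the package's external formats. All tabular
# outputs are TSV with '#' metadata header lines (tool version, seed,
# config hash); intervals are 0-based half-open throughout.

#' Write / read a bedgraph-style depth track
#'
#' Four columns (chrom, start, end, depth), 0-based half-open, chromosome
#' names "A_chr01".."B_chr11".
#'
#' @param windows depth windows data.frame (chrom, start, end, depth).
#' @param path file path.
#' @param meta character vector of '#' header lines (see internal
#'   `meta_header()`).
#' @return `path` (write) or data.frame (read).
#' @export
write_depth <- function(windows, path, meta = meta_header()) {
  write_tsv_meta(windows[, c("chrom", "start", "end", "depth")], path,
                 meta = meta, col.names = FALSE)
}

#' @rdname write_depth
#' @export
read_depth <- function(path) {
  df <- read_tsv_meta(path, header = FALSE,
                      col.names = c("chrom", "start", "end", "depth"))
  if (nrow(df) == 0L) stop("empty depth file: ", path)
  annotate_windows(df)
}

#' Write / read a homoeologue expression matrix
#'
#' Wide TSV: pair_id, geneA_len, geneB_len, then countA_<sample>_<rep> and
#' countB_<sample>_<rep> column pairs. Library sizes travel in a
#' '# library_sizes:' metadata line.
#'
#' @param expr long expression data.frame (see [simulate_expression()]).
#' @param path file path.
#' @param meta metadata header lines.
#' @export
write_expression <- function(expr, path, meta = meta_header()) {
  combos <- unique(expr[, c("sample", "replicate")])
  combos <- combos[order(combos$sample, combos$replicate), ]
  pairs <- unique(expr[, c("pair_id", "lenA", "lenB")])
  pairs <- pairs[order(pairs$pair_id), ]
  wide <- data.frame(pair_id = pairs$pair_id, geneA_len = pairs$lenA,
                     geneB_len = pairs$lenB)
  libs <- character(0)
  for (i in seq_len(nrow(combos))) {
    s <- combos$sample[i]; r <- combos$replicate[i]
    e <- expr[expr$sample == s & expr$replicate == r, ]
    e <- e[match(pairs$pair_id, e$pair_id), ]
    wide[[paste("countA", s, r, sep = "_")]] <- e$countA
    wide[[paste("countB", s, r, sep = "_")]] <- e$countB
    libs <- c(libs, sprintf("%s_%s=%g", s, r, e$lib_size[1]))
  }
  meta <- c(meta, paste0("# library_sizes: ", paste(libs, collapse = ",")))
  write_tsv_meta(wide, path, meta = meta)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  meta <- read_meta(path)
  if (!"library_sizes" %in% names(meta))
    stop("expression file lacks a '# library_sizes:' metadata line")
  libs <- strsplit(strsplit(meta[["library_sizes"]], ",")[[1]], "=")
  lib_size <- stats::setNames(as.numeric(vapply(libs, `[`, "", 2L)),
                              vapply(libs, `[`, "", 1L))
  wide <- read_tsv_meta(path)
  count_cols <- grep("^count[AB]_", names(wide), value = TRUE)
  long <- lapply(count_cols[startsWith(count_cols, "countA_")],
                 function(ca) {
    tag <- sub("^countA_", "", ca)
    parts <- strsplit(tag, "_")[[1]]
    data.frame(pair_id = wide$pair_id, sample = parts[1],
               replicate = parts[2], countA = wide[[ca]],
               countB = wide[[paste0("countB_", tag)]],
               lib_size = lib_size[[tag]], lenA = wide$geneA_len,
               lenB = wide$geneB_len)
  })
  out <- do.call(rbind, long)
  out <- out[order(out$pair_id, out$sample, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Write / read paired codon alignments as FASTA
#'
#' Two records per pair with `_A` / `_B` identifier suffixes.
#'
#' @param alignments data.frame: pair_id, seqA, seqB.
#' @param path file path.
#' @export
write_codon_pairs <- function(alignments, path) {
  seqs <- character(2 * nrow(alignments))
  nms <- character(2 * nrow(alignments))
  seqs[c(TRUE, FALSE)] <- alignments$seqA
  seqs[c(FALSE, TRUE)] <- alignments$seqB
  nms[c(TRUE, FALSE)] <- paste0(alignments$pair_id, "_A")
  nms[c(FALSE, TRUE)] <- paste0(alignments$pair_id, "_B")
  x <- Biostrings::DNAStringSet(stats::setNames(seqs, nms))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_codon_pairs
#' @export
read_codon_pairs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nms <- names(x)
  ids <- sub("_[AB]$", "", nms)
  a <- x[endsWith(nms, "_A")]
  b <- x[endsWith(nms, "_B")]
  ids_a <- sub("_A$", "", names(a))
  ids_b <- sub("_B$", "", names(b))
  if (!setequal(ids_a, ids_b))
    stop("unpaired records in ", path)
  b <- b[match(ids_a, ids_b)]
  data.frame(pair_id = ids_a, seqA = as.character(a),
             seqB = as.character(b), row.names = NULL)
}

#' Write HE segments as BED6-compatible TSV
#'
#' chrom is the homoeologous group rendered as "HG<nn>"; name carries the
#' direction (donor -> recipient), score the number of supporting windows.
#'
#' @param segments data.frame from [segment_hes()].
#' @param path file path.
#' @param meta metadata header lines.
#' @export
write_segments_bed <- function(segments, path, meta = meta_header()) {
  bed <- data.frame(chrom = sprintf("HG%02d", segments$group),
                    start = segments$start, end = segments$end,
                    name = if (nrow(segments)) paste(segments$direction,
                                                     segments$type,
                                                     sep = ";")
                           else character(0),
                    score = segments$n_windows,
                    strand = rep(".", nrow(segments)))
  bed <- bed[order(bed$chrom, bed$start), ]
  write_tsv_meta(bed, path, meta = meta, col.names = FALSE)
}

#' @rdname write_segments_bed
#' @export
read_segments_bed <- function(path) {
  df <- read_tsv_meta(path, header = FALSE,
                      col.names = c("chrom", "start", "end", "name",
                                    "score", "strand"))
  parts <- strsplit(df$name, ";")
  data.frame(group = as.integer(sub("^HG", "", df$chrom)),
             start = df$start, end = df$end,
             direction = vapply(parts, `[`, "", 1L),
             type = vapply(parts, `[`, "", 2L),
             n_windows = df$score)
}

#' Write a BLAST-tabular hit file
#'
#' @param hits outfmt-6-style data.frame (12 columns).
#' @param path file path.
#' @export
write_blast_hits <- function(hits, path) {
  write_tsv_meta(hits, path, meta = character(), col.names = FALSE)
}
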