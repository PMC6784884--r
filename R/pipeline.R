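# End-to-end pipeline: simulate -> pairs -> hecall -> dominance -> kaks,
# with every stage output written to disk and a JSON report tying the
# stages together.

#' Run the full subgenome-analysis pipeline on simulated data
#'
#' Generates all inputs with [simulate_depth()], [simulate_expression()],
#' [simulate_cds_pairs()] and [simulate_alignment_hits()], writes them in
#' their external formats, then runs homoeologue-pair calling, HE calling
#' and constitution inference, dominance classification, the dosage
#' summary, and Ka/Ks-by-class contrasts. A single global seed (in the
#' config) fans out to fixed per-stage child seeds, so each stage is
#' individually reproducible; re-running with an identical config
#' reproduces identical files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param min_windows minimum HE segment length in windows.
#' @return the report list (also written as `report.json`), with elements
#'   constitution, he_segments (counts by direction), dominance (counts by
#'   class), dosage, kaks (class medians), seed and config hash.
#' @export
run_pipeline <- function(config, out_dir, min_windows = 3L) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- meta_header(config = config, seed = config$seed)
  path <- function(f) file.path(out_dir, f)

  # --- simulate ---------------------------------------------------------
  depth <- simulate_depth(config)
  expr <- simulate_expression(config)
  cds <- simulate_cds_pairs(config)
  aln <- simulate_alignment_hits(config)
  write_depth(depth$windows, path("depth.bedgraph"), meta = meta)
  write_expression(expr$expr, path("expression.tsv"), meta = meta)
  write_codon_pairs(cds$alignments, path("cds_pairs.fasta"))
  write_blast_hits(aln$hits, path("hits.outfmt6"))
  jsonlite::write_json(
    list(constitution = depth$truth$summary,
         hes = depth$truth$hes,
         dominance = expr$truth$dominance,
         compensation = expr$truth$compensation,
         substitutions = cds$truth$counts),
    path("truth.json"), auto_unbox = TRUE, digits = NA, null = "null")

  # --- pairs ------------------------------------------------------------
  pairs <- call_pairs(aln$hits, aln$lengths, synteny = aln$synteny)
  write_tsv_meta(pairs, path("pairs.tsv"), meta = meta)

  # --- hecall -----------------------------------------------------------
  d1 <- estimate_per_copy_depth(depth$windows, config$constitution)
  states <- classify_windows(depth$windows, d1, config$constitution,
                             dispersion = config$dispersion)
  segments <- segment_hes(states, config$constitution,
                          min_windows = min_windows)
  constitution <- summarize_constitution(states)
  write_segments_bed(segments, path("he_segments.bed"), meta = meta)

  # --- dominance --------------------------------------------------------
  dominance <- call_dominance(expr$expr, config$constitution)
  write_tsv_meta(dominance, path("dominance.tsv"), meta = meta)
  dosage <- dosage_summary(expr$expr, config$constitution)

  # --- molecular evolution ---------------------------------------------
  kaks <- kaks_table(cds$alignments)
  kaks$class <- dominance$class[match(kaks$pair_id, dominance$pair_id)]
  kaks$class[is.na(kaks$class)] <- "non_dominant"
  write_tsv_meta(kaks, path("kaks.tsv"), meta = meta)
  classes <- suppressWarnings(compare_classes(kaks))

  report <- list(
    tool = paste0("polysub ",
                  as.character(utils::packageVersion("polysub"))),
    seed = config$seed,
    config_hash = config_hash(config),
    constitution = list(call = constitution$summary,
                        total_A = constitution$total_A,
                        total_B = constitution$total_B,
                        per_copy_depth = d1),
    he_segments = list(
      n_total = nrow(segments),
      n_A_to_B = sum(segments$direction == "A_to_B" &
                       segments$type == "segmental"),
      n_B_to_A = sum(segments$direction == "B_to_A" &
                       segments$type == "segmental"),
      n_replacements = sum(segments$type == "replacement")),
    dominance = as.list(table(factor(dominance$class,
                                     levels = c("A_dominant", "B_dominant",
                                                "non_dominant")))),
    dosage = list(median_log2 = dosage$median_log2,
                  median_ratio = dosage$median_ratio,
                  expected_log2 = dosage$expected_log2,
                  compensation_index = dosage$compensation_index),
    kaks = list(medians = as.list(round(classes$medians, 3)),
                n_excluded = as.list(classes$n_excluded)))
  jsonlite::write_json(report, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  writeLines(c(meta, paste0("# stages: simulate,pairs,hecall,dominance,",
                            "kaks")),
             path("run.log"))
  invisible(report)
}
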