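#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' an ABB-like allotriploid banana: 11 homoeologous chromosome groups of
#' 30 Mb per subgenome, 100 kb depth windows at 20x unique-read depth per
#' chromosome copy, 5,000 homoeologue pairs expressed at a per-copy mean of
#' 200 counts in two samples with two biological replicates each, and codon
#' alignments diverged to Ks 0.2 / Ka 0.05.
#'
#' @param seed integer seed; identical seed + config reproduces
#'   byte-identical outputs.
#' @param constitution constitution string, e.g. "ABB" (see
#'   [parse_constitution()]).
#' @param n_groups number of homoeologous chromosome groups.
#' @param chrom_length chromosome length in bp (scalar or one per group).
#' @param window_size depth window size in bp.
#' @param per_copy_depth mean unique-read depth contributed by one
#'   chromosome copy.
#' @param dispersion negative-binomial over-dispersion alpha with variance
#'   `mu + alpha * mu^2`; 0 gives Poisson.
#' @param planted_hes data.frame with columns `subgenome` (the subgenome
#'   that loses its copy), `group`, `start`, `end` (bp, 0-based half-open)
#'   of segmental homoeologous exchanges. Events are copy-conserving
#'   substitutions: the lost copy is replaced by one extra copy of the
#'   homoeologous segment.
#' @param planted_replacements data.frame with columns `subgenome` (the one
#'   replaced) and `group`, for whole-chromosome replacements.
#' @param n_pairs number of homoeologue gene pairs to simulate.
#' @param expr_mean per-copy mean read count for a 1 kb gene at the nominal
#'   library size.
#' @param n_samples,n_reps samples and biological replicates per sample.
#' @param library_size nominal mapped-library size per replicate.
#' @param dominance_fraction fraction of pairs with planted expression
#'   dominance (split evenly between A- and B-favoured).
#' @param dominance_effect per-copy fold effect applied to the favoured
#'   homoeologue.
#' @param compensation multiplicative factor applied to pair totals
#'   (1 = none; < 1 models dosage compensation toward a diploid output).
#' @param n_codon_pairs,codons_per_pair codon-alignment pairs and their
#'   length in codons.
#' @param target_ks,target_ka target Jukes-Cantor-corrected synonymous and
#'   non-synonymous substitution rates for the simulated alignments.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       constitution = "ABB",
                       n_groups = 11L,
                       chrom_length = 30e6,
                       window_size = 100e3,
                       per_copy_depth = 20,
                       dispersion = 0,
                       planted_hes = NULL,
                       planted_replacements = NULL,
                       n_pairs = 5000L,
                       expr_mean = 200,
                       n_samples = 2L,
                       n_reps = 2L,
                       library_size = 1e6,
                       dominance_fraction = 0,
                       dominance_effect = 4,
                       compensation = 1,
                       n_codon_pairs = 50L,
                       codons_per_pair = 300L,
                       target_ks = 0.2,
                       target_ka = 0.05) {
  ploidy <- parse_constitution(constitution)
  if (sum(ploidy) < 2L)
    stop("total ploidy must be at least 2")
  if (window_size <= 0)
    stop("window_size must be positive")
  if (dominance_fraction < 0 || dominance_fraction > 1)
    stop("dominance_fraction must lie in [0, 1]")
  if (n_reps < 1L || n_samples < 1L)
    stop("need at least one sample and one replicate")
  if (codons_per_pair < 10L)
    stop("codons_per_pair must be >= 10")
  chrom_length <- rep_len(chrom_length, n_groups)
  if (any(chrom_length < window_size))
    stop("chromosomes must span at least one window")
  if (!is.null(planted_hes)) {
    planted_hes <- as.data.frame(planted_hes)
    stopifnot(all(c("subgenome", "group", "start", "end") %in%
                    names(planted_hes)))
    bad <- !(planted_hes$subgenome %in% c("A", "B")) |
      planted_hes$group < 1L | planted_hes$group > n_groups |
      planted_hes$start < 0 | planted_hes$end <= planted_hes$start |
      planted_hes$end > chrom_length[planted_hes$group]
    if (any(bad))
      stop("planted HE outside its chromosome or malformed")
  }
  if (!is.null(planted_replacements)) {
    planted_replacements <- as.data.frame(planted_replacements)
    stopifnot(all(c("subgenome", "group") %in% names(planted_replacements)))
    if (any(!(planted_replacements$subgenome %in% c("A", "B")) |
              planted_replacements$group < 1L |
              planted_replacements$group > n_groups))
      stop("planted replacement outside the genome")
  }
  structure(list(
    seed = as.integer(seed), constitution = constitution, ploidy = ploidy,
    n_groups = as.integer(n_groups), chrom_length = chrom_length,
    window_size = window_size, per_copy_depth = per_copy_depth,
    dispersion = dispersion, planted_hes = planted_hes,
    planted_replacements = planted_replacements,
    n_pairs = as.integer(n_pairs), expr_mean = expr_mean,
    n_samples = as.integer(n_samples), n_reps = as.integer(n_reps),
    library_size = library_size,
    dominance_fraction = dominance_fraction,
    dominance_effect = dominance_effect, compensation = compensation,
    n_codon_pairs = as.integer(n_codon_pairs),
    codons_per_pair = as.integer(codons_per_pair),
    target_ks = target_ks, target_ka = target_ka),
    class = "sim_config")
}

# count draw: Poisson, or NB with variance mu + alpha mu^2
rcount <- function(n, mu, alpha) {
  if (alpha > 0) rnbinom(n, mu = mu, size = 1 / alpha) else rpois(n, mu)
}

chrom_name <- function(subgenome, group) {
  sprintf("%s_chr%02d", subgenome, group)
}

#' Simulate windowed unique-read depth for an allopolyploid
#'
#' Draws one depth value per non-overlapping window per subgenome
#' chromosome, with mean = copy number x `per_copy_depth`. Planted
#' homoeologous exchanges are copy-conserving substitutions: a window that
#' loses its copy on one subgenome gains one on the homoeologous window of
#' the other, so every window satisfies nA + nB = total ploidy. Whole
#' chromosomes can be replaced the same way. Event coordinates are snapped
#' outward to the window grid; the truth records the snapped coordinates.
#'
#' @param config a [sim_config()].
#' @return list with `windows` (data.frame: subgenome, chrom, group, start,
#'   end, depth) and `truth` (list: `states` per homoeologous window,
#'   `hes`, `replacements`, `constitution` per group, `summary`).
#' @export
simulate_depth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  w <- config$window_size
  nom <- config$ploidy

  states <- do.call(rbind, lapply(seq_len(config$n_groups), function(g) {
    starts <- seq(0, config$chrom_length[g] - 1, by = w)
    data.frame(group = g, start = starts,
               end = pmin(starts + w, config$chrom_length[g]),
               nA = nom[["A"]], nB = nom[["B"]])
  }))

  # whole-chromosome replacements: recipient loses all copies, donor gains
  repl <- config$planted_replacements
  const <- data.frame(group = seq_len(config$n_groups),
                      nA = nom[["A"]], nB = nom[["B"]])
  if (!is.null(repl)) {
    for (i in seq_len(nrow(repl))) {
      g <- repl$group[i]
      lost <- repl$subgenome[i]
      gain <- if (lost == "A") "B" else "A"
      k <- const[[paste0("n", lost)]][g]
      if (k == 0) stop("replacement of a subgenome with zero copies")
      const[const$group == g, paste0("n", lost)] <- 0L
      const[const$group == g, paste0("n", gain)] <-
        const[const$group == g, paste0("n", gain)] + k
      sel <- states$group == g
      states[sel, paste0("n", lost)] <- 0L
      states[sel, paste0("n", gain)] <- states[sel, paste0("n", gain)] + k
    }
  }

  # segmental HEs, snapped outward to the window grid
  hes <- config$planted_hes
  hes_truth <- NULL
  if (!is.null(hes) && nrow(hes)) {
    hes$start <- floor(hes$start / w) * w
    hes$end <- pmin(ceiling(hes$end / w) * w,
                    config$chrom_length[hes$group])
    for (sg in c("A", "B")) {
      ev <- hes[hes$subgenome == sg, , drop = FALSE]
      for (g in unique(ev$group)) {
        ivl <- ev[ev$group == g, , drop = FALSE]
        ivl <- ivl[order(ivl$start), ]
        if (nrow(ivl) > 1 && any(ivl$start[-1] < ivl$end[-nrow(ivl)]))
          stop("overlapping planted HEs on the same subgenome segment")
      }
    }
    for (i in seq_len(nrow(hes))) {
      lost <- hes$subgenome[i]
      gain <- if (lost == "A") "B" else "A"
      sel <- states$group == hes$group[i] &
        states$start >= hes$start[i] & states$start < hes$end[i]
      if (any(states[sel, paste0("n", lost)] == 0))
        stop("planted HE removes a copy from a zero-copy segment")
      states[sel, paste0("n", lost)] <- states[sel, paste0("n", lost)] - 1L
      states[sel, paste0("n", gain)] <- states[sel, paste0("n", gain)] + 1L
    }
    hes_truth <- data.frame(
      group = hes$group, start = hes$start, end = hes$end,
      subgenome_lost = hes$subgenome,
      direction = ifelse(hes$subgenome == "A", "B_to_A", "A_to_B"),
      n_windows = (hes$end - hes$start) %/% w)
  }

  d <- config$per_copy_depth
  windows <- rbind(
    data.frame(subgenome = "A", chrom = chrom_name("A", states$group),
               group = states$group, start = states$start, end = states$end,
               depth = rcount(nrow(states), states$nA * d,
                              config$dispersion)),
    data.frame(subgenome = "B", chrom = chrom_name("B", states$group),
               group = states$group, start = states$start, end = states$end,
               depth = rcount(nrow(states), states$nB * d,
                              config$dispersion)))

  truth <- list(states = states, hes = hes_truth, replacements = repl,
                constitution = const,
                summary = sprintf("%dA+%dB", sum(const$nA), sum(const$nB)))
  list(windows = windows, truth = truth)
}

#' Simulate paired homoeologue expression counts
#'
#' For each homoeologue pair and each sample x replicate, draws read counts
#' for the A and B copies with per-copy mean `expr_mean`, scaled by the
#' subgenome copy number, the shared gene length (in kb), the library size,
#' the compensation factor (applied to both homoeologues, preserving the
#' within-pair ratio), and a planted dominance effect on the favoured copy
#' of a labelled subset of pairs.
#'
#' @param config a [sim_config()].
#' @return list with `expr` (long data.frame: pair_id, sample, replicate,
#'   countA, countB, lib_size, lenA, lenB) and `truth` (data.frame pair_id,
#'   class in {A_dominant, B_dominant, non_dominant}, effect; plus the
#'   compensation factor as attribute-free list entry).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_pairs < 1L) stop("n_pairs must be >= 1")
  set.seed(config$seed + 1009L)
  n <- config$n_pairs
  nom <- config$ploidy
  pair_id <- sprintf("pair%05d", seq_len(n))
  len <- round(exp(runif(n, log(500), log(3000))))

  class <- rep("non_dominant", n)
  n_dom <- round(config$dominance_fraction * n)
  if (n_dom > 0) {
    idx <- sample.int(n, n_dom)
    class[idx] <- rep_len(c("B_dominant", "A_dominant"), n_dom)
  }
  effA <- ifelse(class == "A_dominant", config$dominance_effect, 1)
  effB <- ifelse(class == "B_dominant", config$dominance_effect, 1)

  grid <- expand.grid(sample = sprintf("S%d", seq_len(config$n_samples)),
                      replicate = sprintf("R%d", seq_len(config$n_reps)),
                      stringsAsFactors = FALSE)
  expr <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    base <- config$expr_mean * (len / 1000) *
      (config$library_size / 1e6) * config$compensation
    data.frame(pair_id = pair_id, sample = grid$sample[i],
               replicate = grid$replicate[i],
               countA = rcount(n, base * nom[["A"]] * effA,
                               config$dispersion),
               countB = rcount(n, base * nom[["B"]] * effB,
                               config$dispersion),
               lib_size = config$library_size, lenA = len, lenB = len)
  }))
  expr <- expr[order(expr$pair_id, expr$sample, expr$replicate), ]
  rownames(expr) <- NULL

  truth <- list(dominance = data.frame(pair_id = pair_id, class = class,
                                       effect = ifelse(class ==
                                         "non_dominant", 1,
                                         config$dominance_effect)),
                compensation = config$compensation)
  list(expr = expr, truth = truth)
}

#' Simulate diverged codon-alignment pairs with known substitution counts
#'
#' Builds a random ancestor of sense codons per pair, then applies known
#' numbers of synonymous and non-synonymous single-nucleotide substitutions
#' (at most one per codon, never creating stop codons, no gaps). Event
#' counts are binomial draws whose expectation matches the inverse
#' Jukes-Cantor proportion of `target_ks`/`target_ka`, so the corrected
#' NG86 estimates centre on the targets.
#'
#' @param config a [sim_config()].
#' @return list with `alignments` (data.frame: pair_id, seqA, seqB) and
#'   `truth` (data.frame pair_id, n_syn, n_nonsyn, plus a `substitutions`
#'   data.frame with codon index, position, from, to, type, and the
#'   ancestor sequences).
#' @export
simulate_cds_pairs <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2003L)
  nc <- config$codons_per_pair
  # proportion of sites to hit so that the JC-corrected rate equals target
  p_syn <- 0.75 * (1 - exp(-4 * config$target_ks / 3))
  p_non <- 0.75 * (1 - exp(-4 * config$target_ka / 3))

  sense <- sense_codons()
  neighbours <- codon_neighbours()  # per codon: syn / nonsyn sense changes

  res_aln <- vector("list", config$n_codon_pairs)
  res_truth <- vector("list", config$n_codon_pairs)
  for (p in seq_len(config$n_codon_pairs)) {
    id <- sprintf("pair%05d", p)
    anc <- sample(sense, nc, replace = TRUE)
    sites <- ng86_sites_seq(anc)
    n_syn <- rbinom(1, round(sites[["syn"]]), p_syn)
    n_non <- rbinom(1, round(sites[["nonsyn"]]), p_non)

    has_syn <- which(vapply(neighbours[anc],
                            function(x) nrow(x$syn) > 0, TRUE))
    if (n_syn > length(has_syn))
      stop("requested synonymous substitutions exceed available sites")
    syn_at <- if (n_syn) sample(has_syn, n_syn) else integer()
    rest <- setdiff(seq_len(nc), syn_at)
    has_non <- rest[vapply(neighbours[anc[rest]],
                           function(x) nrow(x$nonsyn) > 0, TRUE)]
    if (n_non > length(has_non))
      stop("requested non-synonymous substitutions exceed available sites")
    non_at <- if (n_non) sample(has_non, n_non) else integer()

    derived <- anc
    subs <- list()
    for (i in syn_at) {
      opts <- neighbours[[anc[i]]]$syn
      k <- sample.int(nrow(opts), 1)
      derived[i] <- opts$codon[k]
      subs[[length(subs) + 1]] <- data.frame(
        codon = i, position = opts$position[k],
        from = substr(anc[i], opts$position[k], opts$position[k]),
        to = substr(opts$codon[k], opts$position[k], opts$position[k]),
        type = "synonymous")
    }
    for (i in non_at) {
      opts <- neighbours[[anc[i]]]$nonsyn
      k <- sample.int(nrow(opts), 1)
      derived[i] <- opts$codon[k]
      subs[[length(subs) + 1]] <- data.frame(
        codon = i, position = opts$position[k],
        from = substr(anc[i], opts$position[k], opts$position[k]),
        to = substr(opts$codon[k], opts$position[k], opts$position[k]),
        type = "non_synonymous")
    }
    res_aln[[p]] <- data.frame(pair_id = id,
                               seqA = paste(anc, collapse = ""),
                               seqB = paste(derived, collapse = ""))
    res_truth[[p]] <- list(
      pair_id = id, n_syn = n_syn, n_nonsyn = n_non,
      ancestor = paste(anc, collapse = ""),
      substitutions = if (length(subs)) do.call(rbind, subs) else
        data.frame(codon = integer(), position = integer(),
                   from = character(), to = character(),
                   type = character()))
  }
  counts <- data.frame(
    pair_id = vapply(res_truth, `[[`, "", "pair_id"),
    n_syn = vapply(res_truth, `[[`, 0L, "n_syn"),
    n_nonsyn = vapply(res_truth, `[[`, 0L, "n_nonsyn"))
  list(alignments = do.call(rbind, res_aln),
       truth = list(counts = counts, detail = res_truth))
}

#' Simulate a BLAST-tabular hit table with known CIP/CALP
#'
#' Constructs homoeologue candidate hits whose cumulative identity
#' percentage (CIP) and cumulative alignment length percentage (CALP) are
#' known by construction: HSP lengths, identities and disjoint query
#' intervals are chosen first and the truth values computed by hand
#' arithmetic, independent of [compute_cip_calp()]. The table includes a
#' perfect full-length pair, the two-HSP CIP 72 / CALP 50 case, a pair at
#' exactly the 60/60 inclusive boundary (flagged `boundary`), sub-threshold
#' and non-reciprocal decoy hits.
#'
#' @param config a [sim_config()]; only the seed and `n_pairs` (capped at
#'   30) are used.
#' @return list with `hits` (data.frame in BLAST outfmt-6 column order),
#'   `lengths` (data.frame gene, length), `synteny` (two-column data.frame
#'   of syntenic gene pairs) and `truth` (data.frame geneA, geneB, cip,
#'   calp, boundary, true_pair).
#' @export
simulate_alignment_hits <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3001L)
  n <- min(config$n_pairs, 30L)
  n <- max(n, 4L)
  ga <- sprintf("gA%03d", seq_len(n))
  gb <- sprintf("gB%03d", seq_len(n))

  hsp_rows <- list()
  truth <- list()
  lens <- numeric(0)
  add_hit <- function(q, s, qlen, hsps) {
    # hsps: data.frame(qstart0, len, id) with disjoint query intervals
    for (i in seq_len(nrow(hsps))) {
      pid <- 100 * hsps$id[i] / hsps$len[i]
      hsp_rows[[length(hsp_rows) + 1]] <<- data.frame(
        qseqid = q, sseqid = s, pident = round(pid, 3),
        length = hsps$len[i], mismatch = hsps$len[i] - hsps$id[i],
        gapopen = 0L, qstart = hsps$qstart0[i] + 1L,
        qend = hsps$qstart0[i] + hsps$len[i],
        sstart = hsps$qstart0[i] + 1L, send = hsps$qstart0[i] + hsps$len[i],
        evalue = 1e-50, bitscore = round(hsps$id[i] * 2))
    }
    lens[q] <<- qlen
    if (!s %in% names(lens)) lens[s] <<- qlen
  }

  for (i in seq_len(n)) {
    if (i == 1L) {           # perfect full-length pair
      qlen <- 900; h <- data.frame(qstart0 = 0, len = 900, id = 900)
      cip <- 100; calp <- 100; boundary <- FALSE
    } else if (i == 2L) {    # two-HSP hand case: (240+120)/500, 500/1000
      qlen <- 1000
      h <- data.frame(qstart0 = c(0, 400), len = c(300, 200),
                      id = c(240, 120))
      cip <- 72; calp <- 50; boundary <- FALSE
    } else if (i == 3L) {    # exactly at the inclusive 60/60 boundary
      qlen <- 1000; h <- data.frame(qstart0 = 100, len = 600, id = 360)
      cip <- 60; calp <- 60; boundary <- TRUE
    } else {                 # random well-separated true pair
      qlen <- sample(600:1500, 1)
      cov <- round(qlen * runif(1, 0.7, 1.0))
      id <- round(cov * runif(1, 0.8, 0.98))
      h <- data.frame(qstart0 = sample(0:(qlen - cov), 1), len = cov,
                      id = id)
      cip <- 100 * id / cov; calp <- 100 * cov / qlen; boundary <- FALSE
    }
    add_hit(ga[i], gb[i], qlen, h)
    truth[[i]] <- data.frame(geneA = ga[i], geneB = gb[i], cip = cip,
                             calp = calp, boundary = boundary,
                             true_pair = TRUE)
  }
  # decoys: weaker cross hits (never outranking a true pair, and kept away
  # from the fixed hand-built cases) and one sub-threshold pair
  for (i in setdiff(seq_len(min(n - 1L, 9L)), 1:3)) {
    qlen <- lens[ga[i]]
    cov <- round(qlen * 0.65)
    id <- round(cov * 0.7)
    add_hit(ga[i], gb[i + 1L], qlen,
            data.frame(qstart0 = 0, len = cov, id = id))
    truth[[length(truth) + 1]] <- data.frame(
      geneA = ga[i], geneB = gb[i + 1L], cip = 100 * id / cov,
      calp = 100 * cov / qlen, boundary = FALSE, true_pair = FALSE)
  }
  qlen <- lens[[ga[n]]]
  half <- round(qlen / 2)
  add_hit(ga[n], gb[n - 1L], qlen,
          data.frame(qstart0 = 0, len = half, id = round(half / 2)))
  truth[[length(truth) + 1]] <- data.frame(
    geneA = ga[n], geneB = gb[n - 1L], cip = 100 * round(half / 2) / half,
    calp = 100 * half / qlen, boundary = FALSE, true_pair = FALSE)
  truth <- do.call(rbind, truth)
  hits <- do.call(rbind, hsp_rows)
  synteny <- data.frame(geneA = ga[seq_len(ceiling(0.8 * n))],
                        geneB = gb[seq_len(ceiling(0.8 * n))])
  list(hits = hits,
       lengths = data.frame(gene = names(lens), length = unname(lens)),
       synteny = synteny, truth = truth)
}
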