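# The generator must reproduce the planted study conditions exactly
# (truth records) and statistically (sample means against the copy-number
# x per-copy-depth model).

test_that("identical seed and config reproduce identical outputs", {
  cfg <- abb_config(seed = 42, n_pairs = 50, n_codon_pairs = 3)
  for (f in list(simulate_depth, simulate_expression, simulate_cds_pairs,
                 simulate_alignment_hits)) {
    expect_identical(f(cfg), f(cfg))
  }
})

test_that("depth follows copy number x per-copy depth and conserves copies", {
  cfg <- abb_config(seed = 9, per_copy_depth = 20)
  sim <- simulate_depth(cfg)
  w <- sim$windows
  a <- w$depth[w$subgenome == "A"]
  b <- w$depth[w$subgenome == "B"]
  # Poisson mean 20 and 40; 3 standard errors over n windows
  expect_lt(abs(mean(a) - 20), 3 * sqrt(20 / length(a)))
  expect_lt(abs(mean(b) - 40), 3 * sqrt(40 / length(b)))
  expect_null(sim$truth$hes)
  expect_true(all(sim$truth$states$nA + sim$truth$states$nB == 3))
})

test_that("a planted A-loss segment zeroes A depth and triples B depth", {
  # replicate draws: mean over 100 seeds of the event windows
  ev <- data.frame(subgenome = "A", group = 1, start = 5e5, end = 1e6)
  a_means <- b_means <- numeric(100)
  for (s in 1:100) {
    cfg <- sim_config(seed = s, constitution = "ABB", n_groups = 1,
                      chrom_length = 2e6, planted_hes = ev)
    sim <- simulate_depth(cfg)
    w <- sim$windows
    in_ev <- w$start >= 5e5 & w$start < 1e6
    a_means[s] <- mean(w$depth[w$subgenome == "A" & in_ev])
    b_means[s] <- mean(w$depth[w$subgenome == "B" & in_ev])
    if (s == 1) {
      expect_equal(nrow(sim$truth$hes), 1L)
      expect_identical(sim$truth$hes$direction, "B_to_A")
      expect_equal(sim$truth$hes$n_windows, 5L)
    }
  }
  n_draws <- 100 * 5
  expect_lt(mean(a_means), 3 * sqrt(0.01 / n_draws) + 0.01)
  expect_lt(abs(mean(b_means) - 60), 3 * sqrt(60 / n_draws))
})

test_that("whole-chromosome replacements give the 8A+25B constitution", {
  cfg <- sim_config(seed = 1, constitution = "ABB",
                    planted_replacements = data.frame(
                      subgenome = "A", group = c(2, 7, 11)))
  sim <- simulate_depth(cfg)
  expect_identical(sim$truth$summary, "8A+25B")
  expect_equal(sum(sim$truth$constitution$nA), 8)
  expect_equal(sum(sim$truth$constitution$nB), 25)
})

test_that("invalid depth configurations are rejected", {
  expect_error(abb_config(window_size = 0), "window_size")
  expect_error(
    abb_config(planted_hes = data.frame(subgenome = "A", group = 1,
                                        start = 2.9e6, end = 3.5e6)),
    "outside")
  cfg <- abb_config(planted_hes = data.frame(
    subgenome = c("A", "A"), group = 1, start = c(0, 2e5),
    end = c(4e5, 6e5)))
  expect_error(simulate_depth(cfg), "overlapping")
})

test_that("expression follows the copy ratio, dominance and compensation", {
  cfg <- abb_config(seed = 5, n_pairs = 2000)
  e <- simulate_expression(cfg)$expr
  expect_equal(mean(e$countB) / mean(e$countA), 2, tolerance = 0.02)

  cfg_dom <- abb_config(seed = 5, n_pairs = 2000,
                        dominance_fraction = 0.1, dominance_effect = 4)
  sim <- simulate_expression(cfg_dom)
  tr <- sim$truth$dominance
  e <- sim$expr
  bdom <- tr$pair_id[tr$class == "B_dominant"]
  sel <- e$pair_id %in% bdom
  expect_equal(mean(e$countB[sel]) / mean(e$countA[sel]), 8,
               tolerance = 0.05)

  cfg_comp <- abb_config(seed = 5, n_pairs = 2000, compensation = 0.66)
  ec <- simulate_expression(cfg_comp)$expr
  e0 <- simulate_expression(abb_config(seed = 5, n_pairs = 2000))$expr
  expect_equal(mean(ec$countA + ec$countB) /
                 mean(e0$countA + e0$countB), 0.66, tolerance = 0.02)
  # within-pair ratio preserved under compensation
  expect_equal(mean(ec$countB) / mean(ec$countA), 2, tolerance = 0.02)
})

test_that("library size scales expected counts but not truth labels", {
  cfg1 <- abb_config(seed = 8, n_pairs = 1000, dominance_fraction = 0.2)
  cfg2 <- abb_config(seed = 8, n_pairs = 1000, dominance_fraction = 0.2,
                     library_size = 2e6)
  s1 <- simulate_expression(cfg1)
  s2 <- simulate_expression(cfg2)
  expect_identical(s1$truth$dominance, s2$truth$dominance)
  expect_equal(mean(s2$expr$countA) / mean(s1$expr$countA), 2,
               tolerance = 0.03)
})

test_that("dominance_fraction outside [0,1] is rejected", {
  expect_error(abb_config(dominance_fraction = 1.5), "dominance_fraction")
})

test_that("cds truth substitutions reproduce the emitted sequences", {
  cfg <- abb_config(seed = 13, n_codon_pairs = 5, codons_per_pair = 80)
  sim <- simulate_cds_pairs(cfg)
  for (i in seq_along(sim$truth$detail)) {
    d <- sim$truth$detail[[i]]
    anc <- strsplit(d$ancestor, "")[[1]]
    for (j in seq_len(nrow(d$substitutions))) {
      s <- d$substitutions[j, ]
      at <- (s$codon - 1) * 3 + s$position
      expect_identical(anc[at], s$from)
      anc[at] <- s$to
    }
    expect_identical(paste(anc, collapse = ""), sim$alignments$seqB[i])
    expect_identical(d$ancestor, sim$alignments$seqA[i])
    # one substitution per codon: planted counts are exact Sd/Nd
    expect_equal(sum(d$substitutions$type == "synonymous"), d$n_syn)
  }
})

test_that("zero-divergence cds config yields identical pairs", {
  cfg <- abb_config(seed = 3, n_codon_pairs = 2, target_ks = 0,
                    target_ka = 0)
  sim <- simulate_cds_pairs(cfg)
  expect_identical(sim$alignments$seqA, sim$alignments$seqB)
  expect_true(all(sim$truth$counts$n_syn == 0))
})

test_that("realised synonymous substitutions track the planted proportion", {
  cfg <- abb_config(seed = 21, n_codon_pairs = 30, codons_per_pair = 300)
  sim <- simulate_cds_pairs(cfg)
  anc_syn_sites <- vapply(sim$truth$detail, function(d) {
    s <- 0
    for (cd in substring(d$ancestor, seq(1, nchar(d$ancestor), 3),
                         seq(3, nchar(d$ancestor), 3)))
      s <- s + oracle_sites(cd)
    s
  }, 0)
  p_planted <- 0.75 * (1 - exp(-4 * cfg$target_ks / 3))
  expected <- mean(anc_syn_sites) * p_planted
  # binomial tolerance on the mean over 30 pairs
  se <- sqrt(expected / 30)
  expect_lt(abs(mean(sim$truth$counts$n_syn) - expected), 4 * se)
})

test_that("alignment-hit truth covers the hand-computable fixtures", {
  sim <- simulate_alignment_hits(abb_config(seed = 2, n_pairs = 20))
  tr <- sim$truth
  expect_equal(tr$cip[tr$geneA == "gA001" & tr$true_pair], 100)
  expect_equal(tr$calp[tr$geneA == "gA001" & tr$true_pair], 100)
  expect_equal(tr$cip[tr$geneA == "gA002" & tr$true_pair], 72)
  expect_equal(tr$calp[tr$geneA == "gA002" & tr$true_pair], 50)
  boundary <- tr[tr$boundary, ]
  expect_equal(nrow(boundary), 1L)
  expect_equal(boundary$cip, 60)
  expect_equal(boundary$calp, 60)
})
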