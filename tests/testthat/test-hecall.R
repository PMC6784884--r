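# Window aggregation, per-copy depth estimation, ML copy-state
# classification, HE segmentation and constitution summary.

test_that("aggregate_depth averages records into windows", {
  rec <- data.frame(chrom = "A_chr01", start = 0, end = 300e3, depth = 30)
  w <- aggregate_depth(rec, window_size = 100e3)
  expect_equal(nrow(w), 3L)
  expect_true(all(w$depth == 30))

  halves <- data.frame(chrom = "A_chr01", start = c(0, 50e3),
                       end = c(50e3, 100e3), depth = c(10, 50))
  expect_equal(aggregate_depth(halves, 100e3)$depth, 30)
})

test_that("gaps count as zero depth and match a dense expansion oracle", {
  set.seed(5)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    bounds <- sort(sample(seq(0, 1000, by = 10), n + 1))
    rec <- data.frame(chrom = "A_chr01", start = bounds[-(n + 1)],
                      end = bounds[-1],
                      depth = sample(0:50, n, replace = TRUE))
    rec <- rec[runif(n) > 0.3, ]   # drop some -> gaps
    if (nrow(rec) == 0) next
    w <- aggregate_depth(rec, window_size = 100,
                         chrom_lengths = c(A_chr01 = 1000))
    dense <- numeric(1000)
    for (i in seq_len(nrow(rec)))
      dense[(rec$start[i] + 1):rec$end[i]] <- rec$depth[i]
    expected <- vapply(seq(0, 900, by = 100),
                       function(s) mean(dense[(s + 1):(s + 100)]), 0)
    expect_equal(w$depth, expected)
  }
})

test_that("records beyond the declared chromosome length error", {
  rec <- data.frame(chrom = "A_chr01", start = 0, end = 300, depth = 1)
  expect_error(aggregate_depth(rec, 100, chrom_lengths = c(A_chr01 = 200)),
               "beyond")
})

test_that("per-copy depth is recovered from simulation and robust to HEs", {
  sim <- simulate_depth(abb_config(seed = 2, per_copy_depth = 20))
  d1 <- estimate_per_copy_depth(sim$windows, "ABB")
  expect_equal(d1, 20, tolerance = 0.05)

  # uniform diploid AB depth 30 -> exactly 30
  w <- data.frame(subgenome = rep(c("A", "B"), each = 50),
                  chrom = rep(c("A_chr01", "B_chr01"), each = 50),
                  group = 1, start = rep(seq(0, 49e5, 1e5), 2),
                  end = rep(seq(1e5, 50e5, 1e5), 2), depth = 30)
  expect_equal(estimate_per_copy_depth(w, "AB"), 30)

  # ~20% of windows inside HEs: median still within 10%
  hes <- data.frame(subgenome = "A", group = 1:2, start = 0, end = 6e6)
  sim2 <- simulate_depth(sim_config(seed = 3, constitution = "ABB",
                                    n_groups = 5, chrom_length = 6e6,
                                    planted_hes = hes))
  d2 <- estimate_per_copy_depth(sim2$windows, "ABB")
  expect_equal(d2, 20, tolerance = 0.1)
})

test_that("classification maximises the exhaustive state likelihood", {
  mk <- function(da, db) {
    rbind(data.frame(subgenome = "A", chrom = "A_chr01", group = 1,
                     start = 0, end = 1e5, depth = da),
          data.frame(subgenome = "B", chrom = "B_chr01", group = 1,
                     start = 0, end = 1e5, depth = db))
  }
  cases <- list(list(20, 40, 1L, 2L), list(0, 60, 0L, 3L),
                list(40, 20, 2L, 1L), list(60, 0, 3L, 0L))
  for (cs in cases) {
    st <- classify_windows(mk(cs[[1]], cs[[2]]), d1 = 20, "ABB")
    expect_equal(st$nA, cs[[3]])
    expect_equal(st$nB, cs[[4]])
    # independent exhaustive oracle over the 4 copy-conserving states
    ll <- vapply(0:3, function(nA) {
      muA <- nA * 20 + 0.2; muB <- (3 - nA) * 20 + 0.2
      cs[[1]] * log(muA) - muA - lgamma(cs[[1]] + 1) +
        cs[[2]] * log(muB) - muB - lgamma(cs[[2]] + 1)
    }, 0)
    expect_equal(st$nA, which.max(ll) - 1L)
  }
})

test_that("states conserve total ploidy and handle missing partners", {
  sim <- simulate_depth(abb_config(seed = 4))
  st <- classify_windows(sim$windows, 20, "ABB")
  expect_true(all(st$nA + st$nB == 3, na.rm = TRUE))
  # drop one B window -> its A partner is unresolved
  w <- sim$windows[-which(sim$windows$subgenome == "B")[1], ]
  st2 <- classify_windows(w, 20, "ABB")
  expect_equal(sum(st2$unresolved), 1L)
  expect_true(is.na(st2$nA[st2$unresolved]))
})

make_states <- function(nA, nB, group = 1L) {
  n <- length(nA)
  data.frame(group = group, start = seq(0, by = 1e5, length.out = n),
             end = seq(1e5, by = 1e5, length.out = n),
             depthA = nA * 20, depthB = nB * 20, nA = nA, nB = nB,
             loglik = 0, unresolved = FALSE)
}

test_that("segmentation matches the run-length oracle on random state
           sequences", {
  set.seed(99)
  for (rep in 1:40) {
    n <- sample(5:200, 1)
    nA <- sample(0:3, n, replace = TRUE,
                 prob = c(0.1, 0.7, 0.15, 0.05))
    st <- make_states(nA, 3L - nA)
    min_w <- sample(1:4, 1)
    segs <- segment_hes(st, "ABB", min_windows = min_w,
                        chrom_fraction = 2)  # suppress promotion
    oracle <- oracle_segments(nA, 3L - nA, 1L, 2L, min_w)
    expect_equal(nrow(segs), length(oracle))
    if (length(oracle)) {
      om <- do.call(rbind, oracle)
      expect_equal(segs$start, unname((om[, "from"] - 1) * 1e5))
      expect_equal(segs$end, unname(om[, "to"] * 1e5))
      expect_equal(segs$nA, unname(om[, "nA"]))
    }
  }
})

test_that("segment direction is donor to recipient", {
  # (0,3) in ABB: A lost its copy, B donated -> B_to_A
  st <- make_states(c(1, 0, 0, 0, 0, 1), c(2, 3, 3, 3, 3, 2))
  seg <- segment_hes(st, "ABB")
  expect_equal(nrow(seg), 1L)
  expect_identical(seg$direction, "B_to_A")
  # (2,1): A donated into B's slot -> A_to_B
  st2 <- make_states(c(1, 2, 2, 2, 1), c(2, 1, 1, 1, 2))
  expect_identical(segment_hes(st2, "ABB")$direction, "A_to_B")
})

test_that("runs separated by one nominal window stay separate and short
           runs are dropped", {
  nA <- c(0, 0, 0, 1, 0, 0, 0)
  st <- make_states(nA, 3L - nA)
  expect_equal(nrow(segment_hes(st, "ABB", min_windows = 3)), 2L)
  expect_equal(nrow(segment_hes(st, "ABB", min_windows = 4)), 0L)
})

test_that("increasing min_windows never increases segment count", {
  set.seed(12)
  nA <- sample(0:2, 120, replace = TRUE, prob = c(0.2, 0.6, 0.2))
  st <- make_states(nA, 3L - nA)
  counts <- vapply(1:6, function(m)
    nrow(segment_hes(st, "ABB", min_windows = m)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("near-complete runs are promoted to replacements", {
  nA <- c(rep(0, 29), 1)
  st <- make_states(nA, 3L - nA)
  seg <- segment_hes(st, "ABB", chrom_fraction = 0.9)
  expect_identical(seg$type, "replacement")
})

test_that("constitution summary renders nominal and replaced genomes", {
  sim <- simulate_depth(abb_config(seed = 8))
  st <- classify_windows(sim$windows, 20, "ABB")
  expect_identical(summarize_constitution(st)$summary, "3A+6B")

  mixed <- rbind(make_states(rep(0L, 6), rep(3L, 6), group = 1L),
                 make_states(rep(1L, 6), rep(2L, 6), group = 2L))
  cs <- summarize_constitution(mixed)
  expect_equal(cs$total_A, 1)
  expect_equal(cs$total_B, 5)

  # 60/40 mixture -> mode wins
  nA <- c(rep(0L, 6), rep(1L, 4))
  st3 <- make_states(nA, 3L - nA)
  expect_equal(summarize_constitution(st3)$per_group$nA, 0)
})

test_that("groups with mostly unresolved windows are excluded with a
           warning", {
  st <- make_states(rep(1L, 10), rep(2L, 10))
  st$unresolved[1:6] <- TRUE
  st$nA[1:6] <- NA
  st2 <- make_states(rep(1L, 10), rep(2L, 10), group = 2L)
  expect_warning(cs <- summarize_constitution(rbind(st, st2)), "excluded")
  expect_equal(cs$total_A, 1)
  expect_true(cs$per_group$unresolved[1])
})
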