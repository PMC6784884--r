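# Independent oracles used across the suite. Each is deliberately written
# as naive brute force, structurally unlike the package implementation.

# genetic code lookup via Biostrings (shared constant, not an algorithm)
GC_TABLE <- as.character(Biostrings::GENETIC_CODE)
names(GC_TABLE) <- names(Biostrings::GENETIC_CODE)
SENSE <- names(GC_TABLE)[GC_TABLE != "*"]

# recursive enumeration of all substitution pathways between two codons;
# returns per-pathway (syn, nonsyn, hits_stop) step counts
oracle_pathways <- function(c1, c2) {
  diff_pos <- which(charToRaw(c1) != charToRaw(c2))
  walk <- function(cur, remaining) {
    if (length(remaining) == 0L)
      return(list(c(syn = 0, nonsyn = 0, stop = 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      step_stop <- GC_TABLE[[nxt]] == "*"
      step_syn <- !step_stop && GC_TABLE[[cur]] == GC_TABLE[[nxt]]
      for (tail in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1L]] <- tail +
          c(syn = as.numeric(step_syn),
            nonsyn = as.numeric(!step_syn && !step_stop),
            stop = as.numeric(step_stop))
      }
    }
    out
  }
  walk(c1, diff_pos)
}

# pathway-averaged Sd/Nd following the NG86 convention: pathways through
# stop codons dropped, all pathways (minus stop steps) if none survive
oracle_codon_diff <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  paths <- oracle_pathways(c1, c2)
  m <- do.call(rbind, paths)
  ok <- m[, "stop"] == 0
  if (any(ok)) m <- m[ok, , drop = FALSE]
  c(sd = mean(m[, "syn"]), nd = mean(m[, "nonsyn"]))
}

# NG86 site count of one codon by direct neighbour enumeration
oracle_sites <- function(codon) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (GC_TABLE[[mut]] == "*") next
      valid <- valid + 1
      if (GC_TABLE[[mut]] == GC_TABLE[[codon]]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

# two-sided exact binomial p-value by explicit enumeration
oracle_binom_p <- function(k, n, p) {
  if (n == 0) return(1)
  obs <- choose(n, k) * p^k * (1 - p)^(n - k)
  total <- 0
  for (i in 0:n) {
    pr <- choose(n, i) * p^i * (1 - p)^(n - i)
    if (pr <= obs * (1 + 1e-9)) total <- total + pr
  }
  min(1, total)
}

# Benjamini-Hochberg step-up by the textbook recipe
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) q[i] <- min(q[i], q[i + 1])
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# run-length segments of non-nominal states by explicit scanning
oracle_segments <- function(nA, nB, nomA, nomB, min_windows) {
  segs <- list()
  i <- 1
  n <- length(nA)
  while (i <= n) {
    if (nA[i] == nomA && nB[i] == nomB) { i <- i + 1; next }
    j <- i
    while (j < n && nA[j + 1] == nA[i] && nB[j + 1] == nB[i]) j <- j + 1
    if (j - i + 1 >= min_windows)
      segs[[length(segs) + 1]] <- c(from = i, to = j, nA = nA[i],
                                    nB = nB[i])
    i <- j + 1
  }
  segs
}

# interval union length by dense position marking
oracle_union_length <- function(start, end) {
  covered <- logical(max(end))
  for (i in seq_along(start)) covered[(start[i] + 1):end[i]] <- TRUE
  sum(covered)
}

# small ABB depth configuration used by several tests
abb_config <- function(seed = 1, ...) {
  sim_config(seed = seed, constitution = "ABB", n_groups = 3,
             chrom_length = 3e6, ...)
}
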