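# Homoeologous-exchange calling from windowed unique-read depth.
#
# The caller operationalises the paired high/low coverage signature of an
# HE as a maximum-likelihood copy-state choice: for each pair of
# homoeologous windows the copy numbers (nA, nB) with nA + nB = total
# ploidy P are scored under a Poisson (or negative binomial) emission with
# means nA*d1 and nB*d1, where d1 is the per-copy depth. Runs of
# non-nominal states become HE segments; near-complete runs are promoted
# to whole-chromosome replacements.

#' Aggregate fine-grained depth records into fixed windows
#'
#' Computes the mean depth of non-overlapping windows from bedgraph-style
#' records (chrom, start, end, depth; 0-based half-open). Positions not
#' covered by any record count as depth 0 and the window is flagged as
#' containing a gap; terminal windows shorter than `window_size` are kept
#' and flagged.
#'
#' @param records data.frame with columns chrom, start, end, depth.
#' @param window_size window size in bp.
#' @param chrom_lengths optional named vector of chromosome lengths;
#'   records beyond a declared length raise an error. Defaults to the
#'   largest end coordinate per chromosome.
#' @return data.frame: chrom, start, end, depth (mean), short (flag),
#'   has_gap (flag).
#' @export
aggregate_depth <- function(records, window_size = 100e3,
                            chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(records)))
  if (window_size <= 0) stop("window_size must be positive")
  if (nrow(records) == 0L) stop("no depth records")
  if (any(records$depth < 0)) stop("negative depth")
  if (any(records$end <= records$start)) stop("malformed interval")
  out <- lapply(split(records, records$chrom), function(r) {
    chrom <- r$chrom[1]
    len <- if (!is.null(chrom_lengths)) {
      if (!chrom %in% names(chrom_lengths))
        stop("no declared length for ", chrom)
      chrom_lengths[[chrom]]
    } else max(r$end)
    if (any(r$end > len))
      stop("record beyond declared length of ", chrom)
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    depth_sum <- numeric(length(starts))
    cover <- numeric(length(starts))
    for (i in seq_len(nrow(r))) {
      w1 <- r$start[i] %/% window_size + 1L
      w2 <- (r$end[i] - 1L) %/% window_size + 1L
      for (w in w1:w2) {
        ov <- min(r$end[i], ends[w]) - max(r$start[i], starts[w])
        depth_sum[w] <- depth_sum[w] + ov * r$depth[i]
        cover[w] <- cover[w] + ov
      }
    }
    width <- ends - starts
    data.frame(chrom = chrom, start = starts, end = ends,
               depth = depth_sum / width, short = width < window_size,
               has_gap = cover < width)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# parse "A_chr01"-style names into subgenome and group columns
annotate_windows <- function(windows) {
  if (!all(c("subgenome", "group") %in% names(windows))) {
    m <- regmatches(windows$chrom,
                    regexec("^([AB])_chr([0-9]+)$", windows$chrom))
    if (any(lengths(m) != 3L))
      stop("chromosome names must follow 'A_chr01'/'B_chr01'")
    windows$subgenome <- vapply(m, `[`, "", 2L)
    windows$group <- as.integer(vapply(m, `[`, "", 3L))
  }
  windows
}

#' Estimate the unique-read depth contributed by a single chromosome copy
#'
#' Robust estimate: the median over all windows of depth divided by the
#' window's copy number under the accession's nominal constitution. The
#' median tolerates a minority of windows whose true copy number deviates
#' from the prior (homoeologous exchanges).
#'
#' @param windows depth windows with chrom (or subgenome/group), start,
#'   end, depth.
#' @param constitution nominal constitution string, e.g. "ABB".
#' @return per-copy depth estimate (scalar).
#' @export
estimate_per_copy_depth <- function(windows, constitution) {
  windows <- annotate_windows(windows)
  if (nrow(windows) < 50L) stop("need at least 50 windows")
  if (all(windows$depth == 0)) stop("all depths are zero")
  nom <- parse_constitution(constitution)
  prior <- ifelse(windows$subgenome == "A", nom[["A"]], nom[["B"]])
  if (any(prior == 0))
    stop("nominal constitution assigns zero copies to a subgenome present",
         " in the data")
  median(windows$depth / prior)
}

# Poisson / NB log-density tolerating non-integer x (densities up to a
# constant in x, which cancels across candidate states)
count_loglik <- function(x, mu, alpha) {
  if (alpha > 0) {
    size <- 1 / alpha
    lgamma(x + size) - lgamma(size) - lgamma(x + 1) +
      size * log(size / (size + mu)) + x * log(mu / (size + mu))
  } else {
    x * log(mu) - mu - lgamma(x + 1)
  }
}

#' Classify homoeologous window pairs into copy states
#'
#' For each homoeologous window pair (matched positionally by chromosome
#' group and start), chooses the copy numbers (nA, nB) with
#' nA + nB = P (total ploidy) maximising the joint count-model
#' log-likelihood of the two observed depths with means nA*d1 and nB*d1.
#' A small background term (`bg_frac * d1`) is added to every mean so that
#' zero-copy states tolerate stray reads. Windows without a partner are
#' returned with NA copy numbers and flagged unresolved.
#'
#' @param windows depth windows for both subgenomes.
#' @param d1 per-copy depth, e.g. from [estimate_per_copy_depth()].
#' @param constitution nominal constitution string (sets P = nA + nB).
#' @param dispersion negative-binomial alpha (0 = Poisson).
#' @param bg_frac background depth as a fraction of d1.
#' @return data.frame: group, start, end, depthA, depthB, nA, nB, loglik,
#'   unresolved.
#' @export
classify_windows <- function(windows, d1, constitution, dispersion = 0,
                             bg_frac = 0.01) {
  windows <- annotate_windows(windows)
  if (d1 <= 0) stop("per-copy depth must be positive")
  nom <- parse_constitution(constitution)
  P <- sum(nom)
  a <- windows[windows$subgenome == "A", ]
  b <- windows[windows$subgenome == "B", ]
  key_a <- paste(a$group, a$start)
  key_b <- paste(b$group, b$start)
  common <- intersect(key_a, key_b)
  a <- a[match(common, key_a), ]
  b <- b[match(common, key_b), ]

  states <- 0:P
  ll <- vapply(states, function(nA) {
    muA <- nA * d1 + bg_frac * d1
    muB <- (P - nA) * d1 + bg_frac * d1
    count_loglik(a$depth, muA, dispersion) +
      count_loglik(b$depth, muB, dispersion)
  }, numeric(nrow(a)))
  ll <- matrix(ll, nrow = nrow(a))
  pick <- max.col(ll, ties.method = "first")
  res <- data.frame(group = a$group, start = a$start, end = a$end,
                    depthA = a$depth, depthB = b$depth,
                    nA = states[pick], nB = P - states[pick],
                    loglik = ll[cbind(seq_len(nrow(ll)), pick)],
                    unresolved = FALSE)

  orphan_a <- windows[windows$subgenome == "A", ][!(key_a %in% common), ]
  orphan_b <- windows[windows$subgenome == "B", ][!(key_b %in% common), ]
  if (nrow(orphan_a) + nrow(orphan_b) > 0) {
    orph <- rbind(
      data.frame(group = orphan_a$group, start = orphan_a$start,
                 end = orphan_a$end, depthA = orphan_a$depth,
                 depthB = rep(NA_real_, nrow(orphan_a))),
      data.frame(group = orphan_b$group, start = orphan_b$start,
                 end = orphan_b$end, depthA = rep(NA_real_, nrow(orphan_b)),
                 depthB = orphan_b$depth))
    orph$nA <- NA_integer_; orph$nB <- NA_integer_
    orph$loglik <- NA_real_; orph$unresolved <- TRUE
    res <- rbind(res, orph)
  }
  res <- res[order(res$group, res$start), ]
  rownames(res) <- NULL
  res
}

#' Segment homoeologous exchanges from a copy-state sequence
#'
#' Maximal runs of an identical non-nominal copy state spanning at least
#' `min_windows` windows become HE segments. The direction label is
#' donor -> recipient: when nA exceeds its nominal value the A copy has
#' replaced B's slot (`A_to_B`), and conversely. Runs covering at least
#' `chrom_fraction` of a chromosome group's resolved windows are promoted
#' to whole-chromosome replacements. Unresolved windows break runs and are
#' never part of a segment.
#'
#' @param states output of [classify_windows()].
#' @param constitution nominal constitution string.
#' @param min_windows minimum run length in windows.
#' @param chrom_fraction fraction of a group's windows above which a run
#'   is a whole-chromosome replacement.
#' @return data.frame: group, start, end, nA, nB, direction, n_windows,
#'   type (segmental / replacement), mean_ratio (mean depthB/depthA with
#'   0.5 added to both for boundedness).
#' @export
segment_hes <- function(states, constitution, min_windows = 3L,
                        chrom_fraction = 0.9) {
  nom <- parse_constitution(constitution)
  if (min_windows < 1L) stop("min_windows must be >= 1")
  segs <- lapply(split(states, states$group), function(st) {
    st <- st[order(st$start), ]
    code <- ifelse(st$unresolved, "unresolved",
                   paste(st$nA, st$nB, sep = "/"))
    r <- rle(code)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nominal_code <- paste(nom[["A"]], nom[["B"]], sep = "/")
    keep <- r$values != nominal_code & r$values != "unresolved" &
      r$lengths >= min_windows
    if (!any(keep)) return(NULL)
    n_windows_group <- sum(!st$unresolved)
    do.call(rbind, lapply(which(keep), function(k) {
      i1 <- starts[k]; i2 <- ends[k]
      nA <- st$nA[i1]; nB <- st$nB[i1]
      data.frame(
        group = st$group[1], start = st$start[i1], end = st$end[i2],
        nA = nA, nB = nB,
        direction = if (nA > nom[["A"]]) "A_to_B" else "B_to_A",
        n_windows = i2 - i1 + 1L,
        type = if ((i2 - i1 + 1L) >= chrom_fraction * n_windows_group)
          "replacement" else "segmental",
        mean_ratio = mean((st$depthB[i1:i2] + 0.5) /
                            (st$depthA[i1:i2] + 0.5)))
    }))
  })
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(group = integer(), start = numeric(),
                      end = numeric(), nA = integer(), nB = integer(),
                      direction = character(), n_windows = integer(),
                      type = character(), mean_ratio = numeric())
  rownames(out) <- NULL
  out
}

#' Summarise genome constitution from window copy states
#'
#' Per chromosome group, the modal (nA, nB) over resolved windows; totals
#' are summed over groups and rendered as a summary string such as
#' "8A+25B". Groups with fewer than `min_resolved` of their windows
#' resolved are flagged and excluded from the totals with a warning.
#'
#' @param states output of [classify_windows()].
#' @param min_resolved minimum resolved-window fraction per group.
#' @return object of class `genome_constitution`: list with `per_group`
#'   (data.frame group, nA, nB, n_windows, resolved_fraction, unresolved),
#'   `total_A`, `total_B`, `summary`.
#' @export
summarize_constitution <- function(states, min_resolved = 0.5) {
  per_group <- do.call(rbind, lapply(split(states, states$group),
                                     function(st) {
    ok <- !st$unresolved
    frac <- mean(ok)
    if (sum(ok) == 0 || frac < min_resolved)
      return(data.frame(group = st$group[1], nA = NA_integer_,
                        nB = NA_integer_, n_windows = nrow(st),
                        resolved_fraction = frac, unresolved = TRUE))
    code <- paste(st$nA[ok], st$nB[ok], sep = "/")
    mode_code <- names(which.max(table(code)))
    parts <- as.integer(strsplit(mode_code, "/")[[1]])
    data.frame(group = st$group[1], nA = parts[1], nB = parts[2],
               n_windows = nrow(st), resolved_fraction = frac,
               unresolved = FALSE)
  }))
  rownames(per_group) <- NULL
  if (any(per_group$unresolved))
    warning("group(s) excluded from totals (insufficient resolved ",
            "windows): ",
            paste(per_group$group[per_group$unresolved], collapse = ", "))
  ok <- !per_group$unresolved
  res <- structure(list(per_group = per_group,
                        total_A = sum(per_group$nA[ok]),
                        total_B = sum(per_group$nB[ok]),
                        summary = sprintf("%dA+%dB",
                                          sum(per_group$nA[ok]),
                                          sum(per_group$nB[ok]))),
                   class = "genome_constitution")
  res
}

#' @export
print.genome_constitution <- function(x, ...) {
  cat("Genome constitution:", x$summary, "\n")
  cat(sprintf("  %d groups, %d unresolved\n", nrow(x$per_group),
              sum(x$per_group$unresolved)))
  invisible(x)
}
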