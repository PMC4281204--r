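# Segmentation and calling of probe-level log2ratio profiles.
#
# A profile is a numeric vector of log2ratios aligned to a probe grid
# (data.frame: probe_id, chrom, pos). Missing values are carried as NA and
# excluded from all statistics; missing probes inherit the segment of the
# nearest preceding informative probe.

#' Median-normalize a log2ratio profile
#'
#' Subtracts the median of the non-missing log2ratios so that the profile is
#' centred at zero before segmentation. Missingness is preserved.
#'
#' @param log2ratio Numeric vector of probe log2ratios (may contain `NA`).
#' @return The centred vector; its non-missing median is 0.
#' @examples
#' median_normalize(c(1, 2, 3, 4, 100))
#' @export
median_normalize <- function(log2ratio) {
  if (!is.numeric(log2ratio)) stop("'log2ratio' must be numeric")
  m <- stats::median(log2ratio, na.rm = TRUE)
  if (is.na(m)) stop("profile has no non-missing values")
  log2ratio - m
}

#' Segment one sample's log2ratio profile with circular binary segmentation
#'
#' Recursively splits each chromosome at the arc maximizing the circular
#' two-sample statistic; a split is accepted when its permutation p-value
#' (seeded, with sequential early stopping) falls below `alpha`. Adjacent
#' segments whose means differ by less than `merge_tol` are re-merged.
#'
#' @param grid Probe grid `data.frame` with columns `probe_id`, `chrom`,
#'   `pos`, sorted by (chrom, pos).
#' @param log2ratio Numeric vector aligned to `grid` (normalized; `NA`
#'   allowed).
#' @param sample_id Sample label attached to the output.
#' @param alpha Significance level for the permutation test (default 0.01).
#' @param n_perm Maximum permutations per test (default 1000).
#' @param min_width Minimum probes per segment (default 3; must be >= 2).
#' @param merge_tol Segment means closer than this are merged after the
#'   recursion (log2ratio units, default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return A `data.frame` of segments: `sample_id`, `chrom`,
#'   `start_probe`, `end_probe` (0-based, inclusive, on the full grid),
#'   `start_bp`, `end_bp` (0-based half-open: first probe position to last
#'   probe position + 1), `n_probes`, `mean_log2ratio`.
#' @seealso [mode_normalize()], [call_states()]
#' @export
cbs_segment <- function(grid, log2ratio, sample_id = "S1", alpha = 0.01,
                        n_perm = 1000L, min_width = 3L, merge_tol = 0.05,
                        seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) == length(log2ratio),
            alpha > 0, alpha < 1, min_width >= 2)
  chroms <- unique(as.character(grid$chrom))
  out <- withr::with_seed(as.integer(seed), {
    res <- lapply(chroms, function(ch) {
      idx <- which(grid$chrom == ch)
      .cbs_one_chromosome(grid$pos[idx], log2ratio[idx], ch, sample_id,
                          alpha, n_perm, min_width, merge_tol, idx[1L] - 1L)
    })
    do.call(rbind, res)
  })
  rownames(out) <- NULL
  out
}

# Segment a single chromosome. offset = 0-based index of the chromosome's
# first probe on the full grid.
.cbs_one_chromosome <- function(pos, x, chrom, sample_id, alpha, n_perm,
                                min_width, merge_tol, offset) {
  n <- length(x)
  obs <- which(!is.na(x))
  seg_local <- if (length(obs) < 2L * min_width) {
    if (length(obs) < min_width) {
      warning(sprintf("chromosome %s has fewer than min_width informative probes; single segment",
                      chrom), call. = FALSE)
    }
    cbind(1L, length(obs))
  } else {
    .cbs_recurse(x[obs], 1L, length(obs), alpha, n_perm, min_width)
  }
  if (length(obs) == 0L) {
    # all-missing chromosome: one segment with NA mean
    return(data.frame(sample_id = sample_id, chrom = chrom,
                      start_probe = offset, end_probe = offset + n - 1L,
                      start_bp = pos[1L], end_bp = pos[n] + 1,
                      n_probes = n, mean_log2ratio = NA_real_,
                      stringsAsFactors = FALSE))
  }
  seg_local <- .cbs_merge(x[obs], seg_local, merge_tol)
  # map boundaries from informative-probe space back to the full probe run:
  # a segment starts at its first informative probe, except the first segment
  # which absorbs leading missing probes; missing probes attach to the
  # preceding segment.
  k <- nrow(seg_local)
  starts <- obs[seg_local[, 1L]]
  starts[1L] <- 1L
  ends <- c(starts[-1L] - 1L, n)
  means <- vapply(seq_len(k), function(i) {
    mean(x[obs[seg_local[i, 1L]:seg_local[i, 2L]]])
  }, numeric(1))
  data.frame(sample_id = sample_id, chrom = chrom,
             start_probe = offset + starts - 1L,
             end_probe = offset + ends - 1L,
             start_bp = pos[starts], end_bp = pos[ends] + 1,
             n_probes = ends - starts + 1L,
             mean_log2ratio = means, stringsAsFactors = FALSE)
}

# Recursive splitting on the informative values x[lo:hi] (1-based, inclusive).
# Returns a matrix of (start, end) index pairs in informative space.
.cbs_recurse <- function(x, lo, hi, alpha, n_perm, min_width) {
  n <- hi - lo + 1L
  if (n < 2L * min_width) return(cbind(lo, hi))
  t <- .cbs_split_test(x[lo:hi], as.integer(min_width), as.integer(n_perm),
                       alpha)
  if (t$p >= alpha) return(cbind(lo, hi))
  i <- t$i  # arc is (i, j] in 0-based local coordinates
  j <- t$j
  pieces <- list()
  if (i > 0L) pieces <- c(pieces, list(c(lo, lo + i - 1L)))
  pieces <- c(pieces, list(c(lo + i, lo + j - 1L)))
  if (j < n) pieces <- c(pieces, list(c(lo + j, hi)))
  if (length(pieces) == 1L) return(cbind(lo, hi))
  do.call(rbind, lapply(pieces, function(p) {
    .cbs_recurse(x, p[1L], p[2L], alpha, n_perm, min_width)
  }))
}

# Iteratively merge adjacent segments whose means differ by < tol
# (closest pair first).
.cbs_merge <- function(x, seg, tol) {
  repeat {
    k <- nrow(seg)
    if (k < 2L) return(seg)
    means <- vapply(seq_len(k), function(i) mean(x[seg[i, 1L]:seg[i, 2L]]),
                    numeric(1))
    d <- abs(diff(means))
    if (!any(d < tol)) return(seg)
    i <- which.min(d)
    seg[i, 2L] <- seg[i + 1L, 2L]
    seg <- seg[-(i + 1L), , drop = FALSE]
  }
}

#' Mode-normalize segmented log2ratios
#'
#' Recentres a sample so that its most common segment level — the modal copy
#' number, assumed diploid — sits at log2ratio 0. The mode is the peak of a
#' Gaussian kernel density over segment means weighted by probes per segment;
#' when several peaks tie (within 1e-8 relative density) the one closest to
#' zero wins.
#'
#' @param segments Segment `data.frame` from [cbs_segment()].
#' @param bandwidth Kernel bandwidth in log2ratio units (default 0.1).
#' @return `segments` with shifted `mean_log2ratio`; the shift applied is
#'   attached as `attr(, "shift")` so callers can recentre the underlying
#'   probe-level profile too.
#' @export
mode_normalize <- function(segments, bandwidth = 0.1) {
  stopifnot(nrow(segments) >= 1L, bandwidth > 0)
  ok <- !is.na(segments$mean_log2ratio)
  m <- segments$mean_log2ratio[ok]
  w <- segments$n_probes[ok]
  if (length(m) == 0L) stop("no informative segments")
  shift <- .weighted_kde_mode(m, w / sum(w), bandwidth)
  segments$mean_log2ratio <- segments$mean_log2ratio - shift
  attr(segments, "shift") <- shift
  segments
}

# Mode of sum_i w_i * dnorm(x, m_i, bw): coarse translation-covariant grid,
# then Newton refinement on the exact mixture (machine-precision peak, so a
# second normalization pass is the identity). Ties broken toward zero.
.weighted_kde_mode <- function(m, w, bw) {
  f <- function(x) {
    vapply(x, function(xi) sum(w * stats::dnorm(xi, mean = m, sd = bw)),
           numeric(1))
  }
  grid <- seq(min(m) - 3 * bw, max(m) + 3 * bw, length.out = 512L)
  dens <- f(grid)
  peak_at <- function(g) {
    x <- g
    for (it in 1:60) {
      phi <- stats::dnorm(x, m, bw)
      d1 <- sum(w * (m - x) / bw^2 * phi)
      d2 <- sum(w * (((m - x)^2 - bw^2) / bw^4) * phi)
      if (!is.finite(d1) || !is.finite(d2) || d2 >= 0) break
      xn <- x - d1 / d2
      if (abs(xn - x) < 1e-14) {
        x <- xn
        break
      }
      x <- xn
    }
    c(x, f(x))
  }
  # local maxima on the grid near the global max, refined exactly
  dmax <- max(dens)
  is_peak <- dens >= c(-Inf, dens[-length(dens)]) &
    dens >= c(dens[-1L], -Inf) & dens > dmax - 1e-6 * dmax
  cand <- t(vapply(grid[is_peak], peak_at, numeric(2)))
  best <- max(cand[, 2L])
  cand <- cand[cand[, 2L] >= best * (1 - 1e-8), , drop = FALSE]
  cand[which.min(abs(cand[, 1L])), 1L]
}

#' Call gain/neutral/loss states on segments
#'
#' Thresholds are inclusive: a segment is a loss when its mean is at or below
#' `loss_threshold` and a gain when at or above `gain_threshold`.
#'
#' @param segments Segment `data.frame` (typically mode-normalized).
#' @param loss_threshold,gain_threshold Calling thresholds in log2ratio
#'   units; `loss_threshold < 0 < gain_threshold`.
#' @return `segments` with a `state` column in `{"loss","neutral","gain"}`.
#'   Segments with missing means are called neutral.
#' @export
call_states <- function(segments, loss_threshold = -0.2,
                        gain_threshold = 0.2) {
  stopifnot(loss_threshold < 0, gain_threshold > 0)
  m <- segments$mean_log2ratio
  state <- rep("neutral", nrow(segments))
  state[!is.na(m) & m <= loss_threshold] <- "loss"
  state[!is.na(m) & m >= gain_threshold] <- "gain"
  segments$state <- state
  segments
}
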