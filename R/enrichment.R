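# Census-gene enrichment and between-cohort aberration-frequency comparison.

#' Hypergeometric enrichment of a gene set in a driver census
#'
#' Analytic p-value is the upper hypergeometric tail
#' `P(X >= n_overlap)` for drawing `n_query` genes from the universe; an
#' optional seeded permutation test redraws same-size gene sets and applies
#' the (+1)/(+1) correction.
#'
#' @param query_genes Genes of interest (must lie in the universe).
#' @param census_genes Census list (intersected with the universe).
#' @param universe_genes All genes eligible for selection.
#' @param n_perm Number of permutations (0 = analytic only).
#' @param seed Integer seed for the permutation draw.
#' @return List of class `enrichment_result`: `n_universe`,
#'   `n_census_in_universe`, `n_query`, `n_overlap`, `p_value`,
#'   `p_permutation` (or `NA`).
#' @export
census_enrichment <- function(query_genes, census_genes, universe_genes,
                              n_perm = 0L, seed = 1L) {
  universe <- unique(universe_genes)
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  query <- unique(query_genes)
  if (!all(query %in% universe)) {
    stop("query genes must be a subset of the universe", call. = FALSE)
  }
  census <- intersect(unique(census_genes), universe)
  k <- length(intersect(query, census))
  N <- length(universe)
  K <- length(census)
  n <- length(query)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0L) {
    exceed <- withr::with_seed(as.integer(seed), {
      sum(vapply(seq_len(n_perm), function(i) {
        length(intersect(sample(universe, n), census)) >= k
      }, logical(1)))
    })
    p_perm <- (exceed + 1) / (n_perm + 1)
  }
  structure(list(n_universe = N, n_census_in_universe = K, n_query = n,
                 n_overlap = k, p_value = p, p_permutation = p_perm),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Census enrichment (hypergeometric upper tail)\n")
  cat(sprintf("  universe %d, census-in-universe %d, query %d, overlap %d\n",
              x$n_universe, x$n_census_in_universe, x$n_query, x$n_overlap))
  cat(sprintf("  p = %.4g", x$p_value))
  if (!is.na(x$p_permutation)) cat(sprintf(" (permutation p = %.4g)",
                                           x$p_permutation))
  cat("\n")
  invisible(x)
}

#' Remap two cohorts' call tracks onto a shared bin grid
#'
#' Shared bins are the intersection intervals of all state boundaries from
#' both cohorts; each sample's state propagates to every bin its source
#' interval covers. Bins not covered by every sample of both cohorts are
#' dropped.
#'
#' @param calls_a,calls_b Call tracks: `data.frame`s with `sample_id`,
#'   `chrom`, `start_bp`, `end_bp` (half-open tilings) and `state`.
#' @return List with `bins` (`chrom`, `start_bp`, `end_bp`), and `states_a`,
#'   `states_b` (character matrices, bins x samples).
#' @export
remap_to_common_grid <- function(calls_a, calls_b) {
  chroms <- intersect(unique(calls_a$chrom), unique(calls_b$chrom))
  if (length(chroms) == 0L) {
    stop("cohorts share no chromosomes", call. = FALSE)
  }
  samples_a <- unique(calls_a$sample_id)
  samples_b <- unique(calls_b$sample_id)
  bins <- list()
  sa <- list()
  sb <- list()
  for (ch in chroms) {
    a <- calls_a[calls_a$chrom == ch, , drop = FALSE]
    b <- calls_b[calls_b$chrom == ch, , drop = FALSE]
    bounds <- sort(unique(c(a$start_bp, a$end_bp, b$start_bp, b$end_bp)))
    if (length(bounds) < 2L) next
    bs <- bounds[-length(bounds)]
    be <- bounds[-1L]
    state_of <- function(track, samp, pos) {
      t <- track[track$sample_id == samp, , drop = FALSE]
      idx <- findInterval(pos, t$start_bp)
      ok <- idx >= 1L & idx <= nrow(t)
      st <- rep(NA_character_, length(pos))
      sel <- which(ok)
      sel <- sel[pos[sel] < t$end_bp[idx[sel]]]
      st[sel] <- t$state[idx[sel]]
      st
    }
    mid <- (bs + be) / 2
    ma <- vapply(samples_a, function(s) state_of(a[order(a$start_bp), ], s, mid),
                 character(length(mid)))
    mb <- vapply(samples_b, function(s) state_of(b[order(b$start_bp), ], s, mid),
                 character(length(mid)))
    ma <- matrix(ma, nrow = length(mid), dimnames = list(NULL, samples_a))
    mb <- matrix(mb, nrow = length(mid), dimnames = list(NULL, samples_b))
    keep <- stats::complete.cases(ma) & stats::complete.cases(mb)
    if (!any(keep)) next
    bins[[ch]] <- data.frame(chrom = ch, start_bp = bs[keep],
                             end_bp = be[keep], stringsAsFactors = FALSE)
    sa[[ch]] <- ma[keep, , drop = FALSE]
    sb[[ch]] <- mb[keep, , drop = FALSE]
  }
  if (!length(bins)) stop("no commonly covered bins", call. = FALSE)
  list(bins = do.call(rbind, c(bins, list(make.row.names = FALSE))),
       states_a = do.call(rbind, sa), states_b = do.call(rbind, sb))
}

.state_score <- function(m) {
  s <- matrix(0L, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  s[m == "loss"] <- -1L
  s[m == "gain"] <- 1L
  s
}

#' Compare aberration frequencies between two cohorts
#'
#' After remapping to a common bin grid, each bin's per-sample ordinal state
#' scores (loss = -1, neutral = 0, gain = +1) are compared with a rank-sum
#' test with ties (normal approximation, or a seeded label-permutation test
#' when `n_perm > 0`); q-values are Benjamini-Hochberg.
#'
#' @param calls_a,calls_b Call tracks (see [remap_to_common_grid()]), each
#'   with >= 2 samples.
#' @param n_perm Permutations per bin (0 = analytic rank-sum).
#' @param seed Integer seed for permutations.
#' @param fdr_q FDR level used to flag differing bins (default 0.05).
#' @return `data.frame`: per bin `chrom`, `start_bp`, `end_bp`, `freq_a`,
#'   `freq_b` (fraction of aberrant, i.e. non-neutral, samples), `p`, `q`,
#'   `differs`.
#' @export
compare_cohorts <- function(calls_a, calls_b, n_perm = 0L, seed = 1L,
                            fdr_q = 0.05) {
  stopifnot(length(unique(calls_a$sample_id)) >= 2,
            length(unique(calls_b$sample_id)) >= 2)
  rm <- remap_to_common_grid(calls_a, calls_b)
  A <- .state_score(rm$states_a)
  B <- .state_score(rm$states_b)
  nb <- nrow(rm$bins)
  p <- numeric(nb)
  analytic_p <- function(a, b) {
    if (stats::var(c(a, b)) == 0) return(1)
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
  }
  if (n_perm > 0L) {
    p <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(nb), function(i) {
        a <- A[i, ]
        b <- B[i, ]
        pooled <- c(a, b)
        if (stats::var(pooled) == 0) return(1)
        obs <- abs(mean(a) - mean(b))
        na <- length(a)
        exceed <- sum(vapply(seq_len(n_perm), function(k) {
          perm <- sample(pooled)
          abs(mean(perm[seq_len(na)]) - mean(perm[-seq_len(na)])) >= obs - 1e-12
        }, logical(1)))
        (exceed + 1) / (n_perm + 1)
      }, numeric(1))
    })
  } else {
    p <- vapply(seq_len(nb), function(i) analytic_p(A[i, ], B[i, ]),
                numeric(1))
  }
  q <- stats::p.adjust(p, method = "BH")
  data.frame(rm$bins,
             freq_a = rowMeans(A != 0L), freq_b = rowMeans(B != 0L),
             p = p, q = q, differs = q < fdr_q,
             stringsAsFactors = FALSE)
}
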