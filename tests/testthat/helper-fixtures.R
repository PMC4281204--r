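# Shared builders and independent brute-force oracles.

# Uniform probe grid on one or more chromosomes.
mini_grid <- function(n, chrom = "chr1", spacing = 10000) {
  do.call(rbind, lapply(chrom, function(ch) {
    data.frame(probe_id = sprintf("%s_p%04d", ch, seq_len(n)), chrom = ch,
               pos = spacing * seq_len(n) - spacing / 2,
               stringsAsFactors = FALSE)
  }))
}

# Called-segment rows for filter tests (only the fields the filters read).
seg_calls <- function(sample_id, chrom, start_bp, end_bp, state) {
  data.frame(sample_id = sample_id, chrom = chrom, start_bp = start_bp,
             end_bp = end_bp, state = state, stringsAsFactors = FALSE)
}

# Aberration rows built directly.
make_ab <- function(sample_id, chrom, start_bp, end_bp, direction,
                    focal_limit = 3e6) {
  df <- data.frame(sample_id = sample_id, chrom = chrom, start_bp = start_bp,
                   end_bp = end_bp, direction = direction,
                   stringsAsFactors = FALSE)
  df$size_bp <- df$end_bp - df$start_bp
  df$focal <- df$size_bp <= focal_limit
  df
}

# Independent per-base depth oracle: distinct-sample coverage depth over
# small 0-based half-open intervals; leftmost maximal run.
brute_depth_run <- function(df) {
  stopifnot(length(unique(df$chrom)) == 1L)
  maxpos <- max(df$end_bp)
  depth <- integer(maxpos)
  for (s in unique(df$sample_id)) {
    cov <- logical(maxpos)
    d <- df[df$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      cov[(d$start_bp[i] + 1):d$end_bp[i]] <- TRUE
    }
    depth <- depth + cov
  }
  m <- max(depth)
  r <- rle(depth == m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)[1L]
  list(start_bp = starts[i] - 1L, end_bp = ends[i], depth = m)
}

# Exhaustive circular-split oracle: best (i, j) arc over all pairs with the
# same statistic the segmenter maximizes (plain R double loop).
brute_best_arc <- function(x, min_width = 3L) {
  n <- length(x)
  S <- c(0, cumsum(x))
  best <- -1
  bi <- 0L
  bj <- n
  for (l in min_width:(n - min_width)) {
    den <- sqrt(l * (n - l) / n)
    for (i in 0:(n - l)) {
      d <- abs(S[i + l + 1] - S[i + 1] - l / n * S[n + 1]) / den
      if (d > best) {
        best <- d
        bi <- i
        bj <- i + l
      }
    }
  }
  list(stat = best, i = bi, j = bj)
}

# Small genome that satisfies the generator's placement margins quickly.
small_spec <- function(n_chrom = 2, length_bp = 40e6, spacing = 200000,
                       n_genes = 40, n_loci = 2) {
  genome_spec(chromosomes = data.frame(name = paste0("chr", seq_len(n_chrom)),
                                       length_bp = rep(length_bp, n_chrom)),
              probe_spacing_bp = spacing, n_genes = n_genes,
              n_polymorphic_loci = n_loci)
}

# Fast pipeline config for end-to-end tests.
fast_config <- function(out_dir, seed, ...) {
  pipeline_config(out_dir = out_dir, seed = seed,
                  cbs = list(alpha = 0.01, n_perm = 200L, min_width = 3L,
                             merge_tol = 0.05), ...)
}

fixture_path <- function(name) {
  system.file("extdata", name, package = "focalCNA", mustWork = TRUE)
}

# Random per-sample call tracks on a shared bin tiling.
mk_calls <- function(n_samp, n_bins, prefix, seed, probs = c(.25, .5, .25),
                     bin_bp = 1e5) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_samp), function(s) {
      st <- sample(c("loss", "neutral", "gain"), n_bins, TRUE, probs)
      data.frame(sample_id = paste0(prefix, s), chrom = "chr1",
                 start_bp = (seq_len(n_bins) - 1) * bin_bp,
                 end_bp = seq_len(n_bins) * bin_bp, state = st,
                 stringsAsFactors = FALSE)
    }))
  })
}

# sample() treats a length-1 numeric vector as 1:n; pick explicitly
pick1 <- function(x) x[sample.int(length(x), 1L)]
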