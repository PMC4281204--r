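# Internal helpers shared across modules.
#
# All genomic intervals inside the package are 0-based half-open [start, end)
# on the bp scale (BED convention). GenomicRanges/IRanges are 1-based closed,
# so conversion happens at the boundary of every call into those packages.

# data.frame with chrom/start_bp/end_bp -> GRanges (1-based closed)
.as_granges <- function(df, ...) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start_bp + 1L, end = df$end_bp),
    ...
  )
}

# GRanges -> 0-based half-open columns
.granges_coords <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = GenomicRanges::start(gr) - 1,
    end_bp = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Single-linkage overlap clusters (>= 1 bp, strict overlap; bp-adjacent
# intervals do NOT cluster). Returns an integer cluster id per row of df.
.overlap_clusters <- function(df) {
  if (nrow(df) == 0L) return(integer(0))
  gr <- .as_granges(df)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  ids <- integer(nrow(df))
  ids[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  ids
}

.stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

#' Analysis thresholds for focal-CNA driver nomination
#'
#' Bundles the tunable cut-offs of the pipeline: the fold-change bounds that
#' define under-/overexpression, the minimum frequency of involvement for a
#' candidate driver, the focal size limit, the recurrence minimum, the FDR
#' level for cohort comparisons, and the log2ratio calling thresholds.
#'
#' @param fc_under Fold-change at or below which a loss-direction gene counts
#'   as underexpressed (linear scale, default 0.75).
#' @param fc_over Fold-change at or above which a gain-direction gene counts
#'   as overexpressed (default 1.5).
#' @param freq_min Minimum fraction of tumors with concordant aberrant
#'   expression for a gene to be nominated (default 0.35).
#' @param focal_limit_bp Upper size limit, inclusive, for a focal aberration
#'   in bp (default 3,000,000).
#' @param recurrence_min Minimum number of distinct samples for an aberration
#'   locus to count as recurrent (default 2).
#' @param fdr_q Benjamini-Hochberg q-value cut-off for cohort comparisons
#'   (default 0.05).
#' @param loss_threshold,gain_threshold Segment-mean log2ratio calling
#'   thresholds (inclusive; defaults -0.2 / +0.2).
#' @param strict_fc If `TRUE`, fold-change comparisons are strict (`<`/`>`)
#'   instead of the default inclusive (`<=`/`>=`).
#' @return A list of class `cna_thresholds`.
#' @examples
#' th <- cna_thresholds()
#' th$fc_under
#' @export
cna_thresholds <- function(fc_under = 0.75, fc_over = 1.5, freq_min = 0.35,
                           focal_limit_bp = 3e6, recurrence_min = 2L,
                           fdr_q = 0.05, loss_threshold = -0.2,
                           gain_threshold = 0.2, strict_fc = FALSE) {
  stopifnot(
    fc_under > 0, fc_under < 1, fc_over > 1,
    freq_min > 0, freq_min <= 1,
    focal_limit_bp > 0, recurrence_min >= 1,
    fdr_q > 0, fdr_q < 1,
    loss_threshold < 0, gain_threshold > 0,
    is.logical(strict_fc), length(strict_fc) == 1L
  )
  structure(
    list(fc_under = fc_under, fc_over = fc_over, freq_min = freq_min,
         focal_limit_bp = focal_limit_bp,
         recurrence_min = as.integer(recurrence_min), fdr_q = fdr_q,
         loss_threshold = loss_threshold, gain_threshold = gain_threshold,
         strict_fc = strict_fc),
    class = "cna_thresholds"
  )
}

#' @export
print.cna_thresholds <- function(x, ...) {
  cat("Focal-CNA analysis thresholds\n")
  cat(sprintf("  fold change:  underexpressed %s %.3g, overexpressed %s %.3g\n",
              if (x$strict_fc) "<" else "<=", x$fc_under,
              if (x$strict_fc) ">" else ">=", x$fc_over))
  cat(sprintf("  frequency of involvement: >= %.0f%%\n", 100 * x$freq_min))
  cat(sprintf("  focal size limit: %s bp (inclusive)\n",
              format(x$focal_limit_bp, big.mark = ",")))
  cat(sprintf("  recurrence: >= %d samples; FDR q < %.3g\n",
              x$recurrence_min, x$fdr_q))
  cat(sprintf("  calling: loss <= %.3g, gain >= %.3g (log2ratio)\n",
              x$loss_threshold, x$gain_threshold))
  invisible(x)
}
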