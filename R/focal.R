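# Focal aberration extraction, germline-CNV filtering, and high-frequency
# region (HFR) computation.
#
# An aberration is a maximal run of adjacent same-state non-neutral segments
# in one sample (0-based half-open bp interval). The focal flag marks
# aberrations at or under the focal size limit. Germline CNVs are removed in
# two steps: (1) focal aberrations sufficiently covered by the CNV catalog,
# (2) overlap clusters of focal aberrations showing both recurrent gains and
# recurrent losses. The HFR of a recurrent cluster is the smallest genomic
# interval where the per-base count of distinct focally aberrant samples
# attains the cluster maximum.

#' Extract per-sample aberrations from called segments
#'
#' @param calls Segment `data.frame` with a `state` column (from
#'   [call_states()]), segments tiling each sample/chromosome in order.
#' @param focal_limit_bp Inclusive focal size limit in bp (default 3 Mb:
#'   aberrations of 3 Mb and smaller are focal).
#' @return `data.frame` with `sample_id`, `chrom`, `start_bp`, `end_bp`
#'   (half-open), `direction` (`"gain"`/`"loss"`), `size_bp`, `focal`.
#' @export
extract_aberrations <- function(calls, focal_limit_bp = 3e6) {
  stopifnot(is.data.frame(calls), "state" %in% names(calls))
  out <- list()
  for (key in split(seq_len(nrow(calls)),
                    list(calls$sample_id, calls$chrom), drop = TRUE)) {
    key <- key[order(calls$start_bp[key])]
    st <- calls$state[key]
    r <- rle(st)
    endi <- cumsum(r$lengths)
    starti <- endi - r$lengths + 1L
    for (k in which(r$values != "neutral")) {
      rows <- key[starti[k]:endi[k]]
      out[[length(out) + 1L]] <- data.frame(
        sample_id = calls$sample_id[rows[1L]],
        chrom = calls$chrom[rows[1L]],
        start_bp = min(calls$start_bp[rows]),
        end_bp = max(calls$end_bp[rows]),
        direction = r$values[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      direction = character(0), size_bp = numeric(0),
                      focal = logical(0), stringsAsFactors = FALSE))
  }
  ab <- do.call(rbind, out)
  ab$size_bp <- ab$end_bp - ab$start_bp
  ab$focal <- ab$size_bp <= focal_limit_bp
  rownames(ab) <- NULL
  ab[order(ab$chrom, ab$start_bp, ab$sample_id), , drop = FALSE]
}

#' Remove focal aberrations overlapping the germline-CNV catalog (rule 1)
#'
#' A focal aberration is removed when the union of catalog intervals covers
#' at least `min_covered_fraction` of its length. Non-focal aberrations are
#' never removed by this rule.
#'
#' @param aberrations Aberration `data.frame` from [extract_aberrations()].
#' @param catalog CNV catalog `data.frame` (`chrom`, `start_bp`, `end_bp`).
#' @param min_covered_fraction Coverage fraction triggering removal
#'   (default 0.5).
#' @return List with `kept` and `removed` (a partition of the input).
#' @export
filter_catalog_overlap <- function(aberrations, catalog,
                                   min_covered_fraction = 0.5) {
  stopifnot(min_covered_fraction >= 0, min_covered_fraction <= 1)
  if (nrow(aberrations) == 0L || nrow(catalog) == 0L) {
    return(list(kept = aberrations, removed = aberrations[0, , drop = FALSE]))
  }
  o <- order(catalog$chrom, catalog$start_bp)
  if (!identical(o, seq_len(nrow(catalog)))) {
    warning("CNV catalog was not sorted; sorting internally", call. = FALSE)
    catalog <- catalog[o, , drop = FALSE]
  }
  cat_gr <- GenomicRanges::reduce(.as_granges(catalog))
  ab_gr <- .as_granges(aberrations)
  hits <- GenomicRanges::findOverlaps(ab_gr, cat_gr)
  covered <- rep(0, nrow(aberrations))
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(ab_gr[S4Vectors::queryHits(hits)],
                                    cat_gr[S4Vectors::subjectHits(hits)])
    w <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(w))] <- w
  }
  frac <- covered / aberrations$size_bp
  removed <- aberrations$focal & frac >= min_covered_fraction
  list(kept = aberrations[!removed, , drop = FALSE],
       removed = aberrations[removed, , drop = FALSE])
}

#' Remove bidirectional focal clusters (rule 2)
#'
#' Focal aberrations (both directions pooled) are clustered by single-linkage
#' genomic overlap (>= 1 bp). A cluster is removed in full when it contains
#' focal gains from at least `recurrence_min` distinct samples AND focal
#' losses from at least `recurrence_min` distinct samples — the signature of
#' a polymorphic germline locus rather than a selected somatic event.
#'
#' @param aberrations Catalog-filtered aberration `data.frame`.
#' @param recurrence_min Recurrence threshold per direction (default 2).
#' @return List with `kept` and `removed`.
#' @export
filter_bidirectional <- function(aberrations, recurrence_min = 2L) {
  foc <- which(aberrations$focal)
  if (!length(foc)) {
    return(list(kept = aberrations, removed = aberrations[0, , drop = FALSE]))
  }
  cl <- .overlap_clusters(aberrations[foc, , drop = FALSE])
  removed_idx <- integer(0)
  for (id in unique(cl)) {
    rows <- foc[cl == id]
    n_gain <- length(unique(aberrations$sample_id[
      rows[aberrations$direction[rows] == "gain"]]))
    n_loss <- length(unique(aberrations$sample_id[
      rows[aberrations$direction[rows] == "loss"]]))
    if (n_gain >= recurrence_min && n_loss >= recurrence_min) {
      removed_idx <- c(removed_idx, rows)
    }
  }
  sel <- seq_len(nrow(aberrations)) %in% removed_idx
  list(kept = aberrations[!sel, , drop = FALSE],
       removed = aberrations[sel, , drop = FALSE])
}

#' Compute high-frequency regions from filtered focal aberrations
#'
#' Per direction, overlapping focal aberrations are clustered by
#' single-linkage (>= 1 bp). Within a cluster the HFR is the maximal
#' contiguous genomic run attaining the cluster's maximum per-base count of
#' distinct focally aberrant samples (the smallest genomic overlap); if
#' several disjoint runs tie, the leftmost is taken. Clusters whose maximum
#' count falls below `recurrence_min` yield no HFR.
#'
#' @param aberrations Filtered aberration `data.frame`; only focal rows are
#'   used.
#' @param recurrence_min Minimum distinct focal samples (default 2).
#' @return `data.frame` of class `hfr_set`: `chrom`, `start_bp`, `end_bp`,
#'   `direction`, `focal_count`, `total_count` (initialized to
#'   `focal_count`; see [count_total()]), plus a `members` list-column of
#'   member aberration row indices into `aberrations`.
#' @export
compute_hfrs <- function(aberrations, recurrence_min = 2L) {
  empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), direction = character(0),
                      focal_count = integer(0), total_count = integer(0),
                      stringsAsFactors = FALSE)
  empty$members <- list()
  class(empty) <- c("hfr_set", "data.frame")
  foc <- which(aberrations$focal)
  if (!length(foc)) return(empty)
  out <- list()
  for (dir in c("gain", "loss")) {
    rows <- foc[aberrations$direction[foc] == dir]
    if (!length(rows)) next
    cl <- .overlap_clusters(aberrations[rows, , drop = FALSE])
    for (id in unique(cl)) {
      mem <- rows[cl == id]
      if (length(unique(aberrations$sample_id[mem])) < recurrence_min) next
      hfr <- .max_depth_run(aberrations[mem, , drop = FALSE])
      if (hfr$depth < recurrence_min) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = aberrations$chrom[mem[1L]], start_bp = hfr$start_bp,
        end_bp = hfr$end_bp, direction = dir,
        focal_count = hfr$depth, total_count = hfr$depth,
        members = I(list(mem)), stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("hfr_set", "data.frame")
  res
}

# Leftmost maximal contiguous run of maximum per-base distinct-sample depth
# over a set of same-chromosome intervals.
.max_depth_run <- function(df) {
  # distinct samples: collapse each sample's intervals first
  per_sample <- lapply(split(df, df$sample_id), function(d) {
    GenomicRanges::reduce(.as_granges(d))
  })
  gr <- do.call(c, unname(per_sample))
  cov <- GenomicRanges::coverage(gr)[[as.character(df$chrom[1L])]]
  depth <- max(S4Vectors::runValue(cov))
  runs <- IRanges::IRanges(cov >= depth)  # TRUE runs of maximal depth
  list(start_bp = IRanges::start(runs)[1L] - 1,
       end_bp = IRanges::end(runs)[1L],
       depth = as.integer(depth))
}

#' Count samples containing each HFR (focal or broad)
#'
#' Sets `total_count` to the number of distinct samples having any
#' same-direction aberration — regardless of size — whose interval fully
#' covers the HFR.
#'
#' @param hfrs An `hfr_set` from [compute_hfrs()].
#' @param aberrations All aberrations (including non-focal), typically the
#'   unfiltered output of [extract_aberrations()].
#' @return `hfrs` with updated `total_count`.
#' @export
count_total <- function(hfrs, aberrations) {
  if (nrow(hfrs) == 0L) return(hfrs)
  ab_gr <- .as_granges(aberrations)
  hfr_gr <- .as_granges(hfrs)
  hits <- GenomicRanges::findOverlaps(hfr_gr, ab_gr, type = "within")
  for (i in seq_len(nrow(hfrs))) {
    j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    j <- j[aberrations$direction[j] == hfrs$direction[i]]
    hfrs$total_count[i] <- length(unique(aberrations$sample_id[j]))
  }
  hfrs
}

#' Filter ledger: bookkeeping of the two germline-CNV removal rules
#'
#' @param n_recurrent_observed Recurrent focal aberrations observed.
#' @param n_removed_catalog Removed by catalog overlap (rule 1).
#' @param n_removed_bidirectional Removed by bidirectionality (rule 2).
#' @return List of class `filter_ledger` with the retained count
#'   `n_retained = observed - catalog - bidirectional` (must be
#'   non-negative).
#' @examples
#' make_ledger(550, 266, 145)$n_retained  # 139
#' @export
make_ledger <- function(n_recurrent_observed, n_removed_catalog,
                        n_removed_bidirectional) {
  counts <- c(n_recurrent_observed, n_removed_catalog,
              n_removed_bidirectional)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("ledger counts must be non-negative integers", call. = FALSE)
  }
  retained <- n_recurrent_observed - n_removed_catalog -
    n_removed_bidirectional
  if (retained < 0) {
    stop("inconsistent ledger: more removals than observations",
         call. = FALSE)
  }
  structure(list(n_recurrent_observed = as.integer(n_recurrent_observed),
                 n_removed_catalog = as.integer(n_removed_catalog),
                 n_removed_bidirectional = as.integer(n_removed_bidirectional),
                 n_retained = as.integer(retained)),
            class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("Germline-CNV filter ledger\n")
  cat(sprintf("  recurrent observed:      %d\n", x$n_recurrent_observed))
  cat(sprintf("  removed (catalog):       %d\n", x$n_removed_catalog))
  cat(sprintf("  removed (bidirectional): %d\n", x$n_removed_bidirectional))
  cat(sprintf("  retained:                %d\n", x$n_retained))
  invisible(x)
}
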