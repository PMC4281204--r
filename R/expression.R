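# Expression normalization, fold changes against a reference profile,
# concordant aberrant-expression flagging, candidate selection at the
# frequency-of-involvement rule, and confirmation in an independent set.

#' Normalize tumor expression against a reference profile
#'
#' Per sample, log2ratios (tumor intensity vs mean reference intensity) are
#' corrected for intensity-dependent trend by local regression of the
#' log2ratio on the average log2 intensity (loess, via `limma::loessFit`),
#' then quantile normalization (`limma::normalizeQuantiles`) equalizes the
#' per-sample distributions.
#'
#' @param tumors Linear-intensity matrix (genes/probes x samples, >= 2
#'   samples).
#' @param reference Linear-intensity matrix sharing the row set (>= 10
#'   shared rows).
#' @param span Loess span (default 0.3).
#' @return Matrix of normalized log2ratios (shared rows x tumor samples).
#' @export
normalize_expression <- function(tumors, reference, span = 0.3) {
  stopifnot(is.matrix(tumors), is.matrix(reference), ncol(tumors) >= 2)
  if (any(tumors <= 0, na.rm = TRUE) || any(reference <= 0, na.rm = TRUE)) {
    stop("non-positive intensities: matrices must be on the linear scale",
         call. = FALSE)
  }
  shared <- intersect(rownames(tumors), rownames(reference))
  if (length(shared) < 10L) {
    stop("fewer than 10 shared rows: local regression undefined",
         call. = FALSE)
  }
  tum <- log2(tumors[shared, , drop = FALSE])
  ref <- log2(rowMeans(reference[shared, , drop = FALSE]))
  M <- tum - ref
  A <- (tum + ref) / 2
  for (s in seq_len(ncol(M))) {
    fit <- limma::loessFit(M[, s], A[, s], span = span)
    M[, s] <- M[, s] - fit$fitted
  }
  M <- limma::normalizeQuantiles(M)
  dimnames(M) <- list(shared, colnames(tumors))
  attr(M, "scale") <- "log2ratio"
  M
}

#' Fold changes of tumor expression relative to the reference profile
#'
#' `FC(gene, tumor) = tumor intensity / mean reference intensity` on the
#' linear scale, optionally after loess + quantile normalization (in which
#' case `FC = 2^normalized log2ratio`). With a probe-to-gene map, multiple
#' probes per gene collapse to the probe with the highest mean intensity
#' across all samples. Query genes without a probe are reported as
#' no-information rows (`NA`), never dropped silently.
#'
#' @param tumors,reference Linear-intensity matrices (rows shared).
#' @param probe_map Optional `data.frame` with columns `probe`, `gene`
#'   mapping matrix rows to gene symbols; `NULL` when rows already are
#'   genes.
#' @param genes Optional character vector restricting (and ordering) the
#'   output rows; genes absent from the platform yield `NA` rows.
#' @param normalize If `TRUE`, apply [normalize_expression()] first
#'   (default `FALSE`: plain intensity ratios).
#' @param span Loess span passed through when normalizing.
#' @return Matrix of class `fold_change_table` (linear-scale positive
#'   values, `NA` for no-information genes) with attribute `informative`
#'   (character vector of genes with a usable probe).
#' @export
compute_fold_changes <- function(tumors, reference, probe_map = NULL,
                                 genes = NULL, normalize = FALSE,
                                 span = 0.3) {
  stopifnot(is.matrix(tumors), is.matrix(reference), ncol(reference) >= 1)
  if (any(tumors <= 0, na.rm = TRUE) || any(reference <= 0, na.rm = TRUE)) {
    stop("non-positive intensities: matrices must be on the linear scale",
         call. = FALSE)
  }
  shared <- intersect(rownames(tumors), rownames(reference))
  if (length(shared) == 0L) stop("no shared rows", call. = FALSE)
  if (normalize) {
    fc <- 2^normalize_expression(tumors, reference, span = span)
  } else {
    fc <- tumors[shared, , drop = FALSE] /
      rowMeans(reference[shared, , drop = FALSE])
  }
  if (!is.null(probe_map)) {
    stopifnot(all(c("probe", "gene") %in% names(probe_map)))
    pm <- probe_map[probe_map$probe %in% rownames(fc), , drop = FALSE]
    mean_int <- rowMeans(cbind(tumors[rownames(fc), , drop = FALSE],
                               reference[rownames(fc), , drop = FALSE]))
    best <- vapply(split(pm$probe, pm$gene), function(p) {
      p[which.max(mean_int[p])]
    }, character(1))
    fc <- fc[best, , drop = FALSE]
    rownames(fc) <- names(best)
  }
  if (!is.null(genes)) {
    out <- matrix(NA_real_, nrow = length(genes), ncol = ncol(fc),
                  dimnames = list(genes, colnames(fc)))
    hit <- intersect(genes, rownames(fc))
    out[hit, ] <- fc[hit, ]
    fc <- out
  }
  attr(fc, "informative") <- rownames(fc)[stats::complete.cases(fc)]
  class(fc) <- c("fold_change_table", class(fc))
  fc
}

#' Flag concordant aberrant expression
#'
#' A loss-direction gene is flagged in a sample when its fold change is at
#' or below `fc_under`; a gain-direction gene when at or above `fc_over`
#' (strict comparisons when `thresholds$strict_fc`).
#'
#' @param fc Fold-change matrix (genes x samples; `NA` allowed).
#' @param directions Named character vector or `data.frame`
#'   (`gene`, `direction`) giving each gene's aberration direction.
#' @param thresholds A [cna_thresholds()].
#' @return Logical matrix (`NA` where fold change is missing).
#' @export
flag_aberrant_expression <- function(fc, directions,
                                     thresholds = cna_thresholds()) {
  if (is.data.frame(directions)) {
    directions <- stats::setNames(directions$direction, directions$gene)
  }
  genes <- rownames(fc)
  if (!all(genes %in% names(directions))) {
    stop("every gene needs a direction from its HFR", call. = FALSE)
  }
  dirs <- directions[genes]
  flags <- matrix(NA, nrow = nrow(fc), ncol = ncol(fc), dimnames = dimnames(fc))
  fcm <- unclass(fc)
  for (i in seq_along(genes)) {
    flags[i, ] <- if (dirs[i] == "loss") {
      if (thresholds$strict_fc) fcm[i, ] < thresholds$fc_under else
        fcm[i, ] <= thresholds$fc_under
    } else {
      if (thresholds$strict_fc) fcm[i, ] > thresholds$fc_over else
        fcm[i, ] >= thresholds$fc_over
    }
  }
  flags
}

#' Select candidate drivers by frequency of involvement
#'
#' A gene is nominated when its flagged-sample count reaches
#' `thresholds$freq_min` of all tumors in the expression set (inclusive).
#' Frequencies are kept unrounded for comparison; `freq_pct` is the display
#' percentage.
#'
#' @param flags Logical flag matrix from [flag_aberrant_expression()].
#' @param directions Named direction vector (as in
#'   [flag_aberrant_expression()]).
#' @param thresholds A [cna_thresholds()].
#' @param n_samples Number of tumors in the expression set (defaults to
#'   `ncol(flags)`).
#' @return `data.frame` of class `candidate_drivers`: `gene`, `direction`
#'   (`loss` = candidate tumor suppressor, `gain` = candidate oncogene),
#'   `n_flagged`, `n_samples`, `freq_discovery` (fraction), `freq_pct`,
#'   `status` (`"candidate"`). Genes without information are excluded and
#'   listed in `attr(, "no_information")`.
#' @export
select_candidates <- function(flags, directions,
                              thresholds = cna_thresholds(),
                              n_samples = ncol(flags)) {
  if (is.data.frame(directions)) {
    directions <- stats::setNames(directions$direction, directions$gene)
  }
  informative <- rownames(flags)[rowSums(!is.na(flags)) > 0]
  n_flagged <- rowSums(flags[informative, , drop = FALSE], na.rm = TRUE)
  freq <- n_flagged / n_samples
  sel <- freq >= thresholds$freq_min
  picked <- informative[sel]
  out <- data.frame(gene = picked,
                    direction = unname(directions[picked]),
                    n_flagged = as.integer(n_flagged[sel]),
                    n_samples = rep(as.integer(n_samples), length(picked)),
                    freq_discovery = unname(freq[sel]),
                    freq_pct = round(100 * unname(freq[sel])),
                    status = rep("candidate", length(picked)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$direction, -out$freq_discovery, out$gene), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "no_information") <- setdiff(rownames(flags), informative)
  class(out) <- c("candidate_drivers", "data.frame")
  out
}

#' Confirm candidate drivers in an independent expression set
#'
#' Each candidate's frequency of involvement is recomputed on a validation
#' fold-change table produced by the same operations. Status becomes
#' `"confirmed"` when the validation frequency reaches the selection
#' threshold, `"not_confirmed"` otherwise, and `"no_information"` when the
#' validation platform has no usable probe for the gene.
#'
#' @param candidates A `candidate_drivers` table from
#'   [select_candidates()].
#' @param validation_fc Fold-change matrix for the validation set.
#' @param thresholds A [cna_thresholds()].
#' @return `candidates` with `freq_validation`, `freq_validation_pct`, and
#'   updated `status`.
#' @export
validate_candidates <- function(candidates, validation_fc,
                                thresholds = cna_thresholds()) {
  dirs <- stats::setNames(candidates$direction, candidates$gene)
  freq_val <- rep(NA_real_, nrow(candidates))
  n_val <- ncol(validation_fc)
  fcm <- unclass(validation_fc)
  for (i in seq_len(nrow(candidates))) {
    g <- candidates$gene[i]
    if (!g %in% rownames(fcm) || all(is.na(fcm[g, ]))) next
    v <- fcm[g, ]
    hit <- if (dirs[i] == "loss") {
      if (thresholds$strict_fc) v < thresholds$fc_under else
        v <= thresholds$fc_under
    } else {
      if (thresholds$strict_fc) v > thresholds$fc_over else
        v >= thresholds$fc_over
    }
    freq_val[i] <- sum(hit, na.rm = TRUE) / n_val
  }
  candidates$freq_validation <- freq_val
  candidates$freq_validation_pct <- round(100 * freq_val)
  candidates$status <- ifelse(is.na(freq_val), "no_information",
                              ifelse(freq_val >= thresholds$freq_min,
                                     "confirmed", "not_confirmed"))
  candidates
}

#' @export
print.candidate_drivers <- function(x, ...) {
  cat(sprintf("Candidate driver genes: %d (%d loss-direction, %d gain-direction)\n",
              nrow(x), sum(x$direction == "loss"),
              sum(x$direction == "gain")))
  if (nrow(x)) print.data.frame(x, digits = 3)
  ni <- attr(x, "no_information")
  if (length(ni)) {
    cat(sprintf("(no expression information for %d gene(s))\n", length(ni)))
  }
  invisible(x)
}
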