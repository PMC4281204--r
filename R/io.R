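# Tabular readers/writers for cohort profiles, expression matrices,
# segments and aberrations. All TSV; coordinates 0-based half-open unless a
# header comment says otherwise.

#' Write a copy-number cohort as a probe-level TSV
#'
#' Columns: `probe_id`, `chrom`, `pos`, then one log2ratio column per
#' sample.
#' @param cohort A `cn_cohort` (see [build_profiles()]).
#' @param path Output path.
#' @export
write_profiles <- function(cohort, path) {
  df <- cbind(cohort$grid, as.data.frame(cohort$log2ratio))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe-level cohort TSV written by [write_profiles()]
#' @param path File path.
#' @return A `cn_cohort`.
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character"))
  grid <- df[, c("probe_id", "chrom", "pos")]
  mat <- as.matrix(df[, setdiff(names(df), names(grid)), drop = FALSE])
  rownames(mat) <- grid$probe_id
  structure(list(grid = grid, log2ratio = mat), class = "cn_cohort")
}

#' Write an expression matrix (genes x samples) as TSV
#' @param mat Matrix with gene rownames.
#' @param path Output path.
#' @export
write_expression_matrix <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_matrix()]
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

#' Write segments in SEG format
#'
#' Columns: sample, chrom, start, end, n_probes, seg.mean (plus state when
#' present).
#' @param segments Segment `data.frame` (optionally called).
#' @param path Output path.
#' @param header Optional comment lines (without `#`).
#' @export
write_seg <- function(segments, path, header = NULL) {
  seg <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                    start = segments$start_bp, end = segments$end_bp,
                    n_probes = segments$n_probes,
                    seg.mean = round(segments$mean_log2ratio, 6))
  if ("state" %in% names(segments)) seg$state <- segments$state
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines("# coordinates: 0-based half-open", con)
  utils::write.table(seg, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write aberrations as BED6 (name = direction, score = size in bp)
#' @param aberrations Aberration `data.frame`.
#' @param path Output path.
#' @export
write_aberrations_bed <- function(aberrations, path) {
  bed <- data.frame(aberrations$chrom,
                    format(aberrations$start_bp, scientific = FALSE,
                           trim = TRUE),
                    format(aberrations$end_bp, scientific = FALSE,
                           trim = TRUE),
                    paste0(aberrations$direction, ":",
                           aberrations$sample_id),
                    format(aberrations$size_bp, scientific = FALSE,
                           trim = TRUE),
                    ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
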