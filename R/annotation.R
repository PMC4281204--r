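# Gene and CNV catalog IO and gene-to-HFR mapping.
#
# All coordinates are normalized to 0-based half-open internally. BED input
# is already in that convention; GFF3 (1-based inclusive) is converted.

#' Read a gene catalog from BED or GFF3
#'
#' BED needs at least 4 columns (chrom, start, end, name); strand is taken
#' from column 6 when present. GFF3 parsing goes through
#' `rtracklayer::import()` and keeps `gene`-type records (or all records if
#' none are typed `gene`), using the `Name` (or `ID`) attribute as symbol.
#' Duplicate symbol/interval pairs are collapsed.
#'
#' @param path File path.
#' @param format `"bed"` or `"gff3"`.
#' @return `data.frame` with `symbol`, `chrom`, `start_bp`, `end_bp`
#'   (0-based half-open), `strand`.
#' @export
read_gene_catalog <- function(path, format = c("bed", "gff3")) {
  format <- match.arg(format)
  if (format == "bed") {
    return(.read_bed_genes(path))
  }
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    warning("empty gene catalog: ", path, call. = FALSE)
    return(data.frame(symbol = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  md <- S4Vectors::mcols(gr)
  if ("type" %in% names(md) && any(md$type == "gene")) {
    gr <- gr[md$type == "gene"]
    md <- S4Vectors::mcols(gr)
  }
  symbol <- if ("Name" %in% names(md) && !all(is.na(md$Name))) {
    as.character(md$Name)
  } else if ("ID" %in% names(md)) {
    as.character(md$ID)
  } else {
    stop("GFF3 records carry neither Name nor ID attributes", call. = FALSE)
  }
  out <- data.frame(symbol = symbol,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start_bp = GenomicRanges::start(gr) - 1,
                    end_bp = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)),
                    stringsAsFactors = FALSE)
  out$strand[out$strand == "*"] <- "."
  .validate_genes(out)
}

.read_bed_genes <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    warning("empty gene catalog: ", path, call. = FALSE)
    return(data.frame(symbol = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  idx <- which(keep)
  rows <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) < 4L) {
      stop(sprintf("malformed BED line %d: expected >= 4 fields", i),
           call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s) {
      stop(sprintf("malformed BED line %d: bad coordinates", i),
           call. = FALSE)
    }
    data.frame(symbol = f[4L], chrom = f[1L], start_bp = s, end_bp = e,
               strand = if (length(f) >= 6L && f[6L] %in% c("+", "-", ".")) f[6L] else ".",
               stringsAsFactors = FALSE)
  })
  .validate_genes(do.call(rbind, rows))
}

.validate_genes <- function(df) {
  if (any(!nzchar(df$symbol))) stop("empty gene symbol", call. = FALSE)
  df <- unique(df)
  df <- df[order(df$chrom, df$start_bp, df$symbol), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a gene catalog as BED6
#' @param genes Gene catalog `data.frame` (see [read_gene_catalog()]).
#' @param path Output path.
#' @export
write_gene_catalog <- function(genes, path) {
  bed <- data.frame(genes$chrom, format(genes$start_bp, scientific = FALSE,
                                        trim = TRUE),
                    format(genes$end_bp, scientific = FALSE, trim = TRUE),
                    genes$symbol, 0L, genes$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a germline-CNV catalog (BED3)
#' @param path File path.
#' @return Sorted `data.frame` with `chrom`, `start_bp`, `end_bp`.
#' @export
read_cnv_catalog <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  if (!any(keep)) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(which(keep), function(i) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) < 3L) {
      stop(sprintf("malformed BED line %d: expected >= 3 fields", i),
           call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[2L]))
    e <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(s) || is.na(e) || s < 0 || e <= s) {
      stop(sprintf("malformed BED line %d: bad coordinates", i),
           call. = FALSE)
    }
    data.frame(chrom = f[1L], start_bp = s, end_bp = e,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start_bp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a BED3 interval file
#' @param df `data.frame` with `chrom`, `start_bp`, `end_bp`.
#' @param path Output path.
#' @export
write_cnv_catalog <- function(df, path) {
  bed <- data.frame(df$chrom,
                    format(df$start_bp, scientific = FALSE, trim = TRUE),
                    format(df$end_bp, scientific = FALSE, trim = TRUE))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a driver-gene census list (one symbol per line)
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_census_list <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x) & !grepl("^#", x)]
}

#' Attach genes to high-frequency regions
#'
#' A gene is attached to an HFR when its interval overlaps the HFR by at
#' least 1 bp ("within or overlapping"); strand is ignored. HFRs without
#' genes are retained and flagged gene-less.
#'
#' @param hfrs An `hfr_set` from [compute_hfrs()].
#' @param genes Gene catalog `data.frame`.
#' @return `hfrs` with a `genes` list-column of symbols and an `n_genes`
#'   column.
#' @export
map_genes_to_hfrs <- function(hfrs, genes) {
  if (nrow(hfrs) == 0L) {
    hfrs$genes <- list()
    hfrs$n_genes <- integer(0)
    return(hfrs)
  }
  shared <- intersect(unique(hfrs$chrom), unique(genes$chrom))
  if (length(shared) == 0L) {
    stop(sprintf(
      "no shared chromosome names between HFRs (%s) and genes (%s)",
      paste(unique(hfrs$chrom), collapse = ","),
      paste(unique(genes$chrom), collapse = ",")), call. = FALSE)
  }
  hfr_gr <- .as_granges(hfrs[, c("chrom", "start_bp", "end_bp")])
  gene_gr <- .as_granges(
    data.frame(chrom = genes$chrom, start_bp = genes$start_bp,
               end_bp = genes$end_bp))
  hits <- GenomicRanges::findOverlaps(hfr_gr, gene_gr)
  glist <- rep(list(character(0)), nrow(hfrs))
  for (i in unique(S4Vectors::queryHits(hits))) {
    j <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    glist[[i]] <- sort(unique(genes$symbol[j]))
  }
  hfrs$genes <- glist
  hfrs$n_genes <- lengths(glist)
  hfrs
}

#' Write an HFR table in the published layout
#'
#' Columns: `Chrom`, `Start`, `End`, `Size_kb`, `Focal_gain`, `Focal_loss`,
#' `Total_gain`, `Total_loss`, `Genes`. The HFR's own direction fills its
#' focal/total columns; opposite-direction counts are derived from
#' `aberrations` when supplied (focal counts by >= 1 bp overlap, totals by
#' full coverage), else 0.
#'
#' @param hfrs Gene-mapped `hfr_set`.
#' @param path Output path.
#' @param aberrations Optional full aberration set for opposite-direction
#'   counts.
#' @param dialect `"bed"` (0-based half-open, default) or `"onebased"`
#'   (1-based inclusive) for the printed coordinates.
#' @param header Optional comment lines (without `#`) to prepend.
#' @export
write_hfr_table <- function(hfrs, path, aberrations = NULL,
                            dialect = c("bed", "onebased"), header = NULL) {
  dialect <- match.arg(dialect)
  n <- nrow(hfrs)
  counts <- function(dir, type) {
    if (n == 0L) return(integer(0))
    vapply(seq_len(n), function(i) {
      if (hfrs$direction[i] == dir) {
        return(if (type == "focal") hfrs$focal_count[i] else
          hfrs$total_count[i])
      }
      if (is.null(aberrations)) return(0L)
      opp <- aberrations[aberrations$direction == dir, , drop = FALSE]
      if (type == "focal") opp <- opp[opp$focal, , drop = FALSE]
      if (nrow(opp) == 0L) return(0L)
      if (type == "focal") {
        sel <- opp$chrom == hfrs$chrom[i] & opp$start_bp < hfrs$end_bp[i] &
          opp$end_bp > hfrs$start_bp[i]
      } else {
        sel <- opp$chrom == hfrs$chrom[i] & opp$start_bp <= hfrs$start_bp[i] &
          opp$end_bp >= hfrs$end_bp[i]
      }
      length(unique(opp$sample_id[sel]))
    }, integer(1))
  }
  start <- hfrs$start_bp + if (dialect == "onebased") 1 else 0
  tab <- data.frame(
    Chrom = hfrs$chrom, Start = start, End = hfrs$end_bp,
    Size_kb = (hfrs$end_bp - hfrs$start_bp) / 1000,
    Focal_gain = counts("gain", "focal"),
    Focal_loss = counts("loss", "focal"),
    Total_gain = counts("gain", "total"),
    Total_loss = counts("loss", "total"),
    Genes = vapply(seq_len(max(n, 0L)), function(i) {
      if (!is.null(hfrs$genes) && length(hfrs$genes[[i]])) {
        paste(hfrs$genes[[i]], collapse = ", ")
      } else ""
    }, character(1)),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(sprintf("# coordinates: %s", if (dialect == "bed")
    "0-based half-open" else "1-based inclusive"), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an HFR table in the published layout
#'
#' Parses a TSV with columns `Chrom`, `Start`, `End`, `Size_kb`,
#' `Focal_gain`, `Focal_loss`, `Total_gain`, `Total_loss`, `Genes` (comment
#' lines starting with `#` ignored; genes comma-separated). The packaged
#' reference table of published HFRs ships at
#' `system.file("extdata", "hfr_table_published.tsv", package = "focalCNA")`
#' and uses the printed 1-based coordinates verbatim.
#'
#' @param path File path.
#' @return `data.frame` with the table's columns and a `genes` list-column.
#' @export
read_hfr_table <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = c(Chrom = "character"))
  need <- c("Chrom", "Start", "End", "Size_kb", "Focal_gain", "Focal_loss",
            "Total_gain", "Total_loss", "Genes")
  if (!all(need %in% names(tab))) {
    stop("HFR table lacks required columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  tab$genes <- lapply(tab$Genes, function(g) {
    g <- trimws(strsplit(g, ",")[[1L]])
    g[nzchar(g)]
  })
  tab
}
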