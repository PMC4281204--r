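# End-to-end pipeline: simulate -> normalize -> segment -> call -> focal
# filters -> HFRs -> gene mapping -> expression integration -> validation ->
# enrichment -> reports.

#' Configure a pipeline run
#'
#' @param out_dir Run directory (created; artifacts and the serialized
#'   config land here).
#' @param seed Master seed; every stage derives its stream from it.
#' @param genome A [genome_spec()].
#' @param n_samples Copy-number cohort size (default 26).
#' @param noise_sd Probe noise SD (default 0.15).
#' @param n_tumors,n_reference Discovery expression set sizes (defaults 31
#'   and 1).
#' @param n_validation,n_validation_reference Validation expression set
#'   sizes (defaults 84 and 3).
#' @param thresholds A [cna_thresholds()].
#' @param cbs List of segmentation settings: `alpha`, `n_perm`, `min_width`,
#'   `merge_tol`.
#' @param catalog_min_covered_fraction Rule-1 coverage fraction
#'   (default 0.5).
#' @param stages Named logical vector gating optional stages:
#'   `expression`, `validation`, `enrichment`.
#' @param census_genes Optional census symbols for the enrichment stage;
#'   when `NULL` a synthetic census (planted drivers plus decoys) is drawn.
#' @param dialect Coordinate dialect for the written HFR table (`"bed"` or
#'   `"onebased"`).
#' @param cohort_args Extra arguments passed to [generate_cn_cohort()].
#' @param expression_args Extra arguments passed to
#'   [generate_expression()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, genome = genome_spec(),
                            n_samples = 26L, noise_sd = 0.15,
                            n_tumors = 31L, n_reference = 1L,
                            n_validation = 84L, n_validation_reference = 3L,
                            thresholds = cna_thresholds(),
                            cbs = list(alpha = 0.01, n_perm = 1000L,
                                       min_width = 3L, merge_tol = 0.05),
                            catalog_min_covered_fraction = 0.5,
                            stages = c(expression = TRUE, validation = TRUE,
                                       enrichment = TRUE),
                            census_genes = NULL,
                            dialect = c("bed", "onebased"),
                            cohort_args = list(),
                            expression_args = list()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), genome = genome,
                 n_samples = n_samples, noise_sd = noise_sd,
                 n_tumors = n_tumors, n_reference = n_reference,
                 n_validation = n_validation,
                 n_validation_reference = n_validation_reference,
                 thresholds = thresholds, cbs = cbs,
                 catalog_min_covered_fraction = catalog_min_covered_fraction,
                 stages = stages, census_genes = census_genes,
                 dialect = match.arg(dialect), cohort_args = cohort_args,
                 expression_args = expression_args),
            class = "pipeline_config")
}

#' Run the focal-CNA driver-nomination pipeline end to end
#'
#' Executes simulate, normalize/segment/call, focal filtering, HFR
#' computation, gene mapping and (optionally) expression integration,
#' validation and enrichment, writing a filter ledger, an HFR table, a
#' per-gene expression report and a discovery/validation candidate table to
#' the run directory. Identical config and seed give byte-identical report
#' files; the serialized config's MD5 is embedded in every report header.
#'
#' @param config A [pipeline_config()].
#' @return List of class `focal_pipeline` with the run's objects: `genome`,
#'   `truth`, `segments`, `calls`, `aberrations`, `ledger`, `hfrs`,
#'   `candidates`, `enrichment`, `config`, `config_md5`, `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$out_dir, "config.yaml")
  yaml::write_yaml(.config_as_list(config), cfg_path)
  md5 <- unname(tools::md5sum(cfg_path))
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat("", file = log_path)
  logf("pipeline run; config_md5=%s; seed=%d", md5, config$seed)
  th <- config$thresholds

  # --- simulate ---------------------------------------------------------
  genome <- generate_genome(config$genome, seed = config$seed)
  cohort <- do.call(generate_cn_cohort, c(
    list(genome = genome, n_samples = config$n_samples,
         noise_sd = config$noise_sd, seed = config$seed + 1L),
    config$cohort_args))
  truth <- cohort$truth
  profiles <- cohort$profiles
  logf("simulate: %d probes x %d samples; %d planted drivers",
       nrow(profiles$grid), ncol(profiles$log2ratio),
       nrow(truth$planted_drivers))

  # --- normalize / segment / call --------------------------------------
  sample_ids <- colnames(profiles$log2ratio)
  seg_list <- vector("list", length(sample_ids))
  for (k in seq_along(sample_ids)) {
    x <- median_normalize(profiles$log2ratio[, k])
    seg <- cbs_segment(profiles$grid, x, sample_id = sample_ids[k],
                       alpha = config$cbs$alpha, n_perm = config$cbs$n_perm,
                       min_width = config$cbs$min_width,
                       merge_tol = config$cbs$merge_tol,
                       seed = config$seed + 100L + k)
    seg <- mode_normalize(seg)
    seg_list[[k]] <- seg
  }
  segments <- do.call(rbind, seg_list)
  calls <- call_states(segments, loss_threshold = th$loss_threshold,
                       gain_threshold = th$gain_threshold)
  logf("segment+call: %d segments (%d non-neutral)", nrow(calls),
       sum(calls$state != "neutral"))

  # --- focal extraction and germline-CNV filtering ----------------------
  aberrations <- extract_aberrations(calls,
                                     focal_limit_bp = th$focal_limit_bp)
  if (nrow(aberrations)) {
    rownames(aberrations) <- as.character(seq_len(nrow(aberrations)))
  }
  recurrent <- .recurrent_focal_ids(aberrations, th$recurrence_min)
  f1 <- filter_catalog_overlap(aberrations, genome$cnv_catalog,
                               config$catalog_min_covered_fraction)
  f2 <- filter_bidirectional(f1$kept, recurrence_min = th$recurrence_min)
  ledger <- make_ledger(
    n_recurrent_observed = length(recurrent),
    n_removed_catalog = sum(rownames(f1$removed) %in% recurrent),
    n_removed_bidirectional = sum(rownames(f2$removed) %in% recurrent))
  logf("focal filter: observed %d recurrent; removed %d (catalog) + %d (bidirectional); retained %d",
       ledger$n_recurrent_observed, ledger$n_removed_catalog,
       ledger$n_removed_bidirectional, ledger$n_retained)

  hfrs <- compute_hfrs(f2$kept, recurrence_min = th$recurrence_min)
  hfrs <- count_total(hfrs, aberrations)
  hfrs <- map_genes_to_hfrs(hfrs, genome$genes)
  logf("hfr: %d regions, %d gene-bearing, %d distinct genes",
       nrow(hfrs), sum(hfrs$n_genes > 0),
       length(unique(unlist(hfrs$genes))))

  # --- report: ledger + HFR table --------------------------------------
  utils::write.table(
    data.frame(n_recurrent_observed = ledger$n_recurrent_observed,
               n_removed_catalog = ledger$n_removed_catalog,
               n_removed_bidirectional = ledger$n_removed_bidirectional,
               n_retained = ledger$n_retained),
    file.path(config$out_dir, "ledger.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_seg(calls, file.path(config$out_dir, "segments.seg"),
            header = sprintf("config_md5=%s", md5))
  write_aberrations_bed(aberrations,
                        file.path(config$out_dir, "aberrations.bed"))
  write_hfr_table(hfrs, file.path(config$out_dir, "hfr_table.tsv"),
                  aberrations = aberrations, dialect = config$dialect,
                  header = sprintf("config_md5=%s", md5))

  candidates <- NULL
  enrichment <- NULL
  expression <- NULL

  # --- expression integration ------------------------------------------
  if (isTRUE(config$stages[["expression"]])) {
    expr_args <- config$expression_args
    expression <- do.call(generate_expression, c(
      list(genome = genome, truth = truth, n_tumors = config$n_tumors,
           n_reference = config$n_reference, seed = config$seed + 2L),
      expr_args))
    hfr_genes <- .hfr_gene_directions(hfrs)
    if (nrow(hfr_genes) > 0L) {
      fc <- compute_fold_changes(expression$tumors, expression$reference,
                                 genes = hfr_genes$gene, normalize = TRUE)
      flags <- flag_aberrant_expression(fc, hfr_genes, th)
      candidates <- select_candidates(flags, hfr_genes, th,
                                      n_samples = config$n_tumors)
      .write_expression_report(fc, flags, hfr_genes,
                               file.path(config$out_dir,
                                         "expression_report.tsv"), md5)
      if (isTRUE(config$stages[["validation"]]) && nrow(candidates) > 0L) {
        val <- do.call(generate_expression, c(
          list(genome = genome, truth = truth,
               n_tumors = config$n_validation,
               n_reference = config$n_validation_reference,
               seed = config$seed + 3L, sample_prefix = "V"),
          expr_args))
        val_fc <- compute_fold_changes(val$tumors, val$reference,
                                       genes = candidates$gene,
                                       normalize = TRUE)
        candidates <- validate_candidates(candidates, val_fc, th)
      }
      .write_candidate_table(candidates,
                             file.path(config$out_dir, "candidates.tsv"),
                             md5)
      logf("expression: %d HFR genes scored, %d candidates (%d confirmed)",
           nrow(hfr_genes), nrow(candidates),
           sum(candidates$status == "confirmed"))
    } else {
      logf("expression: no HFR genes to score")
      candidates <- select_candidates(
        matrix(FALSE, 0, config$n_tumors), character(0), th,
        n_samples = config$n_tumors)
      .write_candidate_table(candidates,
                             file.path(config$out_dir, "candidates.tsv"),
                             md5)
    }
  } else {
    warning("expression stage disabled: candidate table not produced",
            call. = FALSE)
    logf("expression: stage disabled")
  }

  # --- enrichment -------------------------------------------------------
  if (isTRUE(config$stages[["enrichment"]])) {
    census <- config$census_genes
    if (is.null(census)) {
      census <- withr::with_seed(config$seed + 4L, {
        decoys <- sample(setdiff(genome$genes$symbol,
                                 truth$planted_drivers$gene),
                         max(3L, round(0.05 * nrow(genome$genes))))
        sort(c(truth$planted_drivers$gene, decoys))
      })
    }
    hfr_gene_set <- unique(unlist(hfrs$genes))
    if (length(hfr_gene_set) > 0L) {
      enrichment <- census_enrichment(hfr_gene_set, census,
                                      genome$genes$symbol,
                                      n_perm = 1000L,
                                      seed = config$seed + 5L)
      utils::write.table(
        data.frame(n_universe = enrichment$n_universe,
                   n_census_in_universe = enrichment$n_census_in_universe,
                   n_query = enrichment$n_query,
                   n_overlap = enrichment$n_overlap,
                   p_value = enrichment$p_value,
                   p_permutation = enrichment$p_permutation),
        file.path(config$out_dir, "enrichment.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      logf("enrichment: overlap %d/%d, p=%.4g", enrichment$n_overlap,
           enrichment$n_query, enrichment$p_value)
    } else {
      logf("enrichment: skipped (no HFR genes)")
    }
  }

  structure(list(genome = genome, truth = truth, profiles = profiles,
                 segments = segments, calls = calls,
                 aberrations = aberrations, ledger = ledger, hfrs = hfrs,
                 candidates = candidates, enrichment = enrichment,
                 expression = expression, config = config,
                 config_md5 = md5, out_dir = config$out_dir),
            class = "focal_pipeline")
}

# rownames of focal aberrations that belong to a same-direction overlap
# cluster spanning >= recurrence_min distinct samples
.recurrent_focal_ids <- function(aberrations, recurrence_min) {
  out <- character(0)
  for (dir in c("gain", "loss")) {
    rows <- which(aberrations$focal & aberrations$direction == dir)
    if (!length(rows)) next
    cl <- .overlap_clusters(aberrations[rows, , drop = FALSE])
    for (id in unique(cl)) {
      mem <- rows[cl == id]
      if (length(unique(aberrations$sample_id[mem])) >= recurrence_min) {
        out <- c(out, rownames(aberrations)[mem])
      }
    }
  }
  out
}

# one (gene, direction) row per gene attached to an HFR
.hfr_gene_directions <- function(hfrs) {
  if (nrow(hfrs) == 0L) {
    return(data.frame(gene = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- do.call(rbind, lapply(seq_len(nrow(hfrs)), function(i) {
    if (!length(hfrs$genes[[i]])) return(NULL)
    data.frame(gene = hfrs$genes[[i]], direction = hfrs$direction[i],
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows)) {
    return(data.frame(gene = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  unique(rows)
}

.write_expression_report <- function(fc, flags, hfr_genes, path, md5) {
  n <- ncol(flags)
  rep_df <- data.frame(
    gene = rownames(flags),
    direction = stats::setNames(hfr_genes$direction,
                                hfr_genes$gene)[rownames(flags)],
    n_flagged = rowSums(flags, na.rm = TRUE),
    n_samples = n,
    pct_flagged = round(100 * rowSums(flags, na.rm = TRUE) / n),
    informative = rowSums(!is.na(flags)) > 0,
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_md5=%s", md5), con)
  writeLines("# per-gene concordant aberrant expression (loss: FC <= under-threshold; gain: FC >= over-threshold)",
             con)
  utils::write.table(rep_df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.write_candidate_table <- function(candidates, path, md5) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_md5=%s", md5), con)
  writeLines("# frequency of involvement (percent) in discovery and validation sets",
             con)
  cols <- intersect(c("gene", "direction", "n_flagged", "n_samples",
                      "freq_pct", "freq_validation_pct", "status"),
                    names(candidates))
  utils::write.table(as.data.frame(candidates)[, cols, drop = FALSE], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.config_as_list <- function(config) {
  list(seed = config$seed,
       genome = list(
         chromosomes = config$genome$chromosomes,
         probe_spacing_bp = config$genome$probe_spacing_bp,
         n_genes = config$genome$n_genes,
         gene_length_range_bp = config$genome$gene_length_range_bp,
         n_polymorphic_loci = config$genome$n_polymorphic_loci,
         catalog_fraction = config$genome$catalog_fraction),
       n_samples = config$n_samples, noise_sd = config$noise_sd,
       n_tumors = config$n_tumors, n_reference = config$n_reference,
       n_validation = config$n_validation,
       n_validation_reference = config$n_validation_reference,
       thresholds = unclass(config$thresholds), cbs = config$cbs,
       catalog_min_covered_fraction = config$catalog_min_covered_fraction,
       stages = as.list(config$stages),
       dialect = config$dialect,
       cohort_args = config$cohort_args,
       expression_args = config$expression_args)
}

#' @export
print.focal_pipeline <- function(x, ...) {
  cat("Focal-CNA driver nomination pipeline run\n")
  cat(sprintf("  run directory: %s (config md5 %s)\n", x$out_dir,
              substr(x$config_md5, 1, 8)))
  print(x$ledger)
  cat(sprintf("  HFRs: %d (%d gene-bearing)\n", nrow(x$hfrs),
              sum(x$hfrs$n_genes > 0)))
  if (!is.null(x$candidates)) {
    cat(sprintf("  candidates: %d (%d confirmed)\n", nrow(x$candidates),
                if ("status" %in% names(x$candidates))
                  sum(x$candidates$status == "confirmed") else 0L))
  }
  if (!is.null(x$enrichment)) {
    cat(sprintf("  census enrichment p = %.4g\n", x$enrichment$p_value))
  }
  invisible(x)
}

#' @export
summary.focal_pipeline <- function(object, ...) {
  print(object)
  if (nrow(object$hfrs)) {
    cat("\nHigh-frequency regions:\n")
    df <- as.data.frame(object$hfrs)
    df$genes <- vapply(df$genes, paste, character(1), collapse = ",")
    df$members <- NULL
    print(utils::head(df, 20))
  }
  invisible(object)
}
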