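# Synthetic cohort generator.
#
# Emulates, at reduced scale, the substrate of a SNP-array driver-gene study:
# a shared probe grid, a gene catalog, a germline-CNV catalog, multi-sample
# log2ratio profiles carrying broad arm-level CNAs, recurrent focal somatic
# CNAs around planted driver genes, shared polymorphic germline CNVs
# (bidirectional at a locus), Gaussian probe noise, and tumor/reference
# expression matrices in which planted drivers are dosage-coupled.
# Every planted event is recorded in a truth set for recovery testing.

#' Specify a synthetic genome
#'
#' @param chromosomes `data.frame` with columns `name` and `length_bp`, or
#'   `NULL` for the default scaled genome (6 chromosomes of 50 Mb — a
#'   desk-scale stand-in for a genome-wide SNP grid).
#' @param probe_spacing_bp Distance between adjacent probes (default 150 kb).
#' @param n_genes Number of non-overlapping genes to place (default 240).
#' @param gene_length_range_bp Min/max gene length (default 20-200 kb).
#' @param n_polymorphic_loci Number of polymorphic germline-CNV loci
#'   (default 12).
#' @param catalog_fraction Fraction of polymorphic loci present in the CNV
#'   catalog; the remainder emulate CNVs missing from the catalog that only
#'   the bidirectionality rule can remove (default 0.6).
#' @return A list of class `genome_spec`.
#' @export
genome_spec <- function(chromosomes = NULL, probe_spacing_bp = 150000,
                        n_genes = 240L,
                        gene_length_range_bp = c(20000, 200000),
                        n_polymorphic_loci = 12L, catalog_fraction = 0.6) {
  if (is.null(chromosomes)) {
    chromosomes <- data.frame(name = paste0("chr", 1:6),
                              length_bp = rep(50e6, 6),
                              stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length_bp") %in% names(chromosomes)),
            all(chromosomes$length_bp > 0),
            probe_spacing_bp >= 1,
            n_genes >= 0, length(gene_length_range_bp) == 2L,
            gene_length_range_bp[1] > 0,
            gene_length_range_bp[2] >= gene_length_range_bp[1],
            n_polymorphic_loci >= 0,
            catalog_fraction >= 0, catalog_fraction <= 1)
  structure(list(chromosomes = chromosomes,
                 probe_spacing_bp = probe_spacing_bp,
                 n_genes = as.integer(n_genes),
                 gene_length_range_bp = gene_length_range_bp,
                 n_polymorphic_loci = as.integer(n_polymorphic_loci),
                 catalog_fraction = catalog_fraction),
            class = "genome_spec")
}

# Draw n non-overlapping intervals, each at least min_gap from its neighbours
# on the same chromosome and at least boundary_margin from the chromosome
# ends and midpoint (where broad arm-level events break; planted loci placed
# closer would fragment broad events into spurious focal aberrations on this
# scaled-down genome). Deterministic under the caller's RNG state.
.place_intervals <- function(chromosomes, n, len_range, min_gap,
                             boundary_margin = 0, max_tries = 200L) {
  if (n == 0L) {
    return(data.frame(chrom = character(0), start_bp = numeric(0),
                      end_bp = numeric(0), stringsAsFactors = FALSE))
  }
  placed <- vector("list", n)
  count <- 0L
  prob <- chromosomes$length_bp / sum(chromosomes$length_bp)
  for (tries in seq_len(max_tries * n)) {
    ci <- sample.int(nrow(chromosomes), 1L, prob = prob)
    len <- stats::runif(1, len_range[1], len_range[2])
    L <- chromosomes$length_bp[ci]
    if (L <= len) next
    s <- floor(stats::runif(1, 0, L - len))
    e <- floor(s + len)
    ok <- TRUE
    if (boundary_margin > 0) {
      for (b in c(0, floor(L / 2), L)) {
        if (s < b + boundary_margin && e > b - boundary_margin) {
          ok <- FALSE
          break
        }
      }
    }
    if (!ok) next
    if (count > 0L) {
      for (k in seq_len(count)) {
        p <- placed[[k]]
        if (p$chrom == chromosomes$name[ci] &&
            s < p$end_bp + min_gap && e > p$start_bp - min_gap) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok) {
      count <- count + 1L
      placed[[count]] <- list(chrom = chromosomes$name[ci], start_bp = s,
                              end_bp = e)
      if (count == n) break
    }
  }
  if (count < n) {
    stop("could not place the requested intervals; genome too small or too crowded",
         call. = FALSE)
  }
  df <- do.call(rbind, lapply(placed, as.data.frame,
                              stringsAsFactors = FALSE))
  df[order(match(df$chrom, chromosomes$name), df$start_bp), , drop = FALSE]
}

#' Generate a synthetic genome: probe grid, gene catalog, CNV catalog
#'
#' Probes are evenly spaced (`spacing/2, 3*spacing/2, ...`) within each
#' chromosome; genes are non-overlapping; polymorphic loci are well separated
#' and exactly `round(catalog_fraction * n_polymorphic_loci)` of them enter
#' the CNV catalog.
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; identical `(spec, seed)` give identical output.
#' @return A list of class `synthetic_genome` with elements `probes`
#'   (`probe_id`, `chrom`, `pos`), `genes` (`symbol`, `chrom`, `start_bp`,
#'   `end_bp`, `strand`; 0-based half-open), `cnv_loci` (polymorphic loci
#'   with an `in_catalog` flag), `cnv_catalog` (BED3-style subset), and the
#'   originating `spec`.
#' @export
generate_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  sp <- spec$probe_spacing_bp
  if (any(spec$chromosomes$length_bp < sp)) {
    stop("chromosome shorter than one probe spacing", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    probes <- do.call(rbind, lapply(seq_len(nrow(spec$chromosomes)),
                                    function(i) {
      L <- spec$chromosomes$length_bp[i]
      k <- floor(L / sp)
      pos <- sp * seq_len(k) - sp / 2
      data.frame(chrom = spec$chromosomes$name[i], pos = pos,
                 stringsAsFactors = FALSE)
    }))
    probes <- data.frame(probe_id = sprintf("p%06d", seq_len(nrow(probes))),
                         probes, stringsAsFactors = FALSE)
    genes <- .place_intervals(spec$chromosomes, spec$n_genes,
                              spec$gene_length_range_bp, min_gap = 0)
    if (nrow(genes) > 0L) {
      genes <- data.frame(symbol = sprintf("G%04d", seq_len(nrow(genes))),
                          genes, strand = "+", stringsAsFactors = FALSE)
    } else {
      genes <- data.frame(symbol = character(0), chrom = character(0),
                          start_bp = numeric(0), end_bp = numeric(0),
                          strand = character(0), stringsAsFactors = FALSE)
    }
    # polymorphic loci span >= 5 probes so that every carrier's event is
    # reliably segmentable (sizes scaled with the coarse probe grid)
    cnv_loci <- .place_intervals(spec$chromosomes, spec$n_polymorphic_loci,
                                 c(max(8e5, 5.3 * sp), 1.5e6 + 5.3 * sp),
                                 min_gap = 4e6, boundary_margin = 3.5e6)
    n_cat <- round(spec$catalog_fraction * spec$n_polymorphic_loci)
    in_catalog <- rep(FALSE, nrow(cnv_loci))
    if (nrow(cnv_loci) > 0L) {
      in_catalog[sample.int(nrow(cnv_loci))[seq_len(n_cat)]] <- TRUE
      cnv_loci$locus_id <- sprintf("cnv%03d", seq_len(nrow(cnv_loci)))
    } else {
      cnv_loci$locus_id <- character(0)
    }
    cnv_loci$in_catalog <- in_catalog
    structure(list(probes = probes, genes = genes, cnv_loci = cnv_loci,
                   cnv_catalog = cnv_loci[cnv_loci$in_catalog,
                                          c("chrom", "start_bp", "end_bp"),
                                          drop = FALSE],
                   spec = spec),
              class = "synthetic_genome")
  })
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf("Synthetic genome: %d chromosomes, %d probes (spacing %s bp)\n",
              nrow(x$spec$chromosomes), nrow(x$probes),
              format(x$spec$probe_spacing_bp, big.mark = ",")))
  cat(sprintf("  %d genes; %d polymorphic CNV loci (%d in catalog)\n",
              nrow(x$genes), nrow(x$cnv_loci), sum(x$cnv_loci$in_catalog)))
  invisible(x)
}

#' Build probe-level log2ratio profiles from planted events
#'
#' Each probe's log2ratio is the sum of the amplitudes of all events covering
#' it (half-open bp intervals), plus Gaussian noise.
#'
#' @param genome A [generate_genome()] result.
#' @param events `data.frame` with `sample_id`, `chrom`, `start_bp`,
#'   `end_bp`, `amplitude`. May be empty.
#' @param sample_ids Character vector of all samples (so event-free samples
#'   still get profiles).
#' @param noise_sd Standard deviation of probe noise (log2ratio units).
#' @param seed Integer seed.
#' @return A list of class `cn_cohort`: `grid` (the probe data.frame) and
#'   `log2ratio` (matrix probes x samples).
#' @export
build_profiles <- function(genome, events, sample_ids, noise_sd = 0.15,
                           seed = 1L) {
  stopifnot(inherits(genome, "synthetic_genome"), noise_sd >= 0)
  grid <- genome$probes
  mat <- matrix(0, nrow = nrow(grid), ncol = length(sample_ids),
                dimnames = list(grid$probe_id, sample_ids))
  if (nrow(events) > 0L) {
    for (i in seq_len(nrow(events))) {
      sel <- grid$chrom == events$chrom[i] &
        grid$pos >= events$start_bp[i] & grid$pos < events$end_bp[i]
      mat[sel, events$sample_id[i]] <- mat[sel, events$sample_id[i]] +
        events$amplitude[i]
    }
  }
  if (noise_sd > 0) {
    mat <- mat + withr::with_seed(as.integer(seed), {
      matrix(stats::rnorm(length(mat), 0, noise_sd), nrow = nrow(mat))
    })
  }
  structure(list(grid = grid, log2ratio = mat), class = "cn_cohort")
}

#' Generate a copy-number cohort with planted ground truth
#'
#' Plants, per sample: broad arm-level CNAs, recurrent focal somatic CNAs
#' around randomly chosen, well-separated driver genes (each carried by
#' `carrier_prob` of samples, at least 2), non-recurrent focal passenger
#' events, and germline polymorphic CNVs whose carriers are drawn
#' independently per sample with both gain and loss carriers possible at a
#' locus. Probe log2ratios are the sum of planted amplitudes plus Gaussian
#' noise.
#'
#' @param genome A [generate_genome()] result.
#' @param n_samples Number of samples (>= 2; default 26).
#' @param noise_sd Probe noise SD (default 0.15).
#' @param seed Integer seed.
#' @param n_loss_drivers,n_gain_drivers Planted driver genes per direction
#'   (defaults 5 and 3).
#' @param carrier_prob Per-sample probability of carrying each driver's focal
#'   event (default 0.65, mid-range of typical discovery frequencies of
#'   involvement for recurrent focal drivers).
#' @param gain_amplitude,loss_amplitude Focal/CNV log2ratio amplitudes —
#'   ideal diploid single-copy values by default (+0.58 / -1.0).
#' @param broad_amplitude Magnitude of broad arm-level events (default 0.4).
#' @param broad_rate,passenger_rate Poisson means of broad and focal
#'   passenger events per sample (defaults 1.5 and 0.5).
#' @param cnv_carrier_prob Per-sample carrier probability at each polymorphic
#'   locus (default 0.5, as for common polymorphisms); carriers split
#'   roughly evenly between deletion and duplication alleles.
#' @param focal_extension_bp Range of the uniform extension of a driver's
#'   focal event beyond the gene on each side (default 450 kb - 1 Mb, keeping
#'   every planted focal event under the 3 Mb focal limit while spanning
#'   several probes).
#' @param effect_loss,effect_gain Expression effect multipliers recorded for
#'   planted drivers (defaults 0.5 and 2.0), used by
#'   [generate_expression()].
#' @return A list with `profiles` (a `cn_cohort`) and `truth` (class
#'   `truth_set`: `planted_broad`, `planted_focal`, `planted_cnv_loci`,
#'   `planted_cnv_events`, `planted_drivers`).
#' @export
generate_cn_cohort <- function(genome, n_samples = 26L, noise_sd = 0.15,
                               seed = 1L, n_loss_drivers = 5L,
                               n_gain_drivers = 3L, carrier_prob = 0.65,
                               gain_amplitude = 0.58, loss_amplitude = -1.0,
                               broad_amplitude = 0.4, broad_rate = 1.5,
                               passenger_rate = 0.5, cnv_carrier_prob = 0.5,
                               focal_extension_bp = c(450000, 1000000),
                               effect_loss = 0.5, effect_gain = 2.0) {
  stopifnot(inherits(genome, "synthetic_genome"), n_samples >= 2,
            noise_sd >= 0, carrier_prob > 0, carrier_prob <= 1)
  sample_ids <- sprintf("S%02d", seq_len(n_samples))
  chroms <- genome$spec$chromosomes
  withr::with_seed(as.integer(seed), {
    drivers <- .choose_driver_genes(genome, n_loss_drivers, n_gain_drivers,
                                    focal_extension_bp)
    drivers$effect_multiplier <- if (nrow(drivers)) {
      ifelse(drivers$direction == "loss", effect_loss, effect_gain)
    } else numeric(0)
    drivers$carrier_prob <- rep(carrier_prob, nrow(drivers))

    ev <- list()
    focal <- list()
    # focal driver events: jittered intervals that all contain the gene
    for (d in seq_len(nrow(drivers))) {
      carriers <- sample_ids[stats::runif(n_samples) < carrier_prob]
      if (length(carriers) < 2L) {
        carriers <- sample(sample_ids, 2L)
      }
      amp <- if (drivers$direction[d] == "gain") gain_amplitude else
        loss_amplitude
      L <- chroms$length_bp[match(drivers$chrom[d], chroms$name)]
      for (s in carriers) {
        ext <- stats::runif(2, focal_extension_bp[1], focal_extension_bp[2])
        st <- max(0, floor(drivers$start_bp[d] - ext[1]))
        en <- min(L, ceiling(drivers$end_bp[d] + ext[2]))
        focal[[length(focal) + 1L]] <- data.frame(
          sample_id = s, chrom = drivers$chrom[d], start_bp = st,
          end_bp = en, direction = drivers$direction[d],
          driver_gene = drivers$gene[d], amplitude = amp,
          stringsAsFactors = FALSE)
      }
    }
    # focal passengers: non-recurrent random events. Kept clear of planted
    # driver and germline loci so that each planted event class exercises
    # exactly one filter and the truth stays recoverable.
    avoid <- rbind(
      if (nrow(drivers)) data.frame(chrom = drivers$chrom,
                                    start_bp = drivers$start_bp - 3e6,
                                    end_bp = drivers$end_bp + 3e6) else NULL,
      if (nrow(genome$cnv_loci)) data.frame(
        chrom = genome$cnv_loci$chrom,
        start_bp = genome$cnv_loci$start_bp - 1.5e6,
        end_bp = genome$cnv_loci$end_bp + 1.5e6) else NULL)
    for (s in sample_ids) {
      np <- stats::rpois(1, passenger_rate)
      for (k in seq_len(np)) {
        for (try in 1:50) {
          ci <- sample.int(nrow(chroms), 1L)
          len <- stats::runif(1, 6e5, 1.2e6)
          st <- floor(stats::runif(1, 0, chroms$length_bp[ci] - len))
          en <- floor(st + len)
          clash <- !is.null(avoid) &&
            any(avoid$chrom == chroms$name[ci] & avoid$start_bp < en &
                  avoid$end_bp > st)
          if (!clash) break
        }
        if (clash) next
        dir <- sample(c("gain", "loss"), 1L)
        focal[[length(focal) + 1L]] <- data.frame(
          sample_id = s, chrom = chroms$name[ci], start_bp = st,
          end_bp = en, direction = dir,
          driver_gene = NA_character_,
          amplitude = if (dir == "gain") gain_amplitude else loss_amplitude,
          stringsAsFactors = FALSE)
      }
    }
    planted_focal <- if (length(focal)) do.call(rbind, focal) else
      data.frame(sample_id = character(0), chrom = character(0),
                 start_bp = numeric(0), end_bp = numeric(0),
                 direction = character(0), driver_gene = character(0),
                 amplitude = numeric(0), stringsAsFactors = FALSE)

    # broad arm-level events
    broad <- list()
    for (s in sample_ids) {
      nb <- stats::rpois(1, broad_rate)
      for (k in seq_len(nb)) {
        ci <- sample.int(nrow(chroms), 1L)
        L <- chroms$length_bp[ci]
        left <- stats::runif(1) < 0.5
        st <- if (left) 0 else floor(L / 2)
        en <- if (left) floor(L / 2) else L
        dir <- sample(c("gain", "loss"), 1L)
        broad[[length(broad) + 1L]] <- data.frame(
          sample_id = s, chrom = chroms$name[ci], start_bp = st, end_bp = en,
          direction = dir,
          amplitude = if (dir == "gain") broad_amplitude else -broad_amplitude,
          stringsAsFactors = FALSE)
      }
    }
    planted_broad <- if (length(broad)) do.call(rbind, broad) else
      data.frame(sample_id = character(0), chrom = character(0),
                 start_bp = numeric(0), end_bp = numeric(0),
                 direction = character(0), amplitude = numeric(0),
                 stringsAsFactors = FALSE)

    # germline polymorphic CNVs: i.i.d. carriers; loci are bidirectional, so
    # when a locus has enough carriers both directions are guaranteed to be
    # recurrent (>= 2 gains and >= 2 losses) — the signature the
    # bidirectionality filter targets
    cnv <- list()
    loci <- genome$cnv_loci
    for (li in seq_len(nrow(loci))) {
      carriers <- sample_ids[stats::runif(n_samples) < cnv_carrier_prob]
      nc <- length(carriers)
      if (nc == 0L) next
      # two common alleles: deletion and duplication carriers in roughly
      # equal numbers (random balanced split)
      n_gain <- floor(nc / 2) + (nc %% 2L) * stats::rbinom(1, 1, 0.5)
      dirs <- sample(c(rep("gain", n_gain), rep("loss", nc - n_gain)))
      for (k in seq_len(nc)) {
        cnv[[length(cnv) + 1L]] <- data.frame(
          sample_id = carriers[k], chrom = loci$chrom[li],
          start_bp = loci$start_bp[li], end_bp = loci$end_bp[li],
          direction = dirs[k], locus_id = loci$locus_id[li],
          amplitude = if (dirs[k] == "gain") gain_amplitude else
            loss_amplitude,
          stringsAsFactors = FALSE)
      }
    }
    planted_cnv_events <- if (length(cnv)) do.call(rbind, cnv) else
      data.frame(sample_id = character(0), chrom = character(0),
                 start_bp = numeric(0), end_bp = numeric(0),
                 direction = character(0), locus_id = character(0),
                 amplitude = numeric(0), stringsAsFactors = FALSE)

    ecols <- c("sample_id", "chrom", "start_bp", "end_bp", "amplitude")
    events <- rbind(planted_focal[, ecols], planted_broad[, ecols],
                    planted_cnv_events[, ecols])
    profiles <- build_profiles(genome, events, sample_ids, noise_sd,
                               seed = sample.int(2^30, 1L))
    truth <- structure(list(planted_broad = planted_broad,
                            planted_focal = planted_focal,
                            planted_cnv_loci = loci,
                            planted_cnv_events = planted_cnv_events,
                            planted_drivers = drivers),
                       class = "truth_set")
    list(profiles = profiles, truth = truth)
  })
}

# Pick driver genes far from each other, from polymorphic loci, and from
# chromosome ends, so planted focal events never collide with germline loci.
.choose_driver_genes <- function(genome, n_loss, n_gain, ext_range) {
  n <- n_loss + n_gain
  if (n == 0L) {
    return(data.frame(gene = character(0), chrom = character(0),
                      start_bp = numeric(0), end_bp = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE))
  }
  genes <- genome$genes
  chroms <- genome$spec$chromosomes
  # keep planted driver loci clear of arm-event breakpoints (chromosome ends
  # and midpoint) so broad events fragmented by a driver's focal event leave
  # only non-focal (> 3 Mb) pieces, and clear of germline loci so overlap
  # clusters never chain a driver into a polymorphic locus
  margin <- 4.5e6
  cand <- genes[order(sample.int(nrow(genes))), , drop = FALSE]
  chosen <- list()
  for (i in seq_len(nrow(cand))) {
    g <- cand[i, ]
    L <- chroms$length_bp[match(g$chrom, chroms$name)]
    if (g$start_bp < margin || g$end_bp > L - margin ||
        (g$start_bp < L / 2 + margin && g$end_bp > L / 2 - margin)) next
    ok <- TRUE
    for (c2 in chosen) {
      if (c2$chrom == g$chrom &&
          abs(c2$start_bp - g$start_bp) < 6e6) { ok <- FALSE; break }
    }
    if (ok && nrow(genome$cnv_loci) > 0L) {
      near <- genome$cnv_loci$chrom == g$chrom &
        genome$cnv_loci$start_bp < g$end_bp + 4.5e6 &
        genome$cnv_loci$end_bp > g$start_bp - 4.5e6
      if (any(near)) ok <- FALSE
    }
    if (ok) {
      chosen[[length(chosen) + 1L]] <- g
      if (length(chosen) == n) break
    }
  }
  if (length(chosen) < n) {
    stop("could not place the requested driver genes; genome too crowded",
         call. = FALSE)
  }
  out <- do.call(rbind, chosen)
  out <- data.frame(gene = out$symbol, chrom = out$chrom,
                    start_bp = out$start_bp, end_bp = out$end_bp,
                    stringsAsFactors = FALSE)
  out$direction <- c(rep("loss", n_loss), rep("gain", n_gain))
  out
}

#' Generate dosage-coupled tumor and reference expression matrices
#'
#' Baseline gene intensities are log-normal; reference samples add
#' multiplicative log-normal noise around the baseline; tumor samples
#' additionally multiply planted driver genes by their effect multiplier in
#' carrier samples (carriers drawn i.i.d. with each driver's recorded carrier
#' probability). Non-driver genes are uncoupled from copy number. A fraction
#' of non-driver genes is dropped from the platform to emulate genes without
#' a usable probe; planted drivers always keep a probe.
#'
#' @param genome A [generate_genome()] result.
#' @param truth The `truth_set` from [generate_cn_cohort()].
#' @param n_tumors Number of tumor samples (default 31).
#' @param n_reference Number of reference (osteoblast-like) samples
#'   (default 1).
#' @param seed Integer seed.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline intensity
#'   parameters (defaults log(500), 1).
#' @param noise_sdlog Multiplicative log-normal noise sdlog (default 0.1,
#'   the low technical variation of bead-averaged array intensities).
#' @param probe_missing_prob Probability that a non-driver gene lacks a probe
#'   (default 0.1).
#' @param sample_prefix Prefix for tumor sample ids (default `"T"`).
#' @return A list: `tumors` and `reference` (linear-intensity matrices,
#'   genes x samples), `carriers` (logical matrix, drivers x tumors), and
#'   `missing_genes`.
#' @export
generate_expression <- function(genome, truth, n_tumors = 31L,
                                n_reference = 1L, seed = 1L,
                                baseline_meanlog = log(500),
                                baseline_sdlog = 1, noise_sdlog = 0.1,
                                probe_missing_prob = 0.1,
                                sample_prefix = "T") {
  stopifnot(inherits(genome, "synthetic_genome"),
            inherits(truth, "truth_set"), n_tumors >= 2, n_reference >= 1)
  drivers <- truth$planted_drivers
  if (nrow(drivers) > 0L &&
      !all(drivers$gene %in% genome$genes$symbol)) {
    stop("driver gene absent from gene catalog", call. = FALSE)
  }
  withr::with_seed(as.integer(seed), {
    genes <- genome$genes$symbol
    is_driver <- genes %in% drivers$gene
    missing <- !is_driver & stats::runif(length(genes)) < probe_missing_prob
    keep <- genes[!missing]
    baseline <- stats::rlnorm(length(keep), baseline_meanlog, baseline_sdlog)
    names(baseline) <- keep
    tum_ids <- sprintf("%s%02d", sample_prefix, seq_len(n_tumors))
    ref_ids <- sprintf("R%02d", seq_len(n_reference))
    noise <- function(nc) matrix(stats::rlnorm(length(keep) * nc, 0,
                                               noise_sdlog),
                                 nrow = length(keep))
    reference <- baseline * noise(n_reference)
    dimnames(reference) <- list(keep, ref_ids)
    tumors <- baseline * noise(n_tumors)
    dimnames(tumors) <- list(keep, tum_ids)
    carriers <- matrix(FALSE, nrow = nrow(drivers), ncol = n_tumors,
                       dimnames = list(drivers$gene, tum_ids))
    for (d in seq_len(nrow(drivers))) {
      carr <- stats::runif(n_tumors) < drivers$carrier_prob[d]
      carriers[d, ] <- carr
      tumors[drivers$gene[d], carr] <-
        tumors[drivers$gene[d], carr] * drivers$effect_multiplier[d]
    }
    attr(tumors, "scale") <- "linear"
    attr(reference, "scale") <- "linear"
    list(tumors = tumors, reference = reference, carriers = carriers,
         missing_genes = genes[missing])
  })
}

#' @export
print.cn_cohort <- function(x, ...) {
  cat(sprintf("Copy-number cohort: %d probes x %d samples\n",
              nrow(x$log2ratio), ncol(x$log2ratio)))
  invisible(x)
}

#' @export
print.truth_set <- function(x, ...) {
  cat("Planted truth set\n")
  cat(sprintf("  drivers: %d (%d loss, %d gain)\n", nrow(x$planted_drivers),
              sum(x$planted_drivers$direction == "loss"),
              sum(x$planted_drivers$direction == "gain")))
  cat(sprintf("  focal events: %d; broad events: %d; germline CNV events: %d at %d loci\n",
              nrow(x$planted_focal), nrow(x$planted_broad),
              nrow(x$planted_cnv_events), nrow(x$planted_cnv_loci)))
  invisible(x)
}
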