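# Synthetic cohort generator: determinism, construction guarantees, and
# recoverability of the planted truth.

test_that("genome generation is deterministic and honours its size parameters", {
  spec <- genome_spec(chromosomes = data.frame(name = "chr1",
                                               length_bp = 1e6),
                      probe_spacing_bp = 10000, n_genes = 0,
                      n_polymorphic_loci = 0)
  g <- generate_genome(spec, seed = 3)
  expect_equal(nrow(g$probes), 100)  # 1 Mb / 10 kb
  expect_true(all(diff(g$probes$pos) > 0))

  g2 <- generate_genome(spec, seed = 3)
  expect_identical(g, g2)

  spec_bad <- genome_spec(chromosomes = data.frame(name = "chr1",
                                                   length_bp = 5000),
                          probe_spacing_bp = 10000, n_genes = 0,
                          n_polymorphic_loci = 0)
  expect_error(generate_genome(spec_bad), "shorter than one probe spacing")
})

test_that("catalog_fraction controls how many loci enter the CNV catalog", {
  spec <- genome_spec(chromosomes = data.frame(name = paste0("chr", 1:4),
                                               length_bp = rep(60e6, 4)),
                      probe_spacing_bp = 200000, n_genes = 10,
                      n_polymorphic_loci = 10, catalog_fraction = 0.5)
  g <- generate_genome(spec, seed = 5)
  expect_equal(nrow(g$cnv_loci), 10)
  expect_equal(sum(g$cnv_loci$in_catalog), 5)
  expect_equal(nrow(g$cnv_catalog), 5)
  # genes within chromosome bounds and non-overlapping per chromosome
  for (ch in unique(g$genes$chrom)) {
    d <- g$genes[g$genes$chrom == ch, ]
    d <- d[order(d$start_bp), ]
    expect_true(all(d$end_bp <= 60e6))
    if (nrow(d) > 1) expect_true(all(d$start_bp[-1] >= d$end_bp[-nrow(d)]))
  }
})

test_that("noiseless profiles are the exact sum of planted effects", {
  spec <- genome_spec(chromosomes = data.frame(name = "chr1",
                                               length_bp = 1e6),
                      probe_spacing_bp = 10000, n_genes = 0,
                      n_polymorphic_loci = 0)
  g <- generate_genome(spec, seed = 1)
  # loss of amplitude -1 over probes 10..19 (0-based): positions 105000..195000
  ev <- data.frame(sample_id = "S1", chrom = "chr1",
                   start_bp = 100000, end_bp = 200000, amplitude = -1)
  prof <- build_profiles(g, ev, sample_ids = c("S1", "S2"), noise_sd = 0)
  x <- prof$log2ratio[, "S1"]
  expect_identical(unname(x[11:20]), rep(-1, 10))
  expect_identical(unname(x[-(11:20)]), rep(0, 90))
  expect_identical(unname(prof$log2ratio[, "S2"]), rep(0, 100))
})

test_that("cohort generation records every planted event and is deterministic", {
  spec <- small_spec()
  g <- generate_genome(spec, seed = 2)
  coh <- generate_cn_cohort(g, n_samples = 26, noise_sd = 0.1, seed = 9,
                            n_loss_drivers = 2, n_gain_drivers = 1)
  expect_equal(ncol(coh$profiles$log2ratio), 26)
  tr <- coh$truth
  expect_equal(nrow(tr$planted_drivers), 3)
  # every planted focal interval respects the focal limit
  expect_true(all(tr$planted_focal$end_bp - tr$planted_focal$start_bp <= 3e6))
  # every driver carried focally by >= 2 samples
  for (d in tr$planted_drivers$gene) {
    expect_gte(length(unique(
      tr$planted_focal$sample_id[tr$planted_focal$driver_gene %in% d])), 2)
  }
  coh2 <- generate_cn_cohort(g, n_samples = 26, noise_sd = 0.1, seed = 9,
                             n_loss_drivers = 2, n_gain_drivers = 1)
  expect_identical(coh$profiles$log2ratio, coh2$profiles$log2ratio)
  expect_identical(coh$truth$planted_focal, coh2$truth$planted_focal)
})

test_that("bidirectional polymorphic loci acquire both gain and loss carriers", {
  spec <- genome_spec(chromosomes = data.frame(name = paste0("chr", 1:4),
                                               length_bp = rep(60e6, 4)),
                      probe_spacing_bp = 200000, n_genes = 20,
                      n_polymorphic_loci = 6)
  g <- generate_genome(spec, seed = 4)
  coh <- generate_cn_cohort(g, n_samples = 100, noise_sd = 0, seed = 21,
                            n_loss_drivers = 1, n_gain_drivers = 1,
                            cnv_carrier_prob = 0.5)
  ev <- coh$truth$planted_cnv_events
  for (id in unique(ev$locus_id)) {
    dirs <- ev$direction[ev$locus_id == id]
    expect_gte(sum(dirs == "gain"), 2)
    expect_gte(sum(dirs == "loss"), 2)
  }
})

test_that("expression matrices couple planted drivers to dosage", {
  spec <- small_spec(n_genes = 60)
  g <- generate_genome(spec, seed = 6)
  coh <- generate_cn_cohort(g, n_samples = 10, noise_sd = 0.1, seed = 7,
                            n_loss_drivers = 2, n_gain_drivers = 1)
  tr <- coh$truth
  # noiseless intensities: carrier fold change is exactly the multiplier
  ex0 <- generate_expression(g, tr, n_tumors = 12, n_reference = 2,
                             seed = 8, noise_sdlog = 0,
                             probe_missing_prob = 0)
  fc <- compute_fold_changes(ex0$tumors, ex0$reference)
  for (d in seq_len(nrow(tr$planted_drivers))) {
    gene <- tr$planted_drivers$gene[d]
    carr <- ex0$carriers[gene, ]
    expect_equal(unname(fc[gene, carr]),
                 rep(tr$planted_drivers$effect_multiplier[d], sum(carr)))
    expect_equal(unname(fc[gene, !carr]), rep(1, sum(!carr)))
  }
  # null effect: tumors and reference share the baseline exactly
  tr0 <- tr
  tr0$planted_drivers$effect_multiplier <- 1
  exn <- generate_expression(g, tr0, n_tumors = 12, n_reference = 2,
                             seed = 8, noise_sdlog = 0,
                             probe_missing_prob = 0)
  fcn <- compute_fold_changes(exn$tumors, exn$reference)
  expect_equal(max(abs(fcn - 1)), 0)
  # default parameters: mean carrier fold change clears the flag threshold
  ex <- generate_expression(g, tr, n_tumors = 31, n_reference = 1, seed = 8)
  fcd <- compute_fold_changes(ex$tumors, ex$reference)
  for (d in seq_len(nrow(tr$planted_drivers))) {
    gene <- tr$planted_drivers$gene[d]
    carr <- ex$carriers[gene, ]
    m <- mean(fcd[gene, carr])
    if (tr$planted_drivers$direction[d] == "loss") {
      expect_lt(m, 0.75)
    } else {
      expect_gt(m, 1.5)
    }
  }
  expect_error(
    generate_expression(g, structure(list(planted_drivers = data.frame(
      gene = "NOT_A_GENE", direction = "loss", effect_multiplier = 0.5,
      carrier_prob = 0.5)), class = "truth_set"), n_tumors = 5,
      n_reference = 1, seed = 1),
    "absent from gene catalog")
})

test_that("event-free noisy cohorts yield no candidates (null calibration)", {
  spec <- small_spec(spacing = 200000, n_genes = 40, n_loci = 0)
  g <- generate_genome(spec, seed = 1)
  clean <- 0L
  for (k in 1:20) {
    coh <- generate_cn_cohort(g, n_samples = 8, noise_sd = 0.15,
                              seed = 300 + k, n_loss_drivers = 0,
                              n_gain_drivers = 0, broad_rate = 0,
                              passenger_rate = 0)
    segs <- do.call(rbind, lapply(colnames(coh$profiles$log2ratio),
                                  function(s) {
      cbs_segment(coh$profiles$grid,
                  median_normalize(coh$profiles$log2ratio[, s]),
                  sample_id = s, n_perm = 100, seed = 400 + k)
    }))
    calls <- call_states(segs)
    abs_ <- extract_aberrations(calls)
    hfrs <- compute_hfrs(filter_bidirectional(abs_)$kept)
    if (nrow(hfrs) == 0L) clean <- clean + 1L
  }
  expect_gte(clean, 19)  # >= 95% of 20 runs
})
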