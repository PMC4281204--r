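# Expression normalization, fold changes, flagging and candidate selection.

make_expr <- function(n_genes = 60, n_tum = 8, n_ref = 2, seed = 1,
                      bias = NULL) {
  withr::with_seed(seed, {
    genes <- sprintf("G%03d", seq_len(n_genes))
    base <- stats::rlnorm(n_genes, log(400), 1)
    ref <- base * matrix(stats::rlnorm(n_genes * n_ref, 0, 0.1), n_genes)
    tum <- base * matrix(stats::rlnorm(n_genes * n_tum, 0, 0.1), n_genes)
    dimnames(ref) <- list(genes, paste0("R", seq_len(n_ref)))
    dimnames(tum) <- list(genes, paste0("T", seq_len(n_tum)))
    if (!is.null(bias)) {
      # intensity-dependent multiplicative bias per sample
      A <- log2(base)
      tum <- tum * 2^outer(A - mean(A), rep(bias, n_tum))
    }
    list(tumors = tum, reference = ref)
  })
}

test_that("quantile normalization equalizes per-sample distributions", {
  ex <- make_expr()
  M <- normalize_expression(ex$tumors, ex$reference)
  sorted <- apply(M, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
})

test_that("a trend-free zero matrix is a fixed point of normalization", {
  ex <- make_expr(n_ref = 1)
  tum <- matrix(rep(ex$reference[, 1], 3), ncol = 3,
                dimnames = list(rownames(ex$reference), paste0("T", 1:3)))
  M <- normalize_expression(tum, ex$reference)
  expect_lt(max(abs(M)), 1e-6)  # log2ratios were exactly 0 and stay 0
})

test_that("local regression removes an injected intensity-dependent trend", {
  ex <- make_expr(n_genes = 400, bias = 0.15)
  ref <- log2(rowMeans(ex$reference))
  M_raw <- log2(ex$tumors[, 1]) - ref
  A <- (log2(ex$tumors[, 1]) + ref) / 2  # the trend covariate
  slope_before <- stats::coef(stats::lm(M_raw ~ A))[2]
  expect_gt(abs(slope_before), 0.1)
  M <- normalize_expression(ex$tumors, ex$reference)
  slope_after <- stats::coef(stats::lm(M[, 1] ~ A))[2]
  expect_lt(abs(slope_after), 0.01)
})

test_that("fold changes are intensity ratios against the mean reference", {
  ref <- matrix(c(10, 100, 20, 200), nrow = 2,
                dimnames = list(c("A", "B"), c("R1", "R2")))
  tum <- matrix(c(15, 300, 30, 150), nrow = 2,
                dimnames = list(c("A", "B"), c("T1", "T2")))
  fc <- compute_fold_changes(tum, ref)
  expect_equal(unname(fc["A", ]), c(1, 2))        # ref mean 15
  expect_equal(unname(fc["B", ]), c(2, 1))        # ref mean 150
  expect_error(compute_fold_changes(-tum, ref), "non-positive")
})

test_that("probes collapse to the highest-intensity probe per gene and missing genes stay visible", {
  probes <- c("p1", "p2", "p3")
  ref <- matrix(c(100, 10, 50), nrow = 3, dimnames = list(probes, "R1"))
  tum <- matrix(c(200, 40, 50, 100, 20, 25), nrow = 3,
                dimnames = list(probes, c("T1", "T2")))
  pm <- data.frame(probe = c("p1", "p2", "p3"), gene = c("GA", "GA", "GB"))
  fc <- compute_fold_changes(tum, ref, probe_map = pm,
                             genes = c("GA", "GB", "GC"))
  expect_equal(unname(fc["GA", ]), c(2, 1))  # p1 wins (highest mean)
  expect_true(all(is.na(fc["GC", ])))        # no probe: no-information row
  expect_setequal(attr(fc, "informative"), c("GA", "GB"))
})

test_that("aberrant-expression thresholds are inclusive by default", {
  fc <- matrix(c(0.75, 0.76, 1.5, 1.49), nrow = 4,
               dimnames = list(c("L1", "L2", "G1", "G2"), "T1"))
  dirs <- c(L1 = "loss", L2 = "loss", G1 = "gain", G2 = "gain")
  flags <- flag_aberrant_expression(fc, dirs)
  expect_equal(unname(flags[, 1]), c(TRUE, FALSE, TRUE, FALSE))
  strict <- flag_aberrant_expression(fc, dirs,
                                     cna_thresholds(strict_fc = TRUE))
  expect_equal(unname(strict[, 1]), c(FALSE, FALSE, FALSE, FALSE))
})

test_that("the 35% frequency-of-involvement rule is inclusive", {
  mk_flags <- function(n_flagged, n) {
    matrix(c(rep(TRUE, n_flagged), rep(FALSE, n - n_flagged)), nrow = 1,
           dimnames = list("G", paste0("T", seq_len(n))))
  }
  dirs <- c(G = "loss")
  expect_equal(nrow(select_candidates(mk_flags(11, 31), dirs)), 1)  # 35.5%
  expect_equal(nrow(select_candidates(mk_flags(10, 31), dirs)), 0)  # 32.3%
  expect_equal(nrow(select_candidates(mk_flags(7, 20), dirs)), 1)   # 35.0%
  cand <- select_candidates(mk_flags(11, 31), dirs)
  expect_equal(cand$freq_discovery, 11 / 31)
  expect_equal(cand$freq_pct, 35)
  expect_equal(cand$status, "candidate")
})

test_that("validation confirms, rejects, or reports missing probes", {
  cand <- data.frame(gene = c("A", "B", "C"),
                     direction = c("loss", "loss", "gain"),
                     n_flagged = c(21, 24, 15), n_samples = 31,
                     freq_discovery = c(21, 24, 15) / 31,
                     freq_pct = round(100 * c(21, 24, 15) / 31),
                     status = "candidate", stringsAsFactors = FALSE)
  class(cand) <- c("candidate_drivers", "data.frame")
  val_fc <- rbind(A = c(rep(0.5, 13), rep(1, 7)),  # 65% underexpressed
                  B = rep(1, 20))                  # 0%
  colnames(val_fc) <- paste0("V", 1:20)
  out <- validate_candidates(cand, val_fc)
  expect_equal(out$status, c("confirmed", "not_confirmed", "no_information"))
  expect_equal(out$freq_validation, c(0.65, 0, NA))
  # confirmed implies both frequencies clear the threshold
  ok <- out$status == "confirmed"
  expect_true(all(out$freq_discovery[ok] >= 0.35 &
                    out$freq_validation[ok] >= 0.35))
})

test_that("tightening fold-change thresholds never raises flagged frequencies", {
  withr::with_seed(42, {
    fc <- matrix(stats::rlnorm(200, 0, 0.5), nrow = 20,
                 dimnames = list(sprintf("G%02d", 1:20), paste0("T", 1:10)))
  })
  dirs <- stats::setNames(rep(c("loss", "gain"), 10), rownames(fc))
  base <- rowSums(flag_aberrant_expression(fc, dirs, cna_thresholds()))
  tight <- rowSums(flag_aberrant_expression(
    fc, dirs, cna_thresholds(fc_under = 0.6, fc_over = 1.8)))
  expect_true(all(tight <= base))
})

test_that("planted drivers are selected and uncoupled genes rejected across seeds", {
  spec <- small_spec(n_chrom = 4, n_genes = 120, n_loci = 2)
  g <- generate_genome(spec, seed = 12)
  good <- 0L
  for (k in 1:20) {
    coh <- generate_cn_cohort(g, n_samples = 10, noise_sd = 0.1,
                              seed = 700 + k, n_loss_drivers = 3,
                              n_gain_drivers = 2)
    drv <- coh$truth$planted_drivers
    ex <- generate_expression(g, coh$truth, n_tumors = 31, n_reference = 3,
                              seed = 800 + k, probe_missing_prob = 0)
    # score every gene, assigning uncoupled genes an arbitrary direction
    dirs <- stats::setNames(rep(c("loss", "gain"),
                                length.out = nrow(g$genes)),
                            g$genes$symbol)
    dirs[drv$gene] <- drv$direction
    fc <- compute_fold_changes(ex$tumors, ex$reference,
                               genes = g$genes$symbol, normalize = TRUE)
    flags <- flag_aberrant_expression(fc, dirs)
    cand <- select_candidates(flags, dirs, n_samples = 31)
    ok_drivers <- all(drv$gene %in% cand$gene)
    ok_null <- !any(setdiff(g$genes$symbol, drv$gene) %in% cand$gene)
    if (ok_drivers && ok_null) good <- good + 1L
  }
  expect_gte(good, 18)  # >= 90% of 20 seeded runs
})
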