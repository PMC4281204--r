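# Aberration extraction, germline-CNV filtering rules, HFR computation.

test_that("adjacent same-state segments merge and the 3 Mb focal limit is inclusive", {
  calls <- seg_calls(sample_id = rep("S1", 4), chrom = "chr1",
                     start_bp = c(0, 1e6, 2e6, 2.5e6),
                     end_bp = c(1e6, 2e6, 2.5e6, 4e6),
                     state = c("neutral", "gain", "gain", "neutral"))
  ab <- extract_aberrations(calls)
  expect_equal(nrow(ab), 1)
  expect_equal(ab$start_bp, 1e6)
  expect_equal(ab$end_bp, 2.5e6)
  expect_equal(ab$size_bp, 1.5e6)
  expect_true(ab$focal)

  lims <- extract_aberrations(
    seg_calls(c("S1", "S2"), "chr1", c(0, 0), c(3000000, 3000001),
              c("loss", "loss")))
  expect_equal(lims$focal, c(TRUE, FALSE))  # 3 Mb in, 3 Mb + 1 bp out
})

test_that("catalog filtering removes focal aberrations by covered fraction", {
  catalog <- data.frame(chrom = "chr1", start_bp = c(100, 5000),
                        end_bp = c(400, 5010))
  ab <- make_ab(c("S1", "S2", "S3", "S4"), "chr1",
                start_bp = c(150, 1000, 0, 0),
                end_bp = c(350, 2000, 100000, 4e6),
                direction = c("loss", "gain", "loss", "loss"))
  # S1 fully inside a catalog CNV; S2 no overlap; S3 10/1000 covered;
  # S4 non-focal (4 Mb), never removed by this rule
  res <- filter_catalog_overlap(ab, catalog)
  expect_equal(res$removed$sample_id, "S1")
  expect_setequal(res$kept$sample_id, c("S2", "S3", "S4"))
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(ab))

  non_focal_inside <- make_ab("S5", "chr1", 0, 4e6, "loss")
  big_catalog <- data.frame(chrom = "chr1", start_bp = 0, end_bp = 5e6)
  expect_equal(nrow(filter_catalog_overlap(non_focal_inside,
                                           big_catalog)$removed), 0)
  # unsorted catalog tolerated with a warning
  expect_warning(
    filter_catalog_overlap(ab, catalog[2:1, ]),
    "not sorted")
})

test_that("bidirectional clusters need two recurrent directions to be removed", {
  # 2 gains + 2 losses overlapping: all removed
  ab1 <- make_ab(c("S1", "S2", "S3", "S4"), "chr1",
                 c(100, 150, 120, 130), c(500, 550, 520, 530),
                 c("gain", "gain", "loss", "loss"))
  r1 <- filter_bidirectional(ab1)
  expect_equal(nrow(r1$removed), 4)
  expect_equal(nrow(r1$kept), 0)
  # 2 gains + 1 loss: all kept (the published tables retain such regions)
  ab2 <- ab1[c(1, 2, 3), ]
  r2 <- filter_bidirectional(ab2)
  expect_equal(nrow(r2$removed), 0)
  # 3 losses only: kept
  ab3 <- make_ab(c("S1", "S2", "S3"), "chr1", c(0, 10, 20), c(100, 110, 120),
                 "loss")
  expect_equal(nrow(filter_bidirectional(ab3)$removed), 0)
  # same sample contributing both directions does not count twice
  ab4 <- make_ab(c("S1", "S1", "S2", "S3"), "chr1",
                 c(100, 150, 120, 130), c(500, 550, 520, 530),
                 c("gain", "gain", "loss", "loss"))
  expect_equal(nrow(filter_bidirectional(ab4)$removed), 0)
})

test_that("the HFR is the smallest maximal-depth overlap of focal aberrations", {
  # nested intervals: intersection
  nested <- make_ab(c("S1", "S2"), "chr1", c(100, 200), c(400, 300), "loss")
  h1 <- compute_hfrs(nested)
  expect_equal(nrow(h1), 1)
  expect_equal(c(h1$start_bp, h1$end_bp), c(200, 300))
  expect_equal(h1$focal_count, 2L)
  # non-transitive chain: the maximal-depth run
  chain <- make_ab(c("S1", "S2", "S3"), "chr1", c(0, 5, 10), c(10, 15, 20),
                   "gain")
  h2 <- compute_hfrs(chain)
  expect_equal(nrow(h2), 1)
  expect_equal(c(h2$start_bp, h2$end_bp), c(5, 15))
  expect_equal(h2$focal_count, 2L)
  # a single-sample aberration yields no HFR
  single <- make_ab("S1", "chr1", 0, 100, "gain")
  expect_equal(nrow(compute_hfrs(single)), 0)
  # two aberrations from the same sample are one sample, not recurrence
  same <- make_ab(c("S1", "S1"), "chr1", c(0, 50), c(100, 150), "gain")
  expect_equal(nrow(compute_hfrs(same)), 0)
})

test_that("HFR computation agrees with the brute-force depth oracle", {
  set.seed(99)
  for (rep in 1:20) {
    n <- sample(5:20, 1)
    start <- sample(0:800, n, replace = TRUE)
    len <- sample(20:200, n, replace = TRUE)
    df <- make_ab(paste0("S", sample(1:6, n, replace = TRUE)), "chr1",
                  start, start + len, "loss")
    h <- compute_hfrs(df)
    oracle <- brute_depth_run(df)
    if (oracle$depth < 2) {
      expect_equal(nrow(h), 0, info = sprintf("rep %d", rep))
    } else {
      # the deepest HFR must equal the oracle's leftmost maximal run
      top <- h[which.max(h$focal_count), ]
      expect_equal(top$focal_count, oracle$depth,
                   info = sprintf("rep %d", rep))
      expect_equal(c(top$start_bp, top$end_bp),
                   c(oracle$start_bp, oracle$end_bp),
                   info = sprintf("rep %d", rep))
    }
  }
})

test_that("filters are invariant to input row order", {
  set.seed(7)
  s <- sample(0:500, 12)
  ab <- make_ab(paste0("S", sample(1:5, 12, replace = TRUE)), "chr1",
                s, s + sample(50:300, 12, TRUE),
                sample(c("gain", "loss"), 12, TRUE))
  catalog <- data.frame(chrom = "chr1", start_bp = 200, end_bp = 400)
  key <- function(d) {
    d <- d[order(d$sample_id, d$start_bp, d$direction), ]
    rownames(d) <- NULL
    d
  }
  perm <- sample(nrow(ab))
  r1 <- filter_catalog_overlap(ab, catalog)
  r2 <- filter_catalog_overlap(ab[perm, ], catalog)
  expect_equal(key(r1$kept), key(r2$kept))
  b1 <- filter_bidirectional(ab)
  b2 <- filter_bidirectional(ab[perm, ])
  expect_equal(key(b1$kept), key(b2$kept))
  h1 <- compute_hfrs(ab)
  h2 <- compute_hfrs(ab[perm, ])
  expect_equal(h1[, c("chrom", "start_bp", "end_bp", "direction",
                      "focal_count")],
               h2[, c("chrom", "start_bp", "end_bp", "direction",
                      "focal_count")])
})

test_that("total counts require full same-direction coverage of the HFR", {
  focal <- make_ab(c("S1", "S2"), "chr1", c(100, 120), c(300, 320), "loss")
  broad <- make_ab(paste0("B", 1:6), "chr1", 0, 5e6, "loss")
  gain_cover <- make_ab("G1", "chr1", 0, 5e6, "gain")
  partial <- make_ab("P1", "chr1", 0, 200, "loss")
  all_ab <- rbind(focal, broad, gain_cover, partial)
  h <- count_total(compute_hfrs(focal), all_ab)
  expect_equal(h$focal_count, 2L)
  expect_equal(h$total_count, 8L)  # 2 focal + 6 whole-arm, same direction only
  # with no broad events total equals focal
  h2 <- count_total(compute_hfrs(focal), focal)
  expect_equal(h2$total_count, h2$focal_count)
  expect_true(all(h$total_count >= h$focal_count))
})

test_that("the filter ledger enforces the subtraction identity", {
  led <- make_ledger(550, 266, 145)
  expect_equal(led$n_retained, 139L)
  expect_equal(make_ledger(10, 0, 0)$n_retained, 10L)
  expect_error(make_ledger(5, 3, 3), "inconsistent")
  expect_error(make_ledger(-1, 0, 0), "non-negative")
})
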