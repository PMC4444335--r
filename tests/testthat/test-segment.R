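test_that("a constant profile yields a single segment", {
  s <- cbs_segment(rep(0.07, 40), seed = 1)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean, 0.07)
  expect_equal(s$n, 40L)
  expect_error(cbs_segment(rep(0, 10), min_width = 0), "min_width")
})

test_that("a planted step is found exactly at the boundary", {
  set.seed(2)
  x <- c(rnorm(20, 0, 0.01), rnorm(20, 0.2, 0.01))
  s <- cbs_segment(x, seed = 3)
  expect_equal(nrow(s), 2)
  expect_equal(s$end_idx[1], 20L)
  expect_equal(s$start_idx[2], 21L)
  expect_lt(abs(s$mean[1] - 0), 0.01)
  expect_lt(abs(s$mean[2] - 0.2), 0.01)
})

test_that("the first CBS split matches brute-force arc maximization (<= 30 points)", {
  set.seed(4)
  for (k in 1:25) {
    n <- sample(5:30, 1)
    x <- rnorm(n) + rep(c(0, sample(c(-1, 1), 1) * runif(1, 0, 2)),
                        c(floor(n / 2), ceiling(n / 2)))
    got <- cbs_best_arc(x, 2L)
    want <- brute_force_first_arc(x, 2)
    expect_equal(got$stat, want$stat, tolerance = 1e-10)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
  }
})

test_that("segments partition the profile and segmentation is idempotent and seeded", {
  set.seed(5)
  x <- c(rnorm(15, -0.1, 0.015), rnorm(12, 0.1, 0.015), rnorm(18, 0, 0.015))
  s1 <- cbs_segment(x, seed = 6)
  expect_equal(sum(s1$n), length(x))
  expect_equal(s1$start_idx[1], 1L)
  expect_equal(s1$end_idx[nrow(s1)], length(x))
  expect_true(all(s1$start_idx[-1] == s1$end_idx[-nrow(s1)] + 1L))
  expect_true(all(abs(diff(s1$mean)) > 1e-10))
  # determinism
  s2 <- cbs_segment(x, seed = 6)
  expect_identical(s1, s2)
  # re-segmenting any returned segment yields no further splits
  for (i in seq_len(nrow(s1))) {
    sub <- x[s1$start_idx[i]:s1$end_idx[i]]
    if (length(sub) >= 4) {
      expect_equal(nrow(cbs_segment(sub, seed = 6)), 1)
    }
  }
})

test_that("planted breakpoints are recovered with high precision and recall", {
  set.seed(7)
  n_pts <- 60
  tp <- 0L; fp <- 0L; fn <- 0L
  for (trial in 1:50) {
    # three breakpoints per chromosome (the simulator default), >= 5 apart
    cuts <- sort(sample(5:(n_pts - 5), 3))
    while (any(diff(cuts) < 5)) cuts <- sort(sample(5:(n_pts - 5), 3))
    steps <- sample(c(-1, 1), length(cuts), replace = TRUE) *
      runif(length(cuts), 0.05, 0.15)
    levels <- cumsum(c(0, steps))
    truth_idx <- cuts
    x <- rnorm(n_pts, 0, 0.015) +
      rep(levels, diff(c(0, cuts, n_pts)))
    s <- cbs_segment(x, n_permutations = 2000)
    found <- s$end_idx[-nrow(s)]
    hit <- vapply(truth_idx, function(b) any(abs(found - b) <= 1), logical(1))
    used <- vapply(found, function(f) any(abs(truth_idx - f) <= 1), logical(1))
    tp <- tp + sum(hit); fn <- fn + sum(!hit); fp <- fp + sum(!used)
  }
  precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  expect_gte(precision, 0.9)
  expect_gte(recall, 0.9)
})

test_that("breakpoints are classified in the telomere direction of their arm", {
  gm <- fixture_genome()  # centromere at 50 kb
  # two segments on the right arm: centromere side 0.15, telomere side -0.05
  segs_r <- data.frame(chrom = "chrT", start_idx = c(1L, 3L),
                       end_idx = c(2L, 4L), mean = c(0.15, -0.05), n = 2L,
                       span_start = c(55000, 75000),
                       span_end = c(65000, 95000))
  bp_r <- classify_breakpoints(segs_r, gm)
  expect_equal(bp_r$class, "Downstep")
  expect_equal(bp_r$delta, -0.2)
  expect_equal(bp_r$arm, "R")
  expect_equal(bp_r$region_start, 65000)
  expect_equal(bp_r$region_end, 75000)

  # mirror the profile onto the left arm: fitness increasing toward lower
  # coordinates is an Upstep, so reflection swaps no classes
  segs_l <- data.frame(chrom = "chrT", start_idx = c(1L, 3L),
                       end_idx = c(2L, 4L), mean = c(-0.05, 0.15), n = 2L,
                       span_start = c(5000, 35000),
                       span_end = c(25000, 45000))
  bp_l <- classify_breakpoints(segs_l, gm)
  expect_equal(bp_l$class, "Downstep")
  expect_equal(bp_l$delta, -0.2)
  expect_equal(bp_l$arm, "L")

  # a boundary whose flanking segments straddle the centromere is unclassified
  segs_x <- data.frame(chrom = "chrT", start_idx = c(1L, 3L),
                       end_idx = c(2L, 4L), mean = c(0.1, 0), n = 2L,
                       span_start = c(20000, 60000),
                       span_end = c(45000, 90000))
  segs_x$span_end[1] <- 55000  # left segment spans the centromere
  bp_x <- classify_breakpoints(segs_x, gm)
  expect_equal(bp_x$class, "cross_centromere")
})

test_that("breakpoint regions collect overlapped genes plus one centromeric gene", {
  gm <- fixture_genome()  # genes A..J tile 0..100 kb; centromere 50 kb
  # right arm: region between flanking Tamps covering genes H and I (70-90 kb)
  bp <- data.frame(chrom = "chrT", arm = "R", region_start = 70000,
                   region_end = 90000, class = "Downstep", delta = -0.1)
  expect_equal(breakpoint_region_genes(bp, gm), c("G", "H", "I"))
  expect_equal(breakpoint_region_genes(bp, gm, extra_centromeric = 0),
               c("H", "I"))
  expect_equal(breakpoint_region_genes(bp, gm, extra_centromeric = 2),
               c("F", "G", "H", "I"))
  # left arm: the centromeric side is at higher coordinates
  bpl <- data.frame(chrom = "chrT", arm = "L", region_start = 10000,
                    region_end = 30000, class = "Upstep", delta = 0.1)
  expect_equal(breakpoint_region_genes(bpl, gm), c("B", "C", "D"))
  expect_error(breakpoint_region_genes(
    data.frame(chrom = "chrT", arm = NA, region_start = 1, region_end = 2,
               class = "cross_centromere", delta = NA), gm), "classified")
})

test_that("profile construction sorts by genome position and validates ids", {
  gm <- fixture_genome()
  fit <- data.frame(tamp = c("I", "B", "G"), condition = "glucose",
                    fitness = c(0.1, 0.2, 0.3), se = 0.01, n = 20,
                    method = "mode", filter = "kept")
  prof <- build_profile(fit, gm, "glucose")
  expect_equal(prof$tamp, c("B", "G", "I"))
  expect_true(!is.unsorted(prof$init_position))
  expect_equal(nrow(build_profile(fit[0, ], gm, "glucose")), 0)
  # shuffled input gives the identical profile
  expect_equal(build_profile(fit[c(3, 1, 2), ], gm, "glucose"), prof)
  fit$tamp[1] <- "NOPE"
  expect_error(build_profile(fit, gm, "glucose"), "NOPE")
})
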