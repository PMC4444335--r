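test_that("planted landscapes are piecewise constant with controlled sharing", {
  gm <- toy_genome(n_chromosomes = 2, seed = 3)
  # no breakpoints -> constant landscape per condition
  l0 <- plant_landscape(gm, n_breakpoints = 0, seed = 1)
  for (cond in l0$conditions) {
    s <- landscape_value(l0, cond, gm$genes$chrom, gm$genes$start)
    expect_equal(length(unique(round(s[gm$genes$chrom == "chr1"], 12))), 1)
  }
  # full sharing -> identical breakpoint positions in all conditions
  l1 <- plant_landscape(gm, n_breakpoints = 4, sharing_fraction = 1, seed = 2)
  bp <- split(l1$breakpoints$position, l1$breakpoints$condition)
  expect_equal(bp[[1]], bp[[2]])
  expect_equal(bp[[2]], bp[[3]])
  # more breakpoints than candidate Tamp positions is an error
  expect_error(plant_landscape(gm, n_breakpoints = 1000, seed = 3),
               "more breakpoints")
  # lookup matches the segment table directly
  seg <- l1$segments[l1$segments$condition == "glucose" &
                       l1$segments$chrom == "chr1", ]
  mid <- (seg$start + seg$end) / 2
  expect_equal(landscape_value(l1, "glucose", rep("chr1", nrow(seg)), mid),
               seg$s)
})

test_that("pool frequencies conserve mass and follow exponential dynamics", {
  s <- c(a = 0, b = 0, c = 0)
  f <- pool_frequencies(s, 0:5)
  expect_true(all(abs(f - 1 / 3) < 1e-12))
  s2 <- c(a = 0.1, ref = 0)
  gens <- seq(0, 25, length.out = 10)
  f2 <- pool_frequencies(s2, gens)
  expect_equal(colSums(f2), rep(1, 10), tolerance = 1e-12,
               ignore_attr = TRUE)
  # log2 frequency-ratio slope of lineage a relative to ref equals s
  lr <- log2(f2["a", ] / f2["ref", ])
  expect_equal(unname(diff(lr) / diff(gens)), rep(0.1, 9), tolerance = 1e-12)
  expect_error(pool_frequencies(s2, gens, f0 = c(0, 1)), "zero initial")
})

test_that("noise-free two-strain competition recovers s = 0.1 exactly, and at depth 1e6 within 0.005", {
  # closed-form oracle: frequencies without sampling, exact OLS
  gens <- seq(0, 25, length.out = 10)
  f <- pool_frequencies(c(test = 0.1, ref = 0), gens)
  lr <- log2((f["test", ] / f["test", 1]))  # renormalized pool ratio
  fit <- fit_replicate_slope(log2(f["test", ] / f["test", 1]), gens)
  # raw pooled slope is s minus mean pool fitness; normalize against ref
  ref <- fit_replicate_slope(log2(f["ref", ] / f["ref", 1]), gens)
  expect_equal(fit$slope - ref$slope, 0.1, tolerance = 1e-10)

  # multinomial sampling at depth 1e6
  set.seed(99)
  est <- replicate(5, {
    cnt <- sapply(seq_along(gens), function(t) {
      stats::rmultinom(1, 1e6, f[, t])[, 1]
    })
    lr_t <- log2(((cnt["test", ] + 1) / colSums(cnt)) /
                   ((cnt["test", 1] + 1) / sum(cnt[, 1])))
    lr_r <- log2(((cnt["ref", ] + 1) / colSums(cnt)) /
                   ((cnt["ref", 1] + 1) / sum(cnt[, 1])))
    fit_replicate_slope(lr_t, gens)$slope -
      fit_replicate_slope(lr_r, gens)$slope
  })
  expect_lt(abs(mean(est) - 0.1), 0.005)
})

test_that("corrupt_replicates implements the strain-construction error model", {
  gm <- toy_genome(n_chromosomes = 1, chromosome_length = 100000,
                   genes_per_chromosome = 20, seed = 5)
  lp <- plant_landscape(gm, n_breakpoints = 1, conditions = "glucose",
                        sharing_fraction = 0, seed = 6)
  cfg <- sim_config(aberrant_prob = 0, background_jitter = c(0, 0),
                    mean_replicates = 10)
  truth <- make_truth(gm, lp, cfg, seed = 7)
  expect_false(any(truth$replicates$aberrant))
  # invariant: non-aberrant realized fitness equals landscape at init + background
  ti <- match(truth$fitness$tamp, truth$tamps$id)
  want <- landscape_value(lp, "glucose", truth$tamps$chrom[ti],
                          truth$tamps$init_position[ti]) +
    truth$tamps$background[ti]
  expect_equal(truth$fitness$s, want)

  # with aberration on, truncated replicates take the landscape value at
  # their truncation point (direct landscape lookup oracle)
  t2 <- corrupt_replicates(truth, prob = 1, unrelated_prob = 0, seed = 8)
  expect_true(all(t2$replicates$aberrant))
  ri <- match(paste(t2$fitness$tamp, t2$fitness$replicate_bc),
              paste(t2$replicates$tamp, t2$replicates$replicate_bc))
  ti2 <- match(t2$fitness$tamp, t2$tamps$id)
  want2 <- landscape_value(lp, "glucose", t2$tamps$chrom[ti2],
                           t2$replicates$realized_pos[ri]) +
    t2$tamps$background[ti2]
  expect_equal(t2$fitness$s, want2)
  # truncation points are telomere-ward of the initiation position
  reps <- t2$replicates
  arm <- t2$tamps$arm[match(reps$tamp, t2$tamps$id)]
  init <- t2$tamps$init_position[match(reps$tamp, t2$tamps$id)]
  expect_true(all(ifelse(arm == "R", reps$realized_pos >= init,
                         reps$realized_pos <= init)))
})

test_that("simulated pools are seed-deterministic and conserve counts", {
  gm <- toy_genome(n_chromosomes = 1, chromosome_length = 60000,
                   genes_per_chromosome = 10, seed = 9)
  lp <- plant_landscape(gm, n_breakpoints = 1, conditions = "glucose",
                        sharing_fraction = 0, seed = 10)
  cfg <- sim_config(mean_replicates = 5, tech_replicates = 2, depth = 2e4,
                    n_timepoints = 4)
  truth <- make_truth(gm, lp, cfg, seed = 11)
  a <- simulate_pool(truth, conditions = "glucose", seed = 12)
  b <- simulate_pool(truth, conditions = "glucose", seed = 12)
  expect_identical(a, b)
  tot <- tapply(a$counts$count, a$counts$sample_id, sum)
  expect_true(all(tot == cfg$depth))
  expect_equal(nrow(a$samples), 2 * 4)
})

test_that("pairwise GFP trajectories follow s * ln(2) per generation", {
  tr0 <- simulate_pairwise(0, noise = FALSE)
  expect_equal(log(tr0$dark / tr0$gfp), rep(0, 5))
  tr <- simulate_pairwise(0.1, generations = c(0, 5, 10, 15), noise = FALSE)
  expect_equal(log(tr$dark / tr$gfp), c(0, 0.3466, 0.6931, 1.0397),
               tolerance = 1e-4)
  set.seed(1)
  trn <- simulate_pairwise(0.533, seed = 2)
  expect_true(all(trn$dark + trn$gfp == 5e4))
})

test_that("simulated aCGH profiles match the mixture model", {
  gm <- toy_genome(n_chromosomes = 1, chromosome_length = 100000,
                   genes_per_chromosome = 10, seed = 13)
  reg <- data.frame(chrom = "chr1", start = 60000, end = 100000, copy = 3)
  p0 <- simulate_acgh(gm, reg, f = 0, noise_sd = 0, seed = 14)
  expect_true(all(p0$log2ratio == 0))
  p1 <- simulate_acgh(gm, reg, f = 1, noise_sd = 0, seed = 15)
  hit <- p1$position >= 60000
  expect_equal(unique(p1$log2ratio[hit]), log2(1.5))
  expect_true(all(p1$log2ratio[!hit] == 0))
  expect_true(!is.unsorted(p1$position))
  p13 <- simulate_acgh(gm, reg, f = 0.13, noise_sd = 0, seed = 16)
  expect_equal(unique(p13$log2ratio[p13$position >= 60000]), log2(2.13 / 2))
})
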