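make_small_pool <- function() {
  gm <- toy_genome(n_chromosomes = 1, chromosome_length = 60000,
                   genes_per_chromosome = 8, seed = 21)
  lp <- plant_landscape(gm, n_breakpoints = 1, conditions = "glucose",
                        sharing_fraction = 0, seed = 22)
  cfg <- sim_config(mean_replicates = 3, tech_replicates = 1, depth = 2500,
                    n_timepoints = 4)
  truth <- make_truth(gm, lp, cfg, seed = 23)
  counts <- simulate_pool(truth, conditions = "glucose", seed = 24)
  list(genome = gm, truth = truth, counts = counts)
}

test_that("demultiplexing assigns every read once and conserves totals", {
  sc <- barcode_scheme()
  mux <- data.frame(sample_id = c("s1", "s2"),
                    barcode = c("AAAAAA", "CCCCCC"))
  body <- strrep("G", sc$tamp_len + sc$replicate_len)
  reads <- c(paste0("AAAAAA", body), paste0("CCCCCC", body),
             paste0("TTTTTT", body))
  d <- demultiplex(reads, sc, mux)
  expect_length(d$assigned$s1, 1)
  expect_length(d$assigned$s2, 1)
  expect_equal(d$unassigned, 1)
  expect_equal(length(unlist(d$assigned)) + d$unassigned, length(reads))
  # ambiguous table at the configured radius errors at load time
  sc1 <- barcode_scheme(multiplex_mismatch = 1)
  mux_close <- data.frame(sample_id = c("s1", "s2"),
                          barcode = c("AAAAAA", "AAAAAC"))
  expect_error(demultiplex(reads, sc1, mux_close), "ambiguous")
  expect_error(demultiplex(reads, sc,
                           data.frame(sample_id = c("a", "b"),
                                      barcode = c("AAAAAA", "AAAAAA"))),
               "duplicate")
})

test_that("synthesized reads demultiplex and count back to the exact emission", {
  p <- make_small_pool()
  sr <- synthesize_reads(p$counts, p$truth, seed = 25)
  sc <- barcode_scheme()
  d <- demultiplex(sr$reads, sc, sr$multiplex_table)
  expect_equal(d$unassigned, 0)
  cm <- count_samples(d, p$counts$samples, sc, sr$tamp_bc_table)
  a <- cm$counts[order(cm$counts$sample_id, cm$counts$tamp,
                       cm$counts$replicate_bc), ]
  b <- p$counts$counts[order(p$counts$counts$sample_id, p$counts$counts$tamp,
                             p$counts$counts$replicate_bc), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b[, names(a)])
  expect_true(all(cm$samples$unknown == 0))
  # FASTQ round trip preserves the reads
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(sr$reads[1:50], fq)
  expect_equal(read_reads_fastq(fq), sr$reads[1:50], ignore_attr = TRUE)
})

test_that("count_barcodes applies the min-read floor and tallies unknowns", {
  sc <- barcode_scheme(tamp_len = 4, replicate_len = 2)
  tab <- data.frame(barcode = c("ACGT", "TTTT"), tamp = c("T1", "T2"))
  reads <- c(rep(paste0("AAAAAA", "ACGT", "GG"), 5),
             paste0("AAAAAA", "TTTT", "CC"),
             paste0("AAAAAA", "GGGG", "CC"))
  r <- count_barcodes(reads, sc, tab, min_reads = 2)
  expect_equal(r$counts$tamp, "T1")
  expect_equal(r$counts$count, 5L)
  expect_equal(r$unknown, 1L)
  expect_equal(r$dropped, 1L)
  empty <- count_barcodes(character(0), sc, tab)
  expect_equal(nrow(empty$counts), 0)
})

test_that("trajectories use pseudocounted frequency ratios against t0", {
  samples <- data.frame(sample_id = c("a0", "a1"), condition = "glucose",
                        tech_rep = 1L, timepoint = 0:1,
                        generations = c(0, 10), depth = 1e4)
  counts <- data.frame(tamp = "T1", replicate_bc = "r1",
                       sample_id = c("a0", "a1"), count = c(99L, 199L))
  filler <- data.frame(tamp = "T2", replicate_bc = "r2",
                       sample_id = c("a0", "a1"),
                       count = c(10000L - 99L, 10000L - 199L))
  cm <- structure(list(counts = rbind(counts, filler), samples = samples),
                  class = "count_matrix")
  tr <- to_trajectories(cm, pseudocount = 1)
  x <- tr[tr$gene == "T1", ]
  expect_equal(x$log2_ratio[x$timepoint == 0], 0)
  expect_equal(x$log2_ratio[x$timepoint == 1], 1.0)  # log2(200/100)
  # constant frequencies -> all ratios 0
  cm2 <- cm
  cm2$counts$count <- c(99L, 99L, 9901L, 9901L)
  tr2 <- to_trajectories(cm2)
  expect_true(all(tr2$log2_ratio == 0))
  # pseudocount monotonicity: raising one count raises that ratio
  cm3 <- cm
  cm3$counts$count[2] <- 200L
  tr3 <- to_trajectories(cm3)
  expect_gt(tr3$log2_ratio[tr3$gene == "T1" & tr3$timepoint == 1],
            x$log2_ratio[x$timepoint == 1])
})

test_that("trajectory CSV schema round-trips and rejects malformed input", {
  p <- make_small_pool()
  tr <- to_trajectories(p$counts)
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f)
  back <- read_trajectory_csv(f)
  key <- function(t) paste(t$gene, t$mer, t$replicate, t$timepoint)
  tr_cmp <- tr[order(key(tr)), c("gene", "mer", "timepoint", "generations",
                                 "log2_ratio")]
  bk_cmp <- back[order(key(back)), c("gene", "mer", "timepoint",
                                     "generations", "log2_ratio")]
  rownames(tr_cmp) <- rownames(bk_cmp) <- NULL
  expect_equal(bk_cmp, tr_cmp, tolerance = 1e-12)
  # write -> read -> write is byte-identical (numeric round trip)
  f2 <- tempfile(fileext = ".csv")
  write_trajectory_csv(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # NA cells shorten the trajectory; bad cells are located
  hdr <- paste(c("gene", "mer", "replicate", paste0("t", 1:9),
                 paste0("g", 1:9)), collapse = ",")
  row <- paste(c("T1", "r1", "1", "0.1", "0.2", "0.3", "0.4", "0.5", "0.6",
                 rep("NA", 3), 2, 4, 6, 8, 10, 12, rep("NA", 3)),
               collapse = ",")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c(hdr, row), f3)
  t3 <- read_trajectory_csv(f3)
  expect_equal(nrow(t3), 7)  # t0 + six observed points
  writeLines(c(sub("^gene", "genes", hdr), row), f3)
  expect_error(read_trajectory_csv(f3), "malformed header")
  writeLines(c(hdr, sub("0.3", "oops", row)), f3)
  expect_error(read_trajectory_csv(f3), "row 2, column t3")
})

test_that("pool complexity reports the share of Tamps above the read floor", {
  p <- make_small_pool()
  pc <- pool_complexity(p$counts, targeted = p$truth$tamps$id)
  expect_equal(pc$n_targeted, nrow(p$truth$tamps))
  expect_true(pc$n_above <= pc$n_targeted)
  # a Tamp absent from the pool counts below the floor
  pc2 <- pool_complexity(p$counts, targeted = c(p$truth$tamps$id, "ABSENT"))
  expect_equal(pc2$n_above, pc$n_above)
  expect_equal(pc2$n_targeted, pc$n_targeted + 1)
})
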