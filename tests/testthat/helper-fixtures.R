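# Fixed tiny genome: one 100 kb chromosome, centromere at 50 kb, five
# abutting 10 kb genes on each arm (A..E left, F..J right in genomic order).
fixture_genome <- function() {
  genes <- data.frame(
    id = LETTERS[1:10],
    chrom = "chrT",
    start = seq(0, 90000, by = 10000),
    end = seq(10000, 100000, by = 10000),
    strand = rep(c("+", "-"), 5),
    stringsAsFactors = FALSE)
  genome_model(data.frame(name = "chrT", length = 100000),
               c(chrT = 50000), genes)
}

# Independent brute-force oracle for the first CBS split: scans every arc
# (i, j] with the same width constraints and returns the max standardized
# mean-difference statistic. Written against the definition, not the
# package internals.
brute_force_first_arc <- function(x, min_width = 2) {
  n <- length(x)
  s <- stats::sd(x)
  best <- list(stat = -Inf, i = NA, j = NA)
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      if (i == 0 && j == n) next
      k <- j - i
      if (k < min_width || n - k < min_width) next
      if (i > 0 && i < min_width) next
      if (j < n && n - j < min_width) next
      inside <- x[(i + 1):j]
      outside <- x[-((i + 1):j)]
      t <- abs(mean(inside) - mean(outside)) /
        (s * sqrt(1 / k + 1 / (n - k)))
      if (t > best$stat + 1e-12) best <- list(stat = t, i = i, j = j)
    }
  }
  best
}

# Synthetic fitness_segments table from explicit boundaries: `cuts` are the
# span_start values of the 2nd..kth segments; means one per segment.
fake_segments <- function(chrom, cuts, means, chrom_len = 100000) {
  starts <- c(0, cuts)
  data.frame(chrom = chrom,
             start_idx = seq_along(means) * 2 - 1,
             end_idx = seq_along(means) * 2,
             mean = means, n = 2,
             span_start = starts,
             span_end = c(cuts, chrom_len) - 1,
             stringsAsFactors = FALSE)
}
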