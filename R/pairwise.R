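#' Relative fitness from a pairwise GFP competition
#'
#' OLS slope (free intercept) of `ln(dark/GFP)` versus generations. The
#' paper-style fitness is the natural-log slope; `log2 = TRUE` divides by
#' ln(2) so pooled (log2-based) and pairwise estimates share units on common
#' truth. Time points with a zero count are dropped with a warning.
#'
#' @param generations sampled generations.
#' @param dark,gfp cell counts of the unmarked test strain and the
#'   GFP-marked control.
#' @param log2 report the slope in per-generation log2 units.
#' @return list `fitness`, `se`, `n`.
#' @export
gfp_competition_fitness <- function(generations, dark, gfp, log2 = FALSE) {
  keep <- dark > 0 & gfp > 0
  if (any(!keep)) {
    warning(sum(!keep), " timepoint(s) with zero counts dropped")
  }
  stop_if_not(sum(keep) >= 3, "fewer than 3 usable timepoints")
  f <- ols_slope(generations[keep], log(dark[keep] / gfp[keep]))
  k <- if (log2) log(2) else 1
  list(fitness = f$slope / k, se = f$se / k, n = f$n)
}

#' Doubling time from a batch-culture growth curve
#'
#' Regression of log2(density) on time (hours) over an exponential-phase
#' window; doubling time is the reciprocal slope, with SE by the delta
#' method.
#'
#' @param time_h time in hours.
#' @param density culture density (positive).
#' @param window optional `c(from, to)` in hours restricting the fit.
#' @return list `hours`, `se`, `n`.
#' @export
doubling_time <- function(time_h, density, window = NULL) {
  keep <- density > 0
  if (!is.null(window)) keep <- keep & time_h >= window[1] & time_h <= window[2]
  stop_if_not(sum(keep) >= 3, "need >= 3 points in the growth window")
  f <- ols_slope(time_h[keep], log2(density[keep]))
  stop_if_not(f$slope > 0, "no growth detected")
  list(hours = 1 / f$slope,
       se = if (is.na(f$se)) NA_real_ else f$se / f$slope^2,
       n = f$n)
}

#' Population frequency of an aneuploid event from aCGH
#'
#' The population copy number over a region is
#' `c_hat = ploidy * 2^mean(log2 ratio)`; with clonal copy number `c`
#' (by default the population copy number rounded up to the next integer
#' above baseline) the frequency of the carrier sub-population is
#' `f = (c_hat - baseline) / (c - baseline)`, clamped to `[0, 1]`.
#' Frequencies below the detection limit (default 6%) are flagged.
#'
#' @param log2ratios per-probe log2 ratios over the region (>= 1 probe), or
#'   an aCGH profile data.frame (`chrom`, `position`, `log2ratio`) together
#'   with `region`.
#' @param region optional list/data.frame `chrom`, `start`, `end` selecting
#'   probes from a profile.
#' @param baseline baseline copy number (default 2).
#' @param clonal clonal copy number, or `NULL` for the rounding rule.
#' @param ploidy base ploidy (default 2).
#' @param detection_limit minimum reportable frequency.
#' @return list `frequency`, `population_copy`, `clonal_copy`,
#'   `below_detection`.
#' @export
acgh_population_frequency <- function(log2ratios, region = NULL, baseline = 2,
                                      clonal = NULL, ploidy = 2,
                                      detection_limit = 0.06) {
  if (is.data.frame(log2ratios)) {
    stop_if_not(!is.null(region), "a profile needs a region")
    p <- log2ratios
    hit <- p$chrom == region$chrom & p$position >= region$start &
      p$position < region$end
    log2ratios <- p$log2ratio[hit]
  }
  stop_if_not(length(log2ratios) >= 1, "region contains no probe")
  c_hat <- ploidy * 2^mean(log2ratios)
  if (is.null(clonal)) {
    clonal <- max(ceiling(c_hat), baseline + 1)
  }
  stop_if_not(clonal != baseline,
              "clonal copy equals baseline: mixture frequency undefined")
  f <- (c_hat - baseline) / (clonal - baseline)
  f <- min(max(f, 0), 1)
  list(frequency = f, population_copy = c_hat, clonal_copy = clonal,
       below_detection = f < detection_limit)
}
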