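#' Union of fitness regions across conditions
#'
#' Per chromosome, the boundaries of every condition's segmentation are
#' pooled; the sorted unique boundaries partition the chromosome into the
#' minimum set of regions whose fitness differs from a neighbor in at least
#' one condition. Each region is annotated with the mean fitness of the
#' segment covering it in every condition.
#'
#' A segment's boundary coordinate is taken as the initiation position of
#' the first Tamp of the telomere-ward (next) segment; the first segment is
#' extended to the chromosome start and the last to its end, so segments
#' cover the chromosome.
#'
#' @param condition_segments named list (condition -> `fitness_segments`
#'   table from [segment_profile()]); all over one genome.
#' @param genome a [genome_model()].
#' @return data.frame `chrom`, `start`, `end`, plus one fitness column per
#'   condition (`fitness.<condition>`).
#' @export
union_regions <- function(condition_segments, genome) {
  stop_if_not(length(condition_segments) >= 1, "need at least one condition")
  conds <- names(condition_segments)
  chroms <- unique(unlist(lapply(condition_segments, function(s) s$chrom)))
  chroms <- chroms[order(match(chroms, genome$chromosomes$name))]
  out <- list()
  for (cn in chroms) {
    len <- chrom_length(genome, cn)
    cuts <- sort(unique(unlist(lapply(condition_segments, function(s) {
      sc <- s[s$chrom == cn, , drop = FALSE]
      sc <- sc[order(sc$start_idx), , drop = FALSE]
      if (nrow(sc) < 2) numeric(0) else sc$span_start[-1]
    }))))
    bounds <- c(0, cuts, len)
    reg <- data.frame(chrom = cn, start = bounds[-length(bounds)],
                      end = bounds[-1], stringsAsFactors = FALSE)
    for (cond in conds) {
      sc <- condition_segments[[cond]]
      sc <- sc[sc$chrom == cn, , drop = FALSE]
      sc <- sc[order(sc$start_idx), , drop = FALSE]
      # covering segment: last segment whose extended start <= region start
      seg_start <- c(0, sc$span_start[-1])
      j <- findInterval(reg$start, seg_start)
      reg[[paste0("fitness.", cond)]] <- sc$mean[pmax(j, 1)]
    }
    out[[cn]] <- reg
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Classify union regions by common fitness effect
#'
#' A region is universally advantageous if its fitness exceeds `threshold`
#' in every condition, universally detrimental if below `-threshold` in
#' every condition, and condition-specific otherwise.
#'
#' @param regions output of [union_regions()].
#' @param threshold common-effect cutoff (default 0.05, i.e. 5%).
#' @return `regions` with an added `effect` column.
#' @export
common_effect_regions <- function(regions, threshold = 0.05) {
  fcols <- grep("^fitness\\.", names(regions), value = TRUE)
  stop_if_not(length(fcols) >= 1, "regions carry no fitness columns")
  f <- as.matrix(regions[fcols])
  stop_if_not(!anyNA(f), "every region needs a fitness in every condition")
  regions$effect <- ifelse(
    apply(f > threshold, 1, all), "universally_advantageous",
    ifelse(apply(f < -threshold, 1, all), "universally_detrimental",
           "condition_specific"))
  regions
}

#' Contrast single-gene amplification fitness at Downsteps vs Upsteps
#'
#' For each breakpoint, the mean single-gene amplification fitness over its
#' region genes; then an unpaired two-tailed t test between Downstep means
#' and Upstep means (pooled variance by default, Welch optional).
#'
#' @param downstep_genes,upstep_genes lists of character vectors (one per
#'   breakpoint, from [breakpoint_region_genes()]).
#' @param gene_fitness named numeric vector: gene id -> single-gene
#'   amplification fitness. Breakpoints with no covered gene are skipped
#'   with a warning.
#' @param welch use Welch's t test instead of pooled variance.
#' @return list `downstep_means`, `upstep_means`, `t`, `df`, `p`.
#' @export
step_gene_contrast <- function(downstep_genes, upstep_genes, gene_fitness,
                               welch = FALSE) {
  bp_means <- function(sets, label) {
    m <- vapply(sets, function(g) {
      v <- gene_fitness[intersect(g, names(gene_fitness))]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    if (anyNA(m)) {
      warning(sum(is.na(m)), " ", label,
              " breakpoint(s) lack fitness coverage; skipped")
    }
    m[!is.na(m)]
  }
  d <- bp_means(downstep_genes, "Downstep")
  u <- bp_means(upstep_genes, "Upstep")
  stop_if_not(length(d) >= 2 && length(u) >= 2,
              "each class needs >= 2 covered breakpoints")
  if (stats::var(c(d, u)) == 0) {
    # degenerate: identical means everywhere
    return(list(downstep_means = unname(d), upstep_means = unname(u),
                t = 0, df = length(d) + length(u) - 2, p = 1))
  }
  tt <- stats::t.test(d, u, var.equal = !welch)
  list(downstep_means = unname(d), upstep_means = unname(u),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Published CEN-plasmid "mean + 2 SD" evidence thresholds
#'
#' Per-condition fitness cutoffs for single-gene amplifications that are
#' extreme relative to the low-copy (CEN) plasmid fitness distribution but
#' below the stricter outlier definition: phosphate < -0.096 or > 0.097;
#' glucose < -0.052 or > 0.050. (Under sulfate limitation the outlier list
#' already subsumes mean + 2 SD genes, so no separate cutoff is defined.)
#'
#' @return data.frame `condition`, `lower`, `upper`.
#' @export
cen_mean2sd_thresholds <- function() {
  data.frame(condition = c("phosphate", "glucose"),
             lower = c(-0.096, -0.052),
             upper = c(0.097, 0.050), stringsAsFactors = FALSE)
}

#' Genes passing a lower/upper extremity screen
#'
#' @param gene_fitness named numeric vector, gene -> fitness.
#' @param lower,upper thresholds: keep genes with fitness below `lower` or
#'   above `upper`.
#' @return character vector of gene ids.
#' @export
extreme_fitness_genes <- function(gene_fitness, lower, upper) {
  names(gene_fitness)[gene_fitness < lower | gene_fitness > upper]
}

#' Filter Downstep genes against evidence lists to call driver candidates
#'
#' A Downstep gene becomes a candidate driver for a condition if it appears
#' in at least one of the condition's evidence lists (union, not
#' intersection): genes up-regulated in evolved clones, CEN-plasmid fitness
#' outliers, CEN mean + 2 SD genes, or genes mutated in evolved populations.
#' Missing evidence lists are skipped with a warning.
#'
#' @param downsteps data.frame `condition`, `downstep_id`, `gene` (one row
#'   per gene per Downstep region).
#' @param evidence nested list: `evidence[[condition]]` is a named list of
#'   character vectors with any of the names `upregulated`, `cen_outlier`,
#'   `cen_mean_2sd`, `mutated`.
#' @return data.frame `gene`, `condition`, `downstep_id` and logical
#'   evidence-flag columns; rows only for candidates (>= 1 flag set).
#' @export
filter_driver_candidates <- function(downsteps, evidence) {
  flags <- c("upregulated", "cen_outlier", "cen_mean_2sd", "mutated")
  out <- downsteps
  for (fl in flags) out[[fl]] <- FALSE
  for (cond in unique(downsteps$condition)) {
    ev <- evidence[[cond]]
    if (is.null(ev)) {
      warning("no evidence lists for condition '", cond, "'")
      next
    }
    missing <- setdiff(flags, names(ev))
    if (length(missing)) {
      warning("condition '", cond, "' lacks evidence list(s): ",
              paste(missing, collapse = ", "))
    }
    rows <- out$condition == cond
    for (fl in intersect(flags, names(ev))) {
      out[[fl]][rows] <- out$gene[rows] %in% ev[[fl]]
    }
  }
  keep <- Reduce(`|`, out[flags])
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Share of Downsteps covered by at least one candidate driver
#'
#' @param candidates output of [filter_driver_candidates()].
#' @param downstep_ids all Downstep ids for the condition(s) considered.
#' @return list `fraction`, `percent` (rounded), `n_covered`, `n_downsteps`.
#' @export
downstep_coverage <- function(candidates, downstep_ids) {
  covered <- unique(candidates$downstep_id)
  n <- sum(downstep_ids %in% covered)
  list(fraction = n / length(downstep_ids),
       percent = round(100 * n / length(downstep_ids)),
       n_covered = n, n_downsteps = length(downstep_ids))
}

#' Predict the fitness of a telomeric amplicon from the landscape
#'
#' The predicted fitness is the mean of the segment containing the
#' amplicon's centromere-proximal boundary (an amplicon initiating at x is
#' exactly the entity whose fitness the landscape reports at x). The number
#' of candidate driver genes is estimated by counting the classified
#' Downsteps whose region lies within the amplicon.
#'
#' @param genome a [genome_model()].
#' @param chrom chromosome name.
#' @param init_position centromere-proximal boundary of the amplicon (bp).
#' @param segments per-condition `fitness_segments`
#'   (named list, as for [union_regions()]).
#' @param breakpoints per-condition breakpoint tables
#'   (from [classify_breakpoints()]).
#' @param amplicon optional explicit interval `c(start, end)`; must touch a
#'   chromosome end and have `init_position` as its centromere-proximal
#'   boundary. Defaults to the Tamp interval implied by `init_position`.
#' @return data.frame `condition`, `predicted_fitness`, `n_downsteps`,
#'   `amp_start`, `amp_end`.
#' @export
predict_amplicon <- function(genome, chrom, init_position, segments,
                             breakpoints, amplicon = NULL) {
  len <- chrom_length(genome, chrom)
  arm <- arm_of(genome, chrom, init_position)
  amp <- amplicon %||% if (arm == "R") c(init_position, len) else
    c(0, init_position)
  stop_if_not(amp[1] == 0 || amp[2] == len,
              "amplicon must touch a chromosome end")
  stop_if_not(init_position %in% amp,
              "init_position must be the amplicon's centromere-proximal boundary")
  out <- do.call(rbind, lapply(names(segments), function(cond) {
    sc <- segments[[cond]]
    sc <- sc[sc$chrom == chrom, , drop = FALSE]
    sc <- sc[order(sc$start_idx), , drop = FALSE]
    stop_if_not(nrow(sc) > 0, "no segments on %s for %s", chrom, cond)
    seg_start <- c(0, sc$span_start[-1])
    j <- max(findInterval(init_position, seg_start), 1)
    bp <- breakpoints[[cond]]
    bp <- bp[bp$chrom == chrom & bp$class == "Downstep" & !is.na(bp$arm) &
               bp$arm == arm, , drop = FALSE]
    n_down <- sum(pmin(bp$region_start, bp$region_end) >= amp[1] &
                    pmax(bp$region_start, bp$region_end) <= amp[2])
    data.frame(condition = cond, predicted_fitness = sc$mean[j],
               n_downsteps = n_down, amp_start = amp[1], amp_end = amp[2],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pleiotropy as between-condition variance in fitness
#'
#' @param fitness fitness of one entity across conditions (>= 2 values).
#' @return sample variance (n - 1 denominator).
#' @export
pleiotropy_variance <- function(fitness) {
  stop_if_not(length(fitness) >= 2, "need fitness in >= 2 conditions")
  stats::var(fitness)
}
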