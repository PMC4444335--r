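#' Genome-ordered fitness profile
#'
#' Orders kept Tamp fitness values along the genome for one condition.
#'
#' @param fitness per-Tamp fitness table (see [tamp_fitness()]); only rows
#'   with `filter == "kept"` and finite fitness are used.
#' @param genome a [genome_model()].
#' @param condition condition label to extract.
#' @param init_at how Tamp ids map to initiation positions (see
#'   [tamp_table()]).
#' @return a `fitness_profile` data.frame: `chrom`, `init_position`, `tamp`,
#'   `fitness`, `se`, sorted by chromosome then position.
#' @export
build_profile <- function(fitness, genome, condition, init_at = "start") {
  x <- fitness[fitness$condition == condition & fitness$filter == "kept" &
                 is.finite(fitness$fitness), , drop = FALSE]
  unknown <- setdiff(x$tamp, genome$genes$id)
  stop_if_not(length(unknown) == 0, "Tamp id(s) not in genome: %s",
              paste(utils::head(unknown, 5), collapse = ", "))
  tt <- tamp_table(genome, x$tamp, init_at = init_at)
  out <- data.frame(chrom = tt$chrom, init_position = tt$init_position,
                    tamp = x$tamp, fitness = x$fitness, se = x$se,
                    stringsAsFactors = FALSE)
  out <- out[order(match(out$chrom, genome$chromosomes$name),
                   out$init_position), ]
  rownames(out) <- NULL
  class(out) <- c("fitness_profile", "data.frame")
  out
}

#' Circular binary segmentation of an ordered value vector
#'
#' Recursive CBS: at each stage the arc maximizing the standardized
#' mean-difference statistic between arc and complement is found; the split
#' is accepted if its within-segment permutation p-value is below `alpha`
#' and every resulting segment holds at least `min_width` points. Adjacent
#' segments with numerically equal means are merged afterwards. Ties in the
#' maximizing arc break to the smallest start index, then the smallest arc.
#'
#' @param values ordered numeric values (one chromosome's profile).
#' @param alpha significance level for a split (default 0.05).
#' @param min_width minimum points per segment (default 2).
#' @param n_permutations permutations per tested split (default 10000).
#' @param seed optional RNG seed (permutations use R's RNG).
#' @return data.frame `start_idx`, `end_idx` (1-based, inclusive), `mean`,
#'   `n`; segments partition `seq_along(values)`.
#' @export
cbs_segment <- function(values, alpha = 0.05, min_width = 2,
                        n_permutations = 10000, seed = NULL) {
  stop_if_not(min_width >= 1, "min_width must be >= 1")
  stop_if_not(length(values) >= 2, "need at least 2 points")
  stop_if_not(!anyNA(values), "profile values must be non-missing")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  bounds <- integer(0)  # accepted cut points (after index k)
  stack <- list(c(1L, n))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    lo <- seg[1]; hi <- seg[2]
    m <- hi - lo + 1L
    if (m < 2L * min_width) next
    x <- values[lo:hi]
    arc <- cbs_best_arc(x, min_width)
    if (is.na(arc$i)) next
    pt <- cbs_perm_test(x, min_width, arc$stat, n_permutations, alpha)
    if (pt$p >= alpha) next
    cuts <- c(if (arc$i > 0) lo + arc$i - 1L,
              if (arc$j < m) lo + arc$j - 1L)
    bounds <- c(bounds, cuts)
    pieces <- sort(unique(c(lo - 1L, cuts, hi)))
    for (k in seq_len(length(pieces) - 1L)) {
      stack[[length(stack) + 1L]] <- c(pieces[k] + 1L, pieces[k + 1L])
    }
  }
  bounds <- sort(unique(bounds))
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, n)
  segs <- data.frame(start_idx = starts, end_idx = ends)
  segs$mean <- vapply(seq_len(nrow(segs)), function(i) {
    mean(values[segs$start_idx[i]:segs$end_idx[i]])
  }, numeric(1))
  segs$n <- segs$end_idx - segs$start_idx + 1L
  # prune: merge adjacent segments with indistinguishable means
  i <- 1L
  while (i < nrow(segs)) {
    if (abs(segs$mean[i] - segs$mean[i + 1]) < 1e-10) {
      a <- segs$start_idx[i]; b <- segs$end_idx[i + 1]
      segs$start_idx[i] <- a; segs$end_idx[i] <- b
      segs$mean[i] <- mean(values[a:b])
      segs$n[i] <- b - a + 1L
      segs <- segs[-(i + 1), , drop = FALSE]
    } else i <- i + 1L
  }
  rownames(segs) <- NULL
  segs
}

#' Segment a genome-ordered fitness profile per chromosome
#'
#' @param profile a `fitness_profile` (see [build_profile()]).
#' @inheritParams cbs_segment
#' @return a `fitness_segments` data.frame: `chrom`, `start_idx`, `end_idx`
#'   (indices within the chromosome's profile), `span_start`, `span_end`
#'   (init positions of the first/last Tamp), `mean`, `n`.
#' @export
segment_profile <- function(profile, alpha = 0.05, min_width = 2,
                            n_permutations = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- do.call(rbind, lapply(unique(profile$chrom), function(cn) {
    p <- profile[profile$chrom == cn, , drop = FALSE]
    if (nrow(p) < 2) {
      s <- data.frame(start_idx = 1L, end_idx = nrow(p),
                      mean = mean(p$fitness), n = nrow(p))
    } else {
      s <- cbs_segment(p$fitness, alpha = alpha, min_width = min_width,
                       n_permutations = n_permutations)
    }
    data.frame(chrom = cn, s,
               span_start = p$init_position[s$start_idx],
               span_end = p$init_position[s$end_idx],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("fitness_segments", "data.frame")
  out
}

segment_arm <- function(genome, chrom, span_start, span_end) {
  a1 <- arm_of(genome, chrom, span_start)
  a2 <- arm_of(genome, chrom, span_end)
  ifelse(a1 == a2, a1, NA_character_)
}

#' Classify segment boundaries as Upsteps or Downsteps
#'
#' For each boundary between adjacent segments whose flanking segments lie
#' on the same arm, the step is evaluated in the telomere direction of that
#' arm: `delta` = telomere-side mean - centromere-side mean. `delta > 0` is
#' an Upstep, `delta < 0` a Downstep. Boundaries involving a segment that
#' spans the centromere are left unclassified (`cross_centromere`). The
#' breakpoint region is the interval between the flanking Tamps' initiation
#' positions.
#'
#' @param segments a `fitness_segments` table (see [segment_profile()]).
#' @param genome a [genome_model()].
#' @return data.frame `chrom`, `arm`, `region_start`, `region_end`, `delta`,
#'   `class` (`Upstep` / `Downstep` / `cross_centromere`),
#'   `centromere_side_mean`, `telomere_side_mean`.
#' @export
classify_breakpoints <- function(segments, genome) {
  out <- list()
  for (cn in unique(segments$chrom)) {
    s <- segments[segments$chrom == cn, , drop = FALSE]
    s <- s[order(s$start_idx), , drop = FALSE]
    if (nrow(s) < 2) next
    arm <- segment_arm(genome, cn, s$span_start, s$span_end)
    for (k in seq_len(nrow(s) - 1)) {
      left <- s[k, ]; right <- s[k + 1, ]
      a <- if (!is.na(arm[k]) && !is.na(arm[k + 1]) &&
               arm[k] == arm[k + 1]) arm[k] else NA_character_
      if (is.na(a)) {
        cls <- "cross_centromere"; delta <- NA_real_
        cen_mean <- NA_real_; tel_mean <- NA_real_
      } else if (a == "R") {
        # telomere side = higher coordinates = right segment
        delta <- right$mean - left$mean
        cen_mean <- left$mean; tel_mean <- right$mean
        cls <- if (delta > 0) "Upstep" else "Downstep"
      } else {
        delta <- left$mean - right$mean
        cen_mean <- right$mean; tel_mean <- left$mean
        cls <- if (delta > 0) "Upstep" else "Downstep"
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = cn, arm = a, region_start = left$span_end,
        region_end = right$span_start, delta = delta, class = cls,
        centromere_side_mean = cen_mean, telomere_side_mean = tel_mean,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), arm = character(),
                      region_start = numeric(), region_end = numeric(),
                      delta = numeric(), class = character(),
                      centromere_side_mean = numeric(),
                      telomere_side_mean = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes assigned to a breakpoint region
#'
#' All genes overlapping the interval between the flanking Tamps'
#' initiation positions, plus `extra_centromeric` additional genes on the
#' centromere side of the region (compensating for segmentation
#' insensitivity at the boundary).
#'
#' @param breakpoint one row of [classify_breakpoints()] output (classified;
#'   not `cross_centromere`).
#' @param genome a [genome_model()].
#' @param extra_centromeric number of extra centromere-side genes
#'   (default 1).
#' @return character vector of gene ids, in genomic order.
#' @export
breakpoint_region_genes <- function(breakpoint, genome,
                                    extra_centromeric = 1) {
  stop_if_not(breakpoint$class %in% c("Upstep", "Downstep"),
              "breakpoint must be classified to an arm")
  lo <- min(breakpoint$region_start, breakpoint$region_end)
  hi <- max(breakpoint$region_start, breakpoint$region_end)
  g <- genes_in_interval(genome, breakpoint$chrom, lo, hi, "any_overlap")
  ids <- g$id
  all_g <- genome$genes[genome$genes$chrom == breakpoint$chrom, , drop = FALSE]
  all_g <- all_g[order(all_g$start), , drop = FALSE]
  if (extra_centromeric > 0) {
    if (breakpoint$arm == "R") {
      before <- all_g$id[all_g$end <= lo & !(all_g$id %in% ids)]
      extra <- utils::tail(before, extra_centromeric)
      ids <- c(extra, ids)
    } else {
      after <- all_g$id[all_g$start >= hi & !(all_g$id %in% ids)]
      extra <- utils::head(after, extra_centromeric)
      ids <- c(ids, extra)
    }
  }
  ids
}

#' Write segments and breakpoints as BED-like TSVs
#'
#' Segments: `chrom`, `start`, `end`, `mean_fitness`, `n_points`;
#' breakpoints: `chrom`, `boundary_start`, `boundary_end`, `class`, `delta`.
#' Coordinates are 1-based inclusive on disk.
#'
#' @param segments,breakpoints outputs of [segment_profile()] /
#'   [classify_breakpoints()].
#' @param path file path.
#' @name landscape_io
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(
    data.frame(chrom = segments$chrom, start = segments$span_start + 1,
               end = segments$span_end + 1, mean_fitness = segments$mean,
               n_points = segments$n),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname landscape_io
#' @export
write_breakpoints_tsv <- function(breakpoints, path) {
  utils::write.table(
    data.frame(chrom = breakpoints$chrom,
               boundary_start = breakpoints$region_start + 1,
               boundary_end = breakpoints$region_end + 1,
               class = breakpoints$class, delta = breakpoints$delta),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
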