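#' Simulation configuration for pooled chemostat competitions
#'
#' Defaults reflect the genome-wide screen design: an average of 26
#' biological replicates per Tamp, 3 technical-replicate chemostats,
#' ~25 generations of steady-state competition sampled at 10 time points,
#' a 50% rate of aberrant strain construction, and neutral host-strain
#' backgrounds in the range -0.05 to 0.04. Read depth per sample is a free
#' parameter (the assay only fixes lane totals).
#'
#' @param mean_replicates mean biological replicates per Tamp (Poisson).
#' @param tech_replicates number of technical-replicate chemostats.
#' @param total_generations generations of competition.
#' @param n_timepoints sampled time points (generations spaced evenly from 0).
#' @param depth reads per barseq sample.
#' @param aberrant_prob probability a replicate's amplicon is mis-built
#'   (0.5 genome-wide; the targeted chrII pool ran nearer 0.2).
#' @param unrelated_prob given aberrant, probability the defect is an
#'   unrelated large aneuploid event rather than a truncation.
#' @param unrelated_sd fitness-offset SD for unrelated aneuploid events.
#' @param background_jitter range of neutral host-strain fitness added per
#'   Tamp.
#' @param dilution_rate chemostat dilution rate (per hour, informational).
#' @param bottleneck_size optional effective population size for a binomial
#'   bottleneck between sampled generations; `Inf` (default) disables it.
#' @param reference_id lineage id of the neutral reference strain carried in
#'   every simulated pool.
#' @return a `sim_config` list.
#' @export
sim_config <- function(mean_replicates = 26, tech_replicates = 3,
                       total_generations = 25, n_timepoints = 10,
                       depth = 1e6, aberrant_prob = 0.5,
                       unrelated_prob = 0.05, unrelated_sd = 0.1,
                       background_jitter = c(-0.05, 0.04),
                       dilution_rate = 0.17, bottleneck_size = Inf,
                       reference_id = "REF_NEUTRAL") {
  cfg <- list(mean_replicates = mean_replicates,
              tech_replicates = as.integer(tech_replicates),
              total_generations = total_generations,
              n_timepoints = as.integer(n_timepoints),
              depth = depth, aberrant_prob = aberrant_prob,
              unrelated_prob = unrelated_prob, unrelated_sd = unrelated_sd,
              background_jitter = background_jitter,
              dilution_rate = dilution_rate,
              bottleneck_size = bottleneck_size,
              reference_id = reference_id)
  stop_if_not(cfg$depth > 0, "depth must be positive")
  stop_if_not(aberrant_prob >= 0 && aberrant_prob <= 1,
              "aberrant_prob must be in [0,1]")
  stop_if_not(unrelated_prob >= 0 && unrelated_prob <= 1,
              "unrelated_prob must be in [0,1]")
  stop_if_not(n_timepoints >= 2, "need at least 2 timepoints")
  class(cfg) <- "sim_config"
  cfg
}

sampled_generations <- function(config) {
  seq(0, config$total_generations, length.out = config$n_timepoints)
}

#' Plant a piecewise-constant fitness landscape
#'
#' Per condition, chromosome coordinates are cut at breakpoints placed on
#' candidate Tamp initiation positions (gene starts) and each resulting
#' segment is assigned a constant selection coefficient. A configurable
#' fraction of breakpoints is shared across conditions (same positions);
#' the remainder are condition-private, emulating the predominantly
#' condition-specific architecture seen in nutrient-limited screens.
#'
#' @param genome a [genome_model()].
#' @param n_breakpoints breakpoints per chromosome per condition.
#' @param conditions condition labels.
#' @param effect_sd SD of segment selection coefficients (drawn N(0, sd)).
#' @param sharing_fraction fraction of breakpoints shared by all conditions.
#' @param seed optional RNG seed.
#' @return object of class `planted_landscape` with `segments`
#'   (condition, chrom, start, end, s) and `breakpoints`
#'   (condition, chrom, position).
#' @export
plant_landscape <- function(genome, n_breakpoints = 3,
                            conditions = c("glucose", "phosphate", "sulfate"),
                            effect_sd = 0.1, sharing_fraction = 0.06,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stop_if_not(n_breakpoints >= 0, "n_breakpoints must be >= 0")
  stop_if_not(sharing_fraction >= 0 && sharing_fraction <= 1,
              "sharing_fraction must be in [0,1]")
  segs <- list(); bps <- list()
  for (cn in genome$chromosomes$name) {
    cand <- sort(unique(genome$genes$start[genome$genes$chrom == cn]))
    cand <- cand[cand > 0]
    stop_if_not(n_breakpoints <= length(cand),
                "more breakpoints than Tamp positions on %s", cn)
    n_shared <- round(sharing_fraction * n_breakpoints)
    shared <- sort(sample(cand, n_shared))
    for (cond in conditions) {
      priv_pool <- setdiff(cand, shared)
      priv <- sort(sample(priv_pool, n_breakpoints - n_shared))
      cuts <- sort(unique(c(shared, priv)))
      bounds <- c(0, cuts, chrom_length(genome, cn))
      s <- stats::rnorm(length(bounds) - 1, 0, effect_sd)
      segs[[length(segs) + 1]] <- data.frame(
        condition = cond, chrom = cn,
        start = bounds[-length(bounds)], end = bounds[-1], s = s,
        stringsAsFactors = FALSE)
      if (length(cuts)) {
        bps[[length(bps) + 1]] <- data.frame(
          condition = cond, chrom = cn, position = cuts,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(conditions = conditions,
                 segments = do.call(rbind, segs),
                 breakpoints = if (length(bps)) do.call(rbind, bps) else
                   data.frame(condition = character(), chrom = character(),
                              position = numeric())),
            class = "planted_landscape")
}

#' Evaluate a planted landscape at genomic positions
#'
#' @param landscape a [plant_landscape()] object.
#' @param condition condition label (scalar).
#' @param chrom,position vectors of positions to evaluate.
#' @return numeric selection coefficients.
#' @export
landscape_value <- function(landscape, condition, chrom, position) {
  seg <- landscape$segments[landscape$segments$condition == condition, ,
                            drop = FALSE]
  stop_if_not(nrow(seg) > 0, "unknown condition '%s'", condition)
  out <- rep(NA_real_, length(position))
  for (cn in unique(chrom)) {
    sc <- seg[seg$chrom == cn, , drop = FALSE]
    idx <- which(chrom == cn)
    j <- findInterval(position[idx], sc$start)
    stop_if_not(all(j >= 1 & position[idx] < max(sc$end)),
                "position outside landscape on %s", cn)
    out[idx] <- sc$s[j]
  }
  out
}

#' Build simulation ground truth: Tamps, replicates and realized fitness
#'
#' Draws the biological-replicate structure (Poisson replicate counts,
#' unique replicate barcodes, per-Tamp neutral background) and applies the
#' strain-construction error model via [corrupt_replicates()]. A replicate's
#' realized fitness is the landscape value at its Tamp's initiation position
#' plus the Tamp's host background; aberrant replicates instead take the
#' landscape value at a truncated extent (or an unrelated offset).
#'
#' @param genome a [genome_model()].
#' @param landscape a [plant_landscape()] object.
#' @param config a [sim_config()].
#' @param tamp_genes genes at which Tamps initiate (default all).
#' @param init_at passed to [tamp_table()].
#' @param seed optional RNG seed.
#' @return object of class `simulation_truth` with `tamps`, `replicates`
#'   (tamp, replicate_bc, aberrant, unrelated, realized_pos) and `fitness`
#'   (tamp, replicate_bc, condition, s).
#' @export
make_truth <- function(genome, landscape, config = sim_config(),
                       tamp_genes = genome$genes$id,
                       init_at = "start", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tamps <- tamp_table(genome, tamp_genes, init_at = init_at)
  tamps$tamp_bc <- random_barcodes(nrow(tamps), 20)
  tamps$background <- stats::runif(nrow(tamps),
                                   config$background_jitter[1],
                                   config$background_jitter[2])
  n_rep <- pmax(1L, stats::rpois(nrow(tamps), config$mean_replicates))
  reps <- data.frame(
    tamp = rep(tamps$id, n_rep),
    replicate_bc = random_barcodes(sum(n_rep), 12),
    stringsAsFactors = FALSE)
  truth <- structure(list(genome = genome, landscape = landscape,
                          config = config, tamps = tamps,
                          replicates = reps, fitness = NULL),
                     class = "simulation_truth")
  corrupt_replicates(truth, prob = config$aberrant_prob,
                     unrelated_prob = config$unrelated_prob)
}

#' Apply the strain-construction error model to replicate lineages
#'
#' Each replicate is independently flagged aberrant with probability `prob`.
#' An aberrant replicate's amplicon initiates at the right place but is
#' truncated at a uniformly chosen gene boundary telomere-ward of the
#' initiating gene, so its realized fitness is the landscape value at the
#' truncation point; with probability `unrelated_prob` the defect is instead
#' an unrelated large aneuploid event, modeled as a Gaussian fitness offset.
#'
#' @param truth a `simulation_truth` (from [make_truth()]).
#' @param prob aberrant probability in `[0,1]`.
#' @param unrelated_prob probability an aberrant replicate carries an
#'   unrelated event instead of a truncation.
#' @param seed optional RNG seed.
#' @return `truth` with `replicates$aberrant`, `replicates$realized_pos`
#'   and the `fitness` table rebuilt.
#' @export
corrupt_replicates <- function(truth, prob = truth$config$aberrant_prob,
                               unrelated_prob = truth$config$unrelated_prob,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stop_if_not(prob >= 0 && prob <= 1, "prob must be in [0,1]")
  genome <- truth$genome
  reps <- truth$replicates
  tamps <- truth$tamps
  ti <- match(reps$tamp, tamps$id)
  reps$aberrant <- stats::runif(nrow(reps)) < prob
  reps$unrelated <- reps$aberrant & (stats::runif(nrow(reps)) < unrelated_prob)
  reps$realized_pos <- tamps$init_position[ti]
  # truncation point: uniform over gene starts strictly telomere-ward of init
  trunc_idx <- which(reps$aberrant & !reps$unrelated)
  for (k in trunc_idx) {
    t <- tamps[ti[k], ]
    gs <- genome$genes$start[genome$genes$chrom == t$chrom]
    cand <- if (t$arm == "R") gs[gs > t$init_position] else
      gs[gs < t$init_position]
    if (length(cand)) {
      reps$realized_pos[k] <- if (length(cand) == 1) cand else sample(cand, 1)
    }
  }
  offsets <- stats::rnorm(nrow(reps), 0, truth$config$unrelated_sd)
  fit <- do.call(rbind, lapply(truth$landscape$conditions, function(cond) {
    s <- landscape_value(truth$landscape, cond,
                         tamps$chrom[ti], reps$realized_pos) +
      tamps$background[ti]
    s[reps$unrelated] <- s[reps$unrelated] + offsets[reps$unrelated]
    data.frame(tamp = reps$tamp, replicate_bc = reps$replicate_bc,
               condition = cond, s = s, stringsAsFactors = FALSE)
  }))
  truth$replicates <- reps
  truth$fitness <- fit
  truth
}

#' Deterministic pooled-competition lineage frequencies
#'
#' Selection acts as exponential ratio dynamics: lineage frequencies follow
#' `f_i(g) = f_i(0) 2^(s_i g)`, renormalized at every sampled generation.
#' All stochasticity lives in the multinomial read sampling of
#' [simulate_pool()] (and the optional bottleneck).
#'
#' @param s named vector of per-lineage selection coefficients
#'   (log2-frequency-ratio change per generation).
#' @param generations generations at which frequencies are reported.
#' @param f0 initial frequencies (default uniform); must all be positive.
#' @return matrix lineages x generations of frequencies, columns summing
#'   to 1.
#' @export
pool_frequencies <- function(s, generations, f0 = NULL) {
  n <- length(s)
  f0 <- f0 %||% rep(1 / n, n)
  stop_if_not(all(f0 > 0), "zero initial frequency for some lineage")
  f0 <- f0 / sum(f0)
  out <- vapply(generations, function(g) {
    w <- f0 * 2^(s * g)
    w / sum(w)
  }, numeric(n))
  rownames(out) <- names(s)
  colnames(out) <- as.character(generations)
  out
}

#' Simulate pooled barseq competition experiments
#'
#' For each condition and technical-replicate chemostat, the deterministic
#' lineage frequencies from [pool_frequencies()] are sampled multinomially
#' at the configured read depth at every time point. A neutral reference
#' lineage (`config$reference_id`, s = 0) is carried in every pool.
#'
#' @param truth a `simulation_truth`.
#' @param conditions conditions to run (default all in the landscape).
#' @param config a [sim_config()] (default the truth's).
#' @param seed optional RNG seed.
#' @return a `count_matrix`: list with `counts` (tamp, replicate_bc,
#'   sample_id, count) and `samples` (sample_id, condition, tech_rep,
#'   timepoint, generations, depth).
#' @export
simulate_pool <- function(truth, conditions = truth$landscape$conditions,
                          config = truth$config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gens <- sampled_generations(config)
  n_ref <- max(2L, as.integer(round(config$mean_replicates)))
  ref_bc <- random_barcodes(n_ref, 12)
  counts <- list(); samples <- list()
  for (cond in conditions) {
    fit <- truth$fitness[truth$fitness$condition == cond, , drop = FALSE]
    key <- c(paste(fit$tamp, fit$replicate_bc, sep = "\r"),
             paste(config$reference_id, ref_bc, sep = "\r"))
    s <- c(fit$s, rep(0, n_ref))
    names(s) <- key
    freq <- pool_frequencies(s, gens)
    for (tech in seq_len(config$tech_replicates)) {
      f <- freq[, 1]
      for (t in seq_along(gens)) {
        if (t > 1) {
          # advance deterministically from the previous sampled generation
          w <- f * 2^(s * (gens[t] - gens[t - 1]))
          f <- w / sum(w)
          if (is.finite(config$bottleneck_size)) {
            n <- stats::rmultinom(1, config$bottleneck_size, f)[, 1]
            f <- (n + 1e-9) / sum(n + 1e-9)
          }
        }
        sample_id <- sprintf("%s_T%d_t%d", cond, tech, t - 1L)
        cnt <- stats::rmultinom(1, config$depth, f)[, 1]
        keep <- cnt > 0
        id <- names(s)[keep]
        counts[[length(counts) + 1]] <- data.frame(
          tamp = sub("\r.*$", "", id),
          replicate_bc = sub("^.*\r", "", id),
          sample_id = sample_id, count = cnt[keep],
          stringsAsFactors = FALSE)
        samples[[length(samples) + 1]] <- data.frame(
          sample_id = sample_id, condition = cond, tech_rep = tech,
          timepoint = t - 1L, generations = gens[t], depth = config$depth,
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(counts = do.call(rbind, counts),
                 samples = do.call(rbind, samples)),
            class = "count_matrix")
}

#' Simulate a pairwise GFP competition trajectory
#'
#' A dark (unmarked) test strain competes against a GFP-marked neutral
#' control from a 50/50 start; `ln(dark/GFP)` drifts linearly with slope
#' `s * ln(2)` (fitness `s` is in per-generation log2 units, as in the
#' pooled assay). With `noise = FALSE` the expected (continuous) cell counts
#' are returned so closed-form checks hold exactly; otherwise dark counts
#' are binomially sampled at each time point.
#'
#' @param s relative fitness of the dark strain (per generation, log2 units).
#' @param generations sampled generations.
#' @param total_cells cells scored per time point.
#' @param noise logical; binomial count sampling.
#' @param seed optional RNG seed.
#' @return data.frame with `generations`, `dark`, `gfp`.
#' @export
simulate_pairwise <- function(s, generations = c(0, 5, 10, 15, 20),
                              total_cells = 5e4, noise = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  odds <- exp(s * log(2) * generations)
  p <- odds / (1 + odds)
  dark <- if (noise) stats::rbinom(length(p), total_cells, p) else
    total_cells * p
  data.frame(generations = generations, dark = dark, gfp = total_cells - dark)
}

#' Simulate an aCGH profile of a mixed (sub-clonal) population
#'
#' Per-probe expected log2 ratio is
#' `log2((f * c_clone + (1 - f) * c_base) / ploidy)` inside the clone's
#' aberrant regions and 0 elsewhere, plus Gaussian probe noise.
#'
#' @param genome a [genome_model()].
#' @param clone_regions data.frame `chrom`, `start`, `end`, `copy` giving the
#'   clone's integer copy number over its aberrant regions; elsewhere the
#'   clone matches the base ploidy.
#' @param f population frequency of the clone, in `[0,1]`.
#' @param ploidy base ploidy (default 2).
#' @param probe_spacing probe spacing in bp.
#' @param noise_sd per-probe Gaussian noise SD.
#' @param seed optional RNG seed.
#' @return data.frame `chrom`, `position`, `log2ratio` (positions sorted
#'   within chromosome).
#' @export
simulate_acgh <- function(genome, clone_regions, f, ploidy = 2,
                          probe_spacing = 1000, noise_sd = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stop_if_not(f >= 0 && f <= 1, "f must be in [0,1]")
  out <- do.call(rbind, lapply(seq_len(nrow(genome$chromosomes)), function(i) {
    cn <- genome$chromosomes$name[i]
    pos <- seq(floor(probe_spacing / 2), genome$chromosomes$length[i],
               by = probe_spacing)
    copy <- rep(ploidy, length(pos))
    cr <- clone_regions[clone_regions$chrom == cn, , drop = FALSE]
    for (k in seq_len(nrow(cr))) {
      hit <- pos >= cr$start[k] & pos < cr$end[k]
      copy[hit] <- cr$copy[k]
    }
    expected <- log2((f * copy + (1 - f) * ploidy) / ploidy)
    data.frame(chrom = cn, position = pos,
               log2ratio = expected + stats::rnorm(length(pos), 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
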