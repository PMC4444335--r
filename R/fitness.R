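#' Per-replicate relative fitness by log-ratio regression
#'
#' The slope of log2 frequency ratio versus generations, fitted by ordinary
#' least squares with a free intercept (t0 sampling noise enters every
#' ratio, so the intercept is not forced through zero). Trajectories with
#' fewer than `min_points` non-missing points get status `"NA"`.
#'
#' @param log2_ratios numeric vector (missing values allowed).
#' @param generations matching generations, strictly increasing.
#' @param min_points minimum informative points for a slope (default 3).
#' @return list with `slope`, `se`, `rse`, `n`, `status` (`"ok"`/`"NA"`).
#' @export
fit_replicate_slope <- function(log2_ratios, generations, min_points = 3) {
  stop_if_not(all(diff(generations) > 0),
              "generations must be strictly increasing")
  keep <- !is.na(log2_ratios)
  n <- sum(keep)
  if (n < min_points) {
    return(list(slope = NA_real_, se = NA_real_, rse = NA_real_,
                n = n, status = "NA"))
  }
  f <- ols_slope(generations[keep], log2_ratios[keep])
  list(slope = f$slope, se = f$se, rse = f$rse, n = n, status = "ok")
}

#' Fit every trajectory of a trajectory table
#'
#' @param traj a `trajectory_table` (see [to_trajectories()]).
#' @param min_points passed to [fit_replicate_slope()].
#' @return data.frame with one row per (condition, gene, mer, replicate):
#'   `slope`, `se`, `n`, `status`.
#' @export
fit_replicate_slopes <- function(traj, min_points = 3) {
  key <- paste(traj$condition, traj$gene, traj$mer, traj$replicate,
               sep = "\r")
  o <- order(key, traj$timepoint)
  traj <- traj[o, ]; key <- key[o]
  idx <- split(seq_len(nrow(traj)), key)
  rows <- lapply(idx, function(i) {
    f <- fit_replicate_slope(traj$log2_ratio[i], traj$generations[i],
                             min_points)
    data.frame(condition = traj$condition[i[1]], gene = traj$gene[i[1]],
               mer = traj$mer[i[1]], replicate = traj$replicate[i[1]],
               slope = f$slope, se = f$se, n = f$n, status = f$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Average technical replicates into biological-replicate fitness
#'
#' The unweighted mean of `ok` slopes across the technical-replicate
#' chemostats of one biological replicate (a lineage tracked in only one or
#' two chemostats still yields a value); `NA` if none are ok.
#'
#' @param rep_fits output of [fit_replicate_slopes()].
#' @return data.frame `condition`, `gene`, `mer`, `slope`, `n_tech`,
#'   `status`.
#' @export
combine_technical <- function(rep_fits) {
  key <- paste(rep_fits$condition, rep_fits$gene, rep_fits$mer, sep = "\r")
  idx <- split(seq_len(nrow(rep_fits)), key)
  out <- do.call(rbind, lapply(idx, function(i) {
    ok <- rep_fits$status[i] == "ok"
    data.frame(condition = rep_fits$condition[i[1]],
               gene = rep_fits$gene[i[1]], mer = rep_fits$mer[i[1]],
               slope = if (any(ok)) mean(rep_fits$slope[i][ok]) else NA_real_,
               n_tech = sum(ok),
               status = if (any(ok)) "ok" else "NA",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Normalize fitness values to a reference strain
#'
#' Shifts all values so the reference is exactly 0; pairwise differences
#' are preserved and the operation is idempotent.
#'
#' @param fitness data.frame with an id column and a `fitness` column.
#' @param reference id of the reference entry.
#' @param id_col name of the id column (default `"tamp"`).
#' @return `fitness` with the `fitness` column shifted.
#' @export
normalize_to_reference <- function(fitness, reference, id_col = "tamp") {
  i <- which(fitness[[id_col]] == reference)
  stop_if_not(length(i) == 1, "reference '%s' not present exactly once",
              reference)
  ref <- fitness$fitness[i]
  stop_if_not(is.finite(ref), "reference fitness is NA")
  fitness$fitness <- fitness$fitness - ref
  fitness
}

#' Replicate-variance filter
#'
#' Tamps whose biological replicates disagree strongly are dropped: sample
#' SD of replicate fitness above `sd_threshold` gives status
#' `dropped_variance`; fewer than 2 ok replicates gives
#' `dropped_insufficient`.
#'
#' @param bio_fits output of [combine_technical()] for one condition, or any
#'   data.frame with `gene`, `slope`, `status`.
#' @param sd_threshold SD cutoff (default 0.05; see
#'   [calibrate_variance_threshold()]).
#' @return data.frame `gene`, `n`, `sd`, `filter`
#'   (`kept` / `dropped_variance` / `dropped_insufficient`).
#' @export
variance_filter <- function(bio_fits, sd_threshold = 0.05) {
  ok <- bio_fits[bio_fits$status == "ok", , drop = FALSE]
  idx <- split(seq_len(nrow(ok)), ok$gene)
  out <- do.call(rbind, lapply(names(idx), function(g) {
    v <- ok$slope[idx[[g]]]
    s <- if (length(v) >= 2) stats::sd(v) else NA_real_
    data.frame(gene = g, n = length(v), sd = s,
               filter = if (length(v) < 2) "dropped_insufficient"
                        else if (s > sd_threshold) "dropped_variance"
                        else "kept",
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Calibrate the variance-filter threshold to a target exclusion rate
#'
#' The screen's published pipeline reports only the outcome of its
#' replicate-variance filter (roughly a fifth of Tamps removed); this helper
#' picks the SD cutoff that removes a chosen fraction of Tamps.
#'
#' @param bio_fits as in [variance_filter()].
#' @param target_fraction fraction of Tamps to exclude (default 0.2).
#' @return the SD threshold (numeric scalar).
#' @export
calibrate_variance_threshold <- function(bio_fits, target_fraction = 0.2) {
  ok <- bio_fits[bio_fits$status == "ok", , drop = FALSE]
  sds <- tapply(ok$slope, ok$gene, function(v) {
    if (length(v) >= 2) stats::sd(v) else NA_real_
  })
  sds <- sds[!is.na(sds)]
  stats::quantile(sds, 1 - target_fraction, names = FALSE, type = 7)
}

#' Mode of a distribution by Gaussian kernel density estimation
#'
#' Silverman ("nrd0") bandwidth, argmax on a 512-point grid spanning
#' `[min - bw, max + bw]`. Degenerate inputs (all equal, or a single value)
#' return that value.
#'
#' @param x numeric values.
#' @param bw bandwidth (default Silverman's rule).
#' @param n_grid grid size.
#' @return the mode (numeric scalar).
#' @export
kde_mode <- function(x, bw = NULL, n_grid = 512) {
  if (length(unique(x)) == 1) return(x[1])
  bw <- bw %||% stats::bw.nrd0(x)
  d <- stats::density(x, bw = bw, n = n_grid, from = min(x) - bw,
                      to = max(x) + bw)
  d$x[which.max(d$y)]
}

#' Aggregate biological replicates into a per-Tamp fitness
#'
#' With more than `mode_cutoff` replicates the Tamp fitness is the mode of
#' the replicate fitness distribution (KDE argmax), which is robust to the
#' mis-constructed replicates the error model produces; with `mode_cutoff`
#' or fewer, the arithmetic mean. SE is sample SD / sqrt(n) in both cases
#' (a seeded bootstrap SE is available for the mode).
#'
#' @param values biological-replicate fitness values (ok only).
#' @param mode_cutoff replicate count above which the mode is used
#'   (default 15).
#' @param bootstrap_se logical; bootstrap the mode's SE (200 resamples).
#' @param seed seed for the bootstrap.
#' @return list `fitness`, `se`, `n`, `method` (`"mode"`/`"mean"`).
#' @export
aggregate_tamp <- function(values, mode_cutoff = 15, bootstrap_se = FALSE,
                           seed = NULL) {
  values <- values[!is.na(values)]
  n <- length(values)
  stop_if_not(n >= 1, "no replicate fitness values")
  method <- if (n > mode_cutoff) "mode" else "mean"
  fitness <- if (method == "mode") kde_mode(values) else mean(values)
  se <- if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_
  if (method == "mode" && bootstrap_se) {
    if (!is.null(seed)) set.seed(seed)
    boot <- replicate(200, kde_mode(sample(values, n, replace = TRUE)))
    se <- stats::sd(boot)
  }
  list(fitness = fitness, se = se, n = n, method = method)
}

#' Full per-Tamp fitness pipeline for one or more conditions
#'
#' Runs slope fitting, technical-replicate averaging, the replicate-variance
#' filter and mode/mean aggregation, with optional reference normalization.
#'
#' @param traj a `trajectory_table`.
#' @param sd_threshold variance-filter cutoff; `NULL` calibrates per
#'   condition via [calibrate_variance_threshold()].
#' @param mode_cutoff see [aggregate_tamp()].
#' @param min_points see [fit_replicate_slope()].
#' @param reference optional reference Tamp id; if given, per-Tamp fitness
#'   is shifted so the reference sits at 0 (dropped from the output).
#' @return data.frame `tamp`, `condition`, `fitness`, `se`, `n`, `method`,
#'   `filter` (dropped Tamps kept with NA fitness and their filter status).
#' @export
tamp_fitness <- function(traj, sd_threshold = 0.05, mode_cutoff = 15,
                         min_points = 3, reference = NULL) {
  slopes <- fit_replicate_slopes(traj, min_points = min_points)
  bio <- combine_technical(slopes)
  out <- list()
  for (cond in unique(bio$condition)) {
    b <- bio[bio$condition == cond, , drop = FALSE]
    thr <- sd_threshold %||% calibrate_variance_threshold(b)
    filt <- variance_filter(b, thr)
    res <- do.call(rbind, lapply(seq_len(nrow(filt)), function(i) {
      g <- filt$gene[i]
      if (filt$filter[i] != "kept") {
        return(data.frame(tamp = g, condition = cond, fitness = NA_real_,
                          se = NA_real_, n = filt$n[i], method = NA_character_,
                          filter = filt$filter[i], stringsAsFactors = FALSE))
      }
      v <- b$slope[b$gene == g & b$status == "ok"]
      a <- aggregate_tamp(v, mode_cutoff = mode_cutoff)
      data.frame(tamp = g, condition = cond, fitness = a$fitness, se = a$se,
                 n = a$n, method = a$method, filter = "kept",
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(reference)) {
      kept <- res[res$filter == "kept", , drop = FALSE]
      kept <- normalize_to_reference(kept, reference)
      res$fitness[res$filter == "kept"] <- kept$fitness
      res <- res[res$tamp != reference, , drop = FALSE]
    }
    out[[cond]] <- res
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write / read per-Tamp fitness tables
#'
#' Tab-delimited `tamp`, `condition`, `fitness`, `se`, `n`, `method`,
#' `filter`.
#'
#' @param fitness per-Tamp fitness table from [tamp_fitness()].
#' @param path file path.
#' @name fitness_io
#' @export
write_fitness_tsv <- function(fitness, path) {
  utils::write.table(fitness, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname fitness_io
#' @export
read_fitness_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
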