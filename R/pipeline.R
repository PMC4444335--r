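#' Pipeline configuration
#'
#' Collects every stage parameter with its screen-derived default:
#' pseudocount 1, minimum 3 trajectory points per slope, variance-filter SD
#' 0.05, mode/mean replicate cutoff 15, segmentation alpha 0.05 and minimum
#' plateau width 2, common-effect threshold 0.05, aCGH detection limit 0.06.
#' Serializes losslessly to/from YAML.
#'
#' @param conditions condition labels.
#' @param pseudocount,min_points,sd_threshold,mode_cutoff,alpha,min_width,n_permutations,common_effect_threshold,detection_limit
#'   stage parameters (see the stage functions).
#' @param sim a [sim_config()] for synthetic runs.
#' @param genome_params arguments for [toy_genome()] when no genome files
#'   are supplied.
#' @param landscape_params arguments for [plant_landscape()].
#' @param trajectory_files optional named character vector
#'   (condition -> trajectory CSV); when set, simulation and counting are
#'   skipped and the pipeline starts from the trajectories.
#' @param seed global seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(conditions = c("glucose", "phosphate", "sulfate"),
                            pseudocount = 1, min_points = 3,
                            sd_threshold = 0.05, mode_cutoff = 15,
                            alpha = 0.05, min_width = 2,
                            n_permutations = 10000,
                            common_effect_threshold = 0.05,
                            detection_limit = 0.06,
                            sim = sim_config(),
                            genome_params = list(n_chromosomes = 2,
                                                 chromosome_length = 200000,
                                                 genes_per_chromosome = 40),
                            landscape_params = list(n_breakpoints = 3,
                                                    effect_sd = 0.1,
                                                    sharing_fraction = 0.06),
                            trajectory_files = NULL,
                            seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML path.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$sim <- unclass(x$sim)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$sim <- do.call(sim_config, x$sim[setdiff(names(x$sim), "read_len")])
  cfg <- do.call(pipeline_config, x[setdiff(names(x), "sim")])
  cfg$sim <- x$sim
  cfg
}

#' Run the full screen pipeline
#'
#' Stages run in order: simulate (or ingest trajectory CSVs) -> fitness
#' estimation -> per-condition segmentation and breakpoint classification ->
#' cross-condition region analysis -> report. All stage outputs are written
#' as plain-text tables under `outdir`, plus a JSON manifest recording the
#' configuration hash and seed. Identical config and seed give identical
#' outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory (created if needed).
#' @param seed overrides `cfg$seed` when given.
#' @return invisibly, a list with the in-memory stage results (`genome`,
#'   `truth`, `fitness`, `segments`, `breakpoints`, `regions`, `manifest`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir, seed = NULL) {
  seed <- seed %||% cfg$seed
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  stages <- character(0)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  truth <- NULL
  if (is.null(cfg$trajectory_files)) {
    stages <- c(stages, "simulate")
    sim <- run_stage("simulate", {
      genome <- do.call(toy_genome, cfg$genome_params)
      landscape <- do.call(plant_landscape,
                           c(list(genome = genome,
                                  conditions = cfg$conditions),
                             cfg$landscape_params))
      truth <- make_truth(genome, landscape, cfg$sim)
      counts <- simulate_pool(truth)
      utils::write.csv(counts$counts, file.path(outdir, "counts.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.csv(counts$samples, file.path(outdir, "samples.csv"),
                       row.names = FALSE, quote = FALSE)
      utils::write.table(truth$fitness, file.path(outdir, "truth_fitness.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(genome = genome, truth = truth, counts = counts)
    })
    genome <- sim$genome; truth <- sim$truth
    stages <- c(stages, "count")
    traj <- run_stage("count", to_trajectories(sim$counts, cfg$pseudocount))
    for (cond in cfg$conditions) {
      write_trajectory_csv(traj[traj$condition == cond, ],
                           file.path(outdir, paste0("trajectories_", cond,
                                                    ".csv")))
    }
  } else {
    genome <- do.call(toy_genome, cfg$genome_params)
    traj <- do.call(rbind, lapply(names(cfg$trajectory_files), function(cond) {
      t <- read_trajectory_csv(cfg$trajectory_files[[cond]])
      t$condition <- cond
      t
    }))
  }

  stages <- c(stages, "fit")
  fitness <- run_stage("fit", tamp_fitness(
    traj, sd_threshold = cfg$sd_threshold, mode_cutoff = cfg$mode_cutoff,
    min_points = cfg$min_points,
    reference = if (is.null(cfg$trajectory_files)) cfg$sim$reference_id))
  fitness <- fitness[fitness$tamp %in% genome$genes$id, , drop = FALSE]
  write_fitness_tsv(fitness, file.path(outdir, "tamp_fitness.tsv"))

  stages <- c(stages, "segment")
  seg_stage <- run_stage("segment", {
    segs_by_cond <- list(); bps_by_cond <- list()
    for (cond in cfg$conditions) {
      prof <- build_profile(fitness, genome, cond)
      segs <- segment_profile(prof, alpha = cfg$alpha,
                              min_width = cfg$min_width,
                              n_permutations = cfg$n_permutations)
      segs_by_cond[[cond]] <- segs
      bps_by_cond[[cond]] <- classify_breakpoints(segs, genome)
      write_segments_tsv(segs, file.path(outdir,
                                         paste0("segments_", cond, ".tsv")))
      write_breakpoints_tsv(bps_by_cond[[cond]],
                            file.path(outdir,
                                      paste0("breakpoints_", cond, ".tsv")))
    }
    list(segments = segs_by_cond, breakpoints = bps_by_cond)
  })
  segments <- seg_stage$segments
  breakpoints <- seg_stage$breakpoints

  stages <- c(stages, "analyze")
  regions <- run_stage("analyze", {
    r <- union_regions(segments, genome)
    r <- common_effect_regions(r, cfg$common_effect_threshold)
    fcols <- grep("^fitness\\.", names(r), value = TRUE)
    if (length(fcols) >= 2) {
      r$pleiotropy <- apply(as.matrix(r[fcols]), 1, pleiotropy_variance)
    }
    utils::write.table(r, file.path(outdir, "regions.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    r
  })

  stages <- c(stages, "report")
  cfg_path <- file.path(outdir, "config.yaml")
  write_pipeline_config(cfg, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tampscape")),
    seed = seed, stages = stages,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_tamps_fit = length(unique(fitness$tamp)),
    n_segments = sum(vapply(segments, nrow, integer(1))),
    n_regions = nrow(regions))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(genome = genome, truth = truth, fitness = fitness,
                 segments = segments, breakpoints = breakpoints,
                 regions = regions, manifest = manifest))
}
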