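#' Genome model: chromosomes, centromeres and gene intervals
#'
#' A `genome_model` is the coordinate system shared by every stage of a Tamp
#' (telomeric amplicon) analysis. Coordinates are 0-based half-open
#' internally; all file readers/writers use 1-based inclusive coordinates.
#'
#' @param chromosomes data.frame with columns `name` and `length` (bp).
#' @param centromeres named numeric vector, chromosome name -> centromere
#'   position (bp, 0-based). Every chromosome must have exactly one
#'   centromere strictly inside `(0, length)`.
#' @param genes data.frame with columns `id`, `chrom`, `start`, `end`
#'   (0-based half-open) and `strand` (`"+"` or `"-"`). Gene ids must be
#'   unique and intervals must lie within their chromosome.
#' @return an object of class `genome_model` with elements `chromosomes`,
#'   `centromeres` and `genes` (genes sorted by chromosome then start).
#' @examples
#' gm <- toy_genome(n_chromosomes = 1, seed = 1)
#' arm_of(gm, gm$genes$chrom[1], gm$genes$start[1])
#' @export
genome_model <- function(chromosomes, centromeres, genes) {
  stop_if_not(all(c("name", "length") %in% names(chromosomes)),
              "chromosomes needs columns 'name' and 'length'")
  stop_if_not(!anyDuplicated(chromosomes$name), "duplicated chromosome names")
  stop_if_not(all(c("id", "chrom", "start", "end", "strand") %in% names(genes)),
              "genes needs columns id, chrom, start, end, strand")
  stop_if_not(!anyDuplicated(genes$id), "gene identifiers must be unique")
  stop_if_not(all(genes$start < genes$end), "gene intervals need start < end")
  stop_if_not(all(genes$chrom %in% chromosomes$name),
              "genes reference unknown chromosomes")
  stop_if_not(setequal(names(centromeres), chromosomes$name),
              "centromeres must name every chromosome exactly once")
  len <- stats::setNames(chromosomes$length, chromosomes$name)
  stop_if_not(all(centromeres > 0 & centromeres < len[names(centromeres)]),
              "centromere positions must lie strictly inside (0, length)")
  stop_if_not(all(genes$start >= 0 & genes$end <= len[genes$chrom]),
              "gene intervals must lie within [0, chromosome length)")
  genes <- genes[order(match(genes$chrom, chromosomes$name), genes$start), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  structure(list(chromosomes = as.data.frame(chromosomes),
                 centromeres = centromeres,
                 genes = as.data.frame(genes)),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d chromosome(s), %d gene(s)\n",
              nrow(x$chromosomes), nrow(x$genes)))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) {
    stop("unknown chromosome: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "), call. = FALSE)
  }
  genome$chromosomes$length[i]
}

#' Chromosome arm of a genomic position
#'
#' Positions below the centromere are on the left (`"L"`) arm, positions at
#' or above it on the right (`"R"`) arm.
#'
#' @param genome a [genome_model()].
#' @param chrom chromosome name(s).
#' @param position 0-based position(s) in bp, within `[0, length)`.
#' @return character vector of `"L"` / `"R"`.
#' @export
arm_of <- function(genome, chrom, position) {
  len <- chrom_length(genome, chrom)
  stop_if_not(all(position >= 0 & position < len),
              "position outside [0, chromosome length)")
  cen <- genome$centromeres[chrom]
  unname(ifelse(position < cen, "L", "R"))
}

#' Direction of increasing coordinates toward the telomere
#'
#' On the right arm coordinates increase toward the telomere (+1); on the
#' left arm they decrease (-1).
#'
#' @param arm `"L"` or `"R"` (vectorized).
#' @return integer vector of +1 / -1.
#' @export
telomere_direction <- function(arm) {
  stop_if_not(all(arm %in% c("L", "R")), "arm must be 'L' or 'R'")
  ifelse(arm == "R", 1L, -1L)
}

#' Arm membership of every gene
#'
#' Genes are assigned to the arm containing their midpoint, so a gene
#' spanning the centromere maps deterministically to one arm.
#'
#' @param genome a [genome_model()].
#' @return character vector parallel to `genome$genes`.
#' @export
gene_arm <- function(genome) {
  g <- genome$genes
  mid <- floor((g$start + g$end) / 2)
  arm_of(genome, g$chrom, mid)
}

#' Genes falling in a genomic interval
#'
#' @param genome a [genome_model()].
#' @param chrom chromosome name.
#' @param start,end interval bounds, 0-based half-open. An empty interval
#'   (`start == end`) returns an empty table.
#' @param mode `"any_overlap"` (>= 1 bp overlap, default) or `"contained"`.
#' @return the matching rows of `genome$genes`, sorted by start coordinate.
#' @export
genes_in_interval <- function(genome, chrom, start, end,
                              mode = c("any_overlap", "contained")) {
  mode <- match.arg(mode)
  chrom_length(genome, chrom)  # validates chromosome
  g <- genome$genes[genome$genes$chrom == chrom, , drop = FALSE]
  if (end <= start) g <- g[0, , drop = FALSE]
  keep <- if (mode == "any_overlap") {
    g$start < end & g$end > start
  } else {
    g$start >= start & g$end <= end
  }
  out <- g[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Tamp definitions for initiating genes
#'
#' A Tamp initiates at a gene and amplifies everything from its initiation
#' position to the proximal telomere. The initiation position defaults to
#' the deleted gene's start (its end is also supported, since only the
#' 3-4 gene resolution of the screen is defined).
#'
#' @param genome a [genome_model()].
#' @param gene_ids genes at which Tamps initiate; default all genes.
#' @param init_at `"start"` (default) or `"end"` of the initiating gene.
#' @return data.frame with columns `id`, `chrom`, `init_position`, `arm`,
#'   `amp_start`, `amp_end` (the amplicon interval, touching one
#'   chromosome end).
#' @export
tamp_table <- function(genome, gene_ids = genome$genes$id,
                       init_at = c("start", "end")) {
  init_at <- match.arg(init_at)
  i <- match(gene_ids, genome$genes$id)
  stop_if_not(!anyNA(i), "unknown gene id(s): %s",
              paste(gene_ids[is.na(i)], collapse = ", "))
  g <- genome$genes[i, , drop = FALSE]
  init <- if (init_at == "start") g$start else g$end
  len <- chrom_length(genome, g$chrom)
  arm <- arm_of(genome, g$chrom, pmin(init, len - 1))
  data.frame(id = g$id, chrom = g$chrom, init_position = init, arm = arm,
             amp_start = ifelse(arm == "R", init, 0),
             amp_end = ifelse(arm == "R", len, init),
             stringsAsFactors = FALSE)
}

#' Random toy genome for tests and simulations
#'
#' Builds a small genome with evenly spaced, jittered, non-overlapping genes
#' and a centromere near the middle of each chromosome. Entirely
#' programmatic; no annotation files required.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chromosome_length length of each chromosome in bp.
#' @param genes_per_chromosome genes per chromosome.
#' @param gene_length gene length in bp.
#' @param seed optional RNG seed.
#' @return a [genome_model()].
#' @export
toy_genome <- function(n_chromosomes = 2, chromosome_length = 200000,
                       genes_per_chromosome = 40, gene_length = 1500,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacing <- chromosome_length / genes_per_chromosome
  stop_if_not(spacing > gene_length + 2,
              "chromosome too short for the requested gene density")
  chroms <- data.frame(name = paste0("chr", seq_len(n_chromosomes)),
                       length = chromosome_length)
  genes <- do.call(rbind, lapply(chroms$name, function(cn) {
    jitter <- floor(stats::runif(genes_per_chromosome, 0,
                                 spacing - gene_length - 1))
    start <- floor((seq_len(genes_per_chromosome) - 1) * spacing) + jitter
    data.frame(id = sprintf("%s_g%03d", toupper(cn),
                            seq_len(genes_per_chromosome)),
               chrom = cn, start = start, end = start + gene_length,
               strand = sample(c("+", "-"), genes_per_chromosome,
                               replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  cen <- stats::setNames(
    floor(chromosome_length * stats::runif(n_chromosomes, 0.4, 0.6)),
    chroms$name)
  # nudge a centromere off any gene boundary collision with position 0/length
  genome_model(chroms, cen, genes)
}

#' Read and write gene annotation tables
#'
#' Tab-delimited, BED-like columns `chrom`, `start`, `end`, `strand`, `id`
#' with 1-based inclusive coordinates on disk (converted to the package's
#' 0-based half-open convention in memory).
#'
#' @param path file path.
#' @param genome a [genome_model()] (for the writers).
#' @return `read_genome_tables()` returns a [genome_model()].
#' @name genome_io
NULL

#' @rdname genome_io
#' @export
write_gene_table <- function(genome, path) {
  g <- genome$genes
  utils::write.table(
    data.frame(chrom = g$chrom, start = g$start + 1L, end = g$end,
               strand = g$strand, id = g$id),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genome_io
#' @export
write_centromere_table <- function(genome, path) {
  utils::write.table(
    data.frame(chrom = genome$chromosomes$name,
               length = genome$chromosomes$length,
               position = genome$centromeres[genome$chromosomes$name] + 1L),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname genome_io
#' @param gene_path,centromere_path paths written by the writers above.
#' @export
read_genome_tables <- function(gene_path, centromere_path) {
  g <- utils::read.table(gene_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  cen <- utils::read.table(centromere_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  genome_model(
    chromosomes = data.frame(name = cen$chrom,
                             length = as.numeric(cen$length)),
    centromeres = stats::setNames(as.numeric(cen$position - 1), cen$chrom),
    genes = data.frame(id = g$id, chrom = g$chrom,
                       start = as.numeric(g$start - 1),
                       end = as.numeric(g$end), strand = g$strand,
                       stringsAsFactors = FALSE))
}
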