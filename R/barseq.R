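#' Three-barcode read layout for Tamp bar-seq
#'
#' Reads carry, in order: a multiplexing barcode (6 bp), the
#' strain-identifying Tamp barcode (the deletion-collection barcode,
#' default 20 bp), and the random replicate barcode identifying the
#' independent transformant (default 12 bp; some processed tables use
#' 10 bp, so the length is configurable).
#'
#' @param multiplex_len,tamp_len,replicate_len barcode lengths in bp.
#' @param multiplex_mismatch,tamp_mismatch,replicate_mismatch allowed
#'   Hamming mismatches per barcode (defaults 0).
#' @return a `barcode_scheme` with barcode offsets within the read.
#' @export
barcode_scheme <- function(multiplex_len = 6, tamp_len = 20,
                           replicate_len = 12, multiplex_mismatch = 0,
                           tamp_mismatch = 0, replicate_mismatch = 0) {
  sc <- list(multiplex_len = multiplex_len, tamp_len = tamp_len,
             replicate_len = replicate_len,
             multiplex_offset = 0L,
             tamp_offset = as.integer(multiplex_len),
             replicate_offset = as.integer(multiplex_len + tamp_len),
             multiplex_mismatch = multiplex_mismatch,
             tamp_mismatch = tamp_mismatch,
             replicate_mismatch = replicate_mismatch)
  sc$read_len <- as.integer(multiplex_len + tamp_len + replicate_len)
  class(sc) <- "barcode_scheme"
  sc
}

read_field <- function(reads, offset, len) substr(reads, offset + 1, offset + len)

# Match observed barcodes against a table at a Hamming radius. Returns the
# index into `table` or NA. radius 0 reduces to exact match().
match_barcodes <- function(obs, table, radius) {
  if (radius == 0) return(match(obs, table))
  u <- unique(obs)
  ui <- vapply(u, function(b) {
    d <- hamming(rep(b, length(table)), table)
    hit <- which(d <= radius)
    if (length(hit) == 1) hit else NA_integer_
  }, integer(1))
  ui[match(obs, u)]
}

#' Synthesize bar-seq reads from a simulated count matrix
#'
#' One read per counted molecule: multiplex BC + Tamp BC + replicate BC.
#' Reads are emitted grouped by sample (no shuffling; demultiplexing is
#' order-independent). The reference lineage uses a dedicated Tamp barcode.
#'
#' @param counts a `count_matrix` from [simulate_pool()].
#' @param truth the `simulation_truth` (supplies Tamp barcodes).
#' @param scheme a [barcode_scheme()].
#' @param multiplex_table data.frame `sample_id`, `barcode` (6 bp); random
#'   unique barcodes are drawn if omitted.
#' @param seed RNG seed for the reference/replicate barcode draw.
#' @return list with `reads` (character vector), `multiplex_table`,
#'   `tamp_bc_table` (data.frame `barcode`, `tamp`) and `emitted`
#'   (the per-(sample, tamp, replicate) counts actually emitted).
#' @export
synthesize_reads <- function(counts, truth, scheme = barcode_scheme(),
                             multiplex_table = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  samples <- counts$samples
  multiplex_table <- multiplex_table %||% data.frame(
    sample_id = samples$sample_id,
    barcode = random_barcodes(nrow(samples), scheme$multiplex_len),
    stringsAsFactors = FALSE)
  tamp_bc <- data.frame(barcode = truth$tamps$tamp_bc,
                        tamp = truth$tamps$id, stringsAsFactors = FALSE)
  ref_bc <- random_barcodes(1, scheme$tamp_len)
  while (ref_bc %in% tamp_bc$barcode) ref_bc <- random_barcodes(1, scheme$tamp_len)
  tamp_bc <- rbind(tamp_bc,
                   data.frame(barcode = ref_bc,
                              tamp = truth$config$reference_id))
  x <- counts$counts
  mux <- multiplex_table$barcode[match(x$sample_id, multiplex_table$sample_id)]
  tbc <- tamp_bc$barcode[match(x$tamp, tamp_bc$tamp)]
  reads <- rep(paste0(mux, tbc, x$replicate_bc), x$count)
  list(reads = reads, multiplex_table = multiplex_table,
       tamp_bc_table = tamp_bc,
       emitted = x)
}

#' Write / read bar-seq reads as FASTQ
#'
#' Thin wrappers over Biostrings; qualities are constant (the pipeline does
#' no quality filtering).
#'
#' @param reads character vector of reads.
#' @param path FASTQ path (plain or gzipped by extension).
#' @name fastq_io
#' @export
write_reads_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read%08d", seq_along(x))
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' @rdname fastq_io
#' @export
read_reads_fastq <- function(path) {
  as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
}

#' Demultiplex reads by the multiplexing barcode
#'
#' Every read is assigned to exactly one sample, or to the unassigned bin.
#' The multiplex table is validated at load time: any two barcodes within
#' twice the allowed mismatch radius are ambiguous and raise an error.
#'
#' @param reads character vector of reads.
#' @param scheme a [barcode_scheme()].
#' @param multiplex_table data.frame `sample_id`, `barcode`.
#' @return list with `assigned` (named list sample_id -> reads) and
#'   `unassigned` (count).
#' @export
demultiplex <- function(reads, scheme, multiplex_table) {
  bcs <- multiplex_table$barcode
  stop_if_not(!anyDuplicated(bcs), "duplicate multiplex barcodes")
  if (length(bcs) > 1) {
    pairs <- utils::combn(length(bcs), 2)
    d <- hamming(bcs[pairs[1, ]], bcs[pairs[2, ]])
    stop_if_not(all(d > 2 * scheme$multiplex_mismatch),
                "ambiguous multiplex table: barcodes within mismatch radius")
  }
  obs <- read_field(reads, scheme$multiplex_offset, scheme$multiplex_len)
  idx <- match_barcodes(obs, bcs, scheme$multiplex_mismatch)
  assigned <- split(reads[!is.na(idx)],
                    multiplex_table$sample_id[idx[!is.na(idx)]])
  # keep empty samples present
  empty <- setdiff(multiplex_table$sample_id, names(assigned))
  for (e in empty) assigned[[e]] <- character(0)
  list(assigned = assigned[multiplex_table$sample_id],
       unassigned = sum(is.na(idx)))
}

#' Count (Tamp, replicate) barcode pairs in one sample's reads
#'
#' @param reads reads of one demultiplexed sample.
#' @param scheme a [barcode_scheme()].
#' @param tamp_bc_table data.frame `barcode`, `tamp` mapping the
#'   strain-identifying barcode to its initiating gene.
#' @param min_reads replicate barcodes observed fewer than `min_reads`
#'   times are dropped (default 1 keeps everything observed).
#' @return list with `counts` (tamp, replicate_bc, count), `unknown`
#'   (reads whose Tamp barcode matched nothing) and `dropped` (reads lost
#'   to the min-read floor).
#' @export
count_barcodes <- function(reads, scheme, tamp_bc_table, min_reads = 1) {
  if (!length(reads)) {
    return(list(counts = data.frame(tamp = character(),
                                    replicate_bc = character(),
                                    count = integer()),
                unknown = 0L, dropped = 0L))
  }
  tbc <- read_field(reads, scheme$tamp_offset, scheme$tamp_len)
  rbc <- read_field(reads, scheme$replicate_offset, scheme$replicate_len)
  idx <- match_barcodes(tbc, tamp_bc_table$barcode, scheme$tamp_mismatch)
  known <- !is.na(idx)
  key <- paste(tamp_bc_table$tamp[idx[known]], rbc[known], sep = "\r")
  tab <- table(key)
  counts <- data.frame(
    tamp = sub("\r.*$", "", names(tab)),
    replicate_bc = sub("^.*\r", "", names(tab)),
    count = as.integer(tab), stringsAsFactors = FALSE)
  low <- counts$count < min_reads
  list(counts = counts[!low, , drop = FALSE],
       unknown = sum(!known),
       dropped = sum(counts$count[low]))
}

#' Count all samples of a demultiplexed read set into a count matrix
#'
#' @param demux result of [demultiplex()].
#' @param samples sample metadata (`sample_id`, `condition`, `tech_rep`,
#'   `timepoint`, `generations`).
#' @inheritParams count_barcodes
#' @return a `count_matrix` (as from [simulate_pool()]) plus per-sample
#'   `unknown` counts in the `samples` table.
#' @export
count_samples <- function(demux, samples, scheme, tamp_bc_table,
                          min_reads = 1) {
  res <- lapply(samples$sample_id, function(sid) {
    count_barcodes(demux$assigned[[sid]], scheme, tamp_bc_table, min_reads)
  })
  counts <- do.call(rbind, lapply(seq_along(res), function(i) {
    x <- res[[i]]$counts
    if (nrow(x)) x$sample_id <- samples$sample_id[i]
    x
  }))
  samples$unknown <- vapply(res, function(x) x$unknown, integer(1))
  structure(list(counts = counts[, c("tamp", "replicate_bc", "sample_id",
                                     "count")],
                 samples = samples),
            class = "count_matrix")
}

#' Fraction of targeted Tamps represented above a read-fraction floor
#'
#' Pool-complexity summary: the share of targeted Tamps whose total read
#' fraction across samples exceeds `floor_fraction` (default 0.005% of all
#' assigned reads).
#'
#' @param counts a `count_matrix`.
#' @param targeted character vector of targeted Tamp ids.
#' @param floor_fraction minimum fraction of total reads.
#' @return list with `fraction`, `percent` (rounded to integer percent),
#'   `n_above`, `n_targeted`.
#' @export
pool_complexity <- function(counts, targeted, floor_fraction = 5e-5) {
  x <- counts$counts[counts$counts$tamp %in% targeted, , drop = FALSE]
  tot <- sum(counts$counts$count)
  by_tamp <- tapply(x$count, x$tamp, sum)
  frac <- rep(0, length(targeted))
  names(frac) <- targeted
  frac[names(by_tamp)] <- by_tamp / tot
  n_above <- sum(frac > floor_fraction)
  list(fraction = n_above / length(targeted),
       percent = round(100 * n_above / length(targeted)),
       n_above = n_above, n_targeted = length(targeted))
}

#' Build log2-ratio trajectories from a count matrix
#'
#' For each (Tamp, replicate barcode, technical replicate) the value at time
#' point t is `log2(((c_t + k) / N_t) / ((c_0 + k) / N_0))` with pseudocount
#' `k` added to read counts (not frequencies) and `N` the total assigned
#' reads in the sample. Lineages missing a t0 sample yield all-missing rows
#' with a warning. The t0 point (ratio exactly 0) is retained.
#'
#' @param counts a `count_matrix`.
#' @param pseudocount added to every read count (default 1).
#' @return a `trajectory_table`: long data.frame `gene`, `mer`, `replicate`,
#'   `timepoint`, `generations`, `log2_ratio`, `condition`.
#' @export
to_trajectories <- function(counts, pseudocount = 1) {
  x <- counts$counts
  meta <- counts$samples
  m <- match(x$sample_id, meta$sample_id)
  x$condition <- meta$condition[m]
  x$tech_rep <- meta$tech_rep[m]
  x$timepoint <- meta$timepoint[m]
  x$generations <- meta$generations[m]
  totals <- tapply(x$count, x$sample_id, sum)
  x$total <- as.numeric(totals[x$sample_id])
  x$freq <- (x$count + pseudocount) / x$total
  key <- paste(x$condition, x$tech_rep, x$tamp, x$replicate_bc, sep = "\r")
  grp <- paste(x$condition, x$tech_rep, sep = "\r")
  # baseline frequency at timepoint 0 per lineage; a lineage unobserved in
  # an existing t0 sample gets count 0 there, i.e. baseline pseudocount/N0
  t0 <- x[x$timepoint == 0, ]
  t0key <- paste(t0$condition, t0$tech_rep, t0$tamp, t0$replicate_bc,
                 sep = "\r")
  f0 <- stats::setNames(t0$freq, t0key)
  meta0 <- meta[meta$timepoint == 0, ]
  n0 <- tapply(as.numeric(totals[meta0$sample_id]),
               paste(meta0$condition, meta0$tech_rep, sep = "\r"),
               function(v) v[1])
  has_t0 <- grp %in% names(n0)
  miss <- has_t0 & !(key %in% names(f0))
  if (any(miss)) {
    f0_miss <- pseudocount / as.numeric(n0[grp[miss]])
    f0 <- c(f0, stats::setNames(f0_miss, key[miss])[!duplicated(key[miss])])
  }
  ratio <- rep(NA_real_, nrow(x))
  ratio[has_t0] <- log2(x$freq[has_t0] / as.numeric(f0[key[has_t0]]))
  if (any(!has_t0)) {
    warning(length(unique(key[!has_t0])),
            " lineage(s) have no t0 sample; trajectories set to NA")
  }
  out <- data.frame(gene = x$tamp, mer = x$replicate_bc,
                    replicate = x$tech_rep, timepoint = x$timepoint,
                    generations = x$generations,
                    log2_ratio = ratio,
                    condition = x$condition, stringsAsFactors = FALSE)
  out <- out[order(out$condition, out$gene, out$mer, out$replicate,
                   out$timepoint), ]
  rownames(out) <- NULL
  class(out) <- c("trajectory_table", "data.frame")
  out
}

trajectory_header <- c("gene", "mer", "replicate",
                       paste0("t", 1:9), paste0("g", 1:9))

#' Read / write trajectory tables in the 9-time-point CSV schema
#'
#' Columns: `gene` (initiating gene), `mer` (replicate barcode),
#' `replicate` (technical replicate), `t1`-`t9` (log2 frequency ratios
#' relative to t0, after pseudocounting), `g1`-`g9` (generations elapsed).
#' Missing values are written/parsed as `NA`. The implicit t0 point
#' (0 generations, ratio 0) is dropped on write and restored on read.
#'
#' @param table a `trajectory_table` (long format; see [to_trajectories()]).
#' @param path CSV path.
#' @name trajectory_io
#' @export
write_trajectory_csv <- function(table, path) {
  x <- table[table$timepoint != 0, , drop = FALSE]
  key <- paste(x$gene, x$mer, x$replicate, sep = "\r")
  rows <- unique(data.frame(gene = x$gene, mer = x$mer,
                            replicate = x$replicate, key = key,
                            stringsAsFactors = FALSE))
  stop_if_not(all(tapply(x$timepoint, key, length) <= 9),
              "schema holds at most 9 post-baseline time points")
  wide <- matrix(NA_real_, nrow(rows), 18,
                 dimnames = list(NULL, c(paste0("t", 1:9), paste0("g", 1:9))))
  ri <- match(key, rows$key)
  ti <- as.integer(ave(x$timepoint, key, FUN = function(z) rank(z)))
  wide[cbind(ri, ti)] <- x$log2_ratio
  wide[cbind(ri, ti + 9L)] <- x$generations
  out <- cbind(rows[c("gene", "mer", "replicate")], as.data.frame(wide))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_trajectory_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  stop_if_not(identical(names(raw), trajectory_header),
              "malformed header: expected %s",
              paste(trajectory_header, collapse = ","))
  num <- raw[, 4:21]
  for (j in seq_along(num)) {
    v <- suppressWarnings(as.numeric(num[[j]]))
    bad <- which(is.na(v) & !is.na(num[[j]]) &
                   !(num[[j]] %in% c("NA", "", "NaN")))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row %d, column %s", bad[1] + 1L,
                   names(num)[j]), call. = FALSE)
    }
    num[[j]] <- v
  }
  long <- do.call(rbind, lapply(1:9, function(t) {
    v <- num[[paste0("t", t)]]
    g <- num[[paste0("g", t)]]
    keep <- which(!is.na(v))
    data.frame(gene = raw$gene[keep], mer = raw$mer[keep],
               replicate = as.integer(raw$replicate[keep]),
               timepoint = rep(t, length(keep)), generations = g[keep],
               log2_ratio = v[keep], stringsAsFactors = FALSE)
  }))
  base <- unique(data.frame(gene = raw$gene, mer = raw$mer,
                            replicate = as.integer(raw$replicate),
                            timepoint = 0L, generations = 0,
                            log2_ratio = 0, stringsAsFactors = FALSE))
  long$condition <- NA_character_
  base$condition <- NA_character_
  out <- rbind(base, long)
  out <- out[order(out$gene, out$mer, out$replicate, out$timepoint), ]
  gkey <- paste(out$gene, out$mer, out$replicate, sep = "\r")
  incr <- tapply(out$generations, gkey, function(g) all(diff(g) > 0))
  stop_if_not(all(incr), "generations must be strictly increasing per row")
  rownames(out) <- NULL
  class(out) <- c("trajectory_table", "data.frame")
  out
}
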