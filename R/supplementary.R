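#' Summaries over externally supplied screen tables
#'
#' Helpers for reproducing headline aggregates from the screen's published
#' supplementary tables, supplied as tab-delimited exports. The package does
#' not bundle those tables; the functions operate on any table matching the
#' documented schema.
#'
#' @name supplementary
NULL

#' Mean population frequency of aneuploid events
#'
#' @param freq table with a `frequency` column (population frequencies of
#'   aneuploid events, as fractions in `[0, 1]`), or a path to a TSV with
#'   that column.
#' @return list `mean_fraction`, `percent` (rounded to integer percent),
#'   `n`.
#' @export
mean_population_frequency <- function(freq) {
  if (is.character(freq)) {
    freq <- utils::read.table(freq, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  stop_if_not("frequency" %in% names(freq), "need a 'frequency' column")
  f <- freq$frequency[!is.na(freq$frequency)]
  stop_if_not(all(f >= 0 & f <= 1), "frequencies must be fractions in [0,1]")
  list(mean_fraction = mean(f), percent = round(100 * mean(f)),
       n = length(f))
}

#' Mean Tamp fitness by driver-gene content
#'
#' Groups Tamps by which of two driver genes their amplicon contains
#' (both, first only, neither; amplicons with only the second gene are
#' reported too when present) and returns the group mean fitnesses. This is
#' the targeted-pool summary: e.g. grouping chrII-right-arm Tamps by
#' SUL1/BSD2 content.
#'
#' @param fitness table with columns `fitness` and two logical columns named
#'   by `genes` indicating whether each Tamp's amplicon contains the gene,
#'   or a path to such a TSV.
#' @param genes length-2 character vector naming the grouping columns,
#'   centromere-proximal gene first (default `c("bsd2", "sul1")`).
#' @return data.frame `group`, `mean_fitness`, `n`.
#' @export
tamp_group_means <- function(fitness, genes = c("bsd2", "sul1")) {
  if (is.character(fitness)) {
    fitness <- utils::read.table(fitness, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  }
  stop_if_not(all(c("fitness", genes) %in% names(fitness)),
              "need columns: fitness, %s", paste(genes, collapse = ", "))
  a <- as.logical(fitness[[genes[1]]])
  b <- as.logical(fitness[[genes[2]]])
  grp <- ifelse(a & b, "both", ifelse(b, paste0(genes[2], "_only"),
                                      ifelse(a, paste0(genes[1], "_only"),
                                             "neither")))
  out <- do.call(rbind, lapply(unique(grp), function(g) {
    v <- fitness$fitness[grp == g & !is.na(fitness$fitness)]
    data.frame(group = g, mean_fitness = mean(v), n = length(v),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
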