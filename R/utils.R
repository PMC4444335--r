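`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Hamming distance between equal-length strings
#'
#' @param a,b character vectors of equal-length strings (recycled).
#' @return integer vector of mismatch counts.
#' @keywords internal
hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) {
    sum(utf8ToInt(x) != utf8ToInt(y))
  }, a, b, USE.NAMES = FALSE)
}

#' Random DNA barcodes
#'
#' Draws `n` distinct random DNA strings of length `len`. Uses the current
#' RNG state; seed upstream for reproducibility.
#'
#' @param n number of barcodes.
#' @param len barcode length in bp.
#' @return character vector of `n` unique barcodes.
#' @export
random_barcodes <- function(n, len) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    new <- vapply(seq_len(need + 4L), function(i) {
      paste(sample(bases, len, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, new))
  }
  out[seq_len(n)]
}

# OLS slope with free intercept; returns slope, intercept, se of slope,
# residual standard error and n. x strictly increasing is not required here.
ols_slope <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  res <- y - intercept - slope * x
  rse <- if (n > 2) sqrt(sum(res^2) / (n - 2)) else NA_real_
  se <- if (n > 2) rse / sqrt(sxx) else NA_real_
  list(slope = slope, intercept = intercept, se = se, rse = rse, n = n)
}
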