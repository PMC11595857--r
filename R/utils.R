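#' Numerically stable logistic function
#'
#' Computes `1 / (1 + exp(-z))` without overflow for large `|z|`.
#' Used for the attention gates; results are strictly inside (0, 1) for
#' finite input.
#'
#' @param z numeric vector or array.
#' @return object of the same shape with values in (0, 1).
#' @keywords internal
stable_sigmoid <- function(z) {
  out <- z
  pos <- !is.na(z) & z >= 0
  out[pos] <- 1 / (1 + exp(-z[pos]))
  ez <- exp(z[!pos])
  out[!pos] <- ez / (1 + ez)
  out
}

#' Round half away from zero
#'
#' Fixed-point rounding used for the published-table complexity figures
#' (base [round()] rounds half to even, which is not how the published
#' table was produced).
#'
#' @param x numeric.
#' @param digits number of decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_positive_int <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a positive integer, got %s", name,
                 paste(x, collapse = ",")), call. = FALSE)
  invisible(as.integer(x))
}

assert_tensor4 <- function(x, name = "x") {
  d <- dim(x)
  if (is.null(d) || length(d) != 4)
    stop(sprintf("`%s` must be a 4-d array with dim (N, C, H, W)", name),
         call. = FALSE)
  if (any(d < 1))
    stop(sprintf("`%s` has a zero-sized dimension (%s)", name,
                 paste(d, collapse = "x")), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("`%s` contains non-finite values", name), call. = FALSE)
  invisible(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
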