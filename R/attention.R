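#' Configure the effective spatial attention (ESA) gate
#'
#' The ESA module squeezes a feature map to a pooled `1 x 1 x C` descriptor,
#' runs a small one-dimensional convolution *across the channel axis* of the
#' transposed `C x 1` descriptor, applies a sigmoid, and multiplies the
#' resulting per-channel gate back onto the input feature map.  Because the
#' transform is a fixed-size cross-channel convolution rather than a fully
#' connected squeeze, it has a handful of parameters regardless of `C` and
#' needs no channel dimensionality reduction.  Despite its name, the
#' mechanism gates channels, not pixels.
#'
#' @param pool_kind pooling used for the descriptor: `"global_average"`
#'   (default) or `"global_max"`.
#' @param kernel_size odd positive integer, extent of the cross-channel
#'   convolution (default 3).
#' @param placement where the gate is inserted in a residual network:
#'   `"per_block_pre_add"` (default; applied to the residual branch output
#'   before the skip addition) or `"per_stage_exit"`.
#' @param bias whether the cross-channel convolution has a bias term.
#' @return an `esa_config` list.
#' @export
#' @examples
#' cfg <- esa_config()
#' x <- array(rnorm(2 * 8 * 4 * 4), c(2, 8, 4, 4))
#' w <- esa_init_weights(cfg)
#' g <- esa_attention_weights(x, cfg, w)
#' stopifnot(all(g > 0 & g < 1), dim(g) == c(2, 8))
esa_config <- function(pool_kind = c("global_average", "global_max"),
                       kernel_size = 3L,
                       placement = c("per_block_pre_add", "per_stage_exit"),
                       bias = TRUE) {
  pool_kind <- match.arg(pool_kind)
  placement <- match.arg(placement)
  assert_positive_int(kernel_size, "kernel_size")
  if (kernel_size %% 2 == 0)
    stop("`kernel_size` must be odd so the channel neighborhood is symmetric",
         call. = FALSE)
  structure(list(pool_kind = pool_kind, kernel_size = as.integer(kernel_size),
                 placement = placement, bias = isTRUE(bias)),
            class = "esa_config")
}

#' Initialize weights for a standalone ESA gate
#'
#' @param config an [esa_config()].
#' @param sd standard deviation of the normal initializer.
#' @return list with elements `w` (length `kernel_size`) and `b` (scalar,
#'   0 when `config$bias` is `FALSE`).
#' @export
esa_init_weights <- function(config = esa_config(), sd = 0.1) {
  list(w = rnorm(config$kernel_size, sd = sd),
       b = if (config$bias) 0 else 0)
}

esa_pool <- function(x, pool_kind) {
  d <- dim(x)
  m <- matrix(aperm(x, c(1, 2, 3, 4)), nrow = d[1] * d[2])
  # rows index (n, c) with n fastest; columns the H*W pixels
  pooled <- if (pool_kind == "global_max") {
    apply(m, 1, max)
  } else {
    rowMeans(m)
  }
  matrix(pooled, nrow = d[1], ncol = d[2])
}

# 1-d convolution of each row of `p` (N x C) along the channel axis with
# zero padding; `w` has odd length.
channel_conv1d <- function(p, w, b = 0) {
  k <- length(w)
  half <- (k - 1L) %/% 2L
  C <- ncol(p)
  z <- matrix(b, nrow = nrow(p), ncol = C)
  for (j in seq_len(k)) {
    off <- j - 1L - half
    src <- seq_len(C) + off
    ok <- src >= 1L & src <= C
    z[, ok] <- z[, ok] + w[j] * p[, src[ok], drop = FALSE]
  }
  z
}

#' Per-channel attention gates of the ESA module
#'
#' @param x feature map, array with dim `(N, C, H, W)`; must be finite.
#' @param config an [esa_config()].
#' @param weights list with `w` (cross-channel kernel) and `b` (bias
#'   scalar), e.g. from [esa_init_weights()].
#' @return `N x C` matrix of gates, every entry strictly in (0, 1).
#' @details The gate is invariant to any spatial permutation of the pixels
#'   of `x` because the descriptor is a global pooling, and the same
#'   `weights` apply to feature maps of any channel count.
#' @export
esa_attention_weights <- function(x, config = esa_config(), weights) {
  assert_tensor4(x)
  if (length(weights$w) != config$kernel_size)
    stop("`weights$w` must have length `config$kernel_size`", call. = FALSE)
  p <- esa_pool(x, config$pool_kind)
  z <- channel_conv1d(p, weights$w, if (config$bias) weights$b else 0)
  stable_sigmoid(z)
}

#' Apply the ESA gate to a feature map
#'
#' Computes `out[n,c,h,w] = x[n,c,h,w] * gate[n,c]`, preserving the input
#' shape.
#'
#' @inheritParams esa_attention_weights
#' @return array of the same shape as `x`.
#' @export
esa_forward <- function(x, config = esa_config(), weights) {
  g <- esa_attention_weights(x, config, weights)
  d <- dim(x)
  x * array(g, d)  # gate recycles over H, W (first two dims match)
}
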