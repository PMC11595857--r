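#' 2-d convolution
#'
#' Direct (cross-correlation) convolution as used by deep learning
#' frameworks, implemented via im2col and a matrix product in compiled
#' code.  Grouped convolution divides the input channels into `groups`
#' independent bundles.
#'
#' @param x input feature map, array with dim `(N, C, H, W)`.
#' @param w weights, array with dim `(C_out, C / groups, k, k)`.
#' @param bias optional numeric vector of length `C_out`, or `NULL`.
#' @param stride,pad positive stride and non-negative zero padding.
#' @param groups number of channel groups; must divide `C` and `C_out`.
#' @return array with dim `(N, C_out, H', W')`.
#' @export
conv2d <- function(x, w, bias = NULL, stride = 1L, pad = 0L, groups = 1L) {
  assert_tensor4(x)
  dw <- dim(w)
  if (is.null(dw) || length(dw) != 4)
    stop("`w` must be a 4-d array (C_out, C_in/groups, k, k)", call. = FALSE)
  cpp_conv2d_forward(x, w, if (is.null(bias)) numeric(0) else bias,
                     as.integer(stride), as.integer(pad), as.integer(groups))
}

#' Depthwise 2-d convolution
#'
#' One spatial filter per input channel (`groups = C`): channel `c` of the
#' output depends only on channel `c` of the input, and the channel count
#' is unchanged.  This is the spatial half of a depthwise-separable
#' convolution; the stride, when used, performs the downsampling that a
#' standard 3x3 convolution would otherwise carry.
#'
#' @param x input feature map, array with dim `(N, C, H, W)`.
#' @param kernels array with dim `(C, k, k)`: filter `c` is applied to
#'   channel `c`.  A `(C, 1, k, k)` array is also accepted.
#' @param stride,pad stride and zero padding.
#' @param bias optional numeric vector of length `C`.
#' @return array with dim `(N, C, H', W')`.
#' @export
depthwise_conv2d <- function(x, kernels, stride = 1L, pad = 0L, bias = NULL) {
  d <- assert_tensor4(x)
  kd <- dim(kernels)
  if (length(kd) == 3) {
    kernels <- array(kernels, c(kd[1], 1L, kd[2], kd[3]))
    kd <- dim(kernels)
  }
  if (length(kd) != 4 || kd[2] != 1)
    stop("`kernels` must have one filter per channel: dim (C, k, k)",
         call. = FALSE)
  if (kd[1] != d[2])
    stop(sprintf("filter count (%d) must equal input channel count (%d)",
                 kd[1], d[2]), call. = FALSE)
  conv2d(x, kernels, bias = bias, stride = stride, pad = pad, groups = d[2])
}

#' Pointwise (1x1) 2-d convolution
#'
#' A learned linear combination of the input channels at every pixel;
#' spatial dimensions are unchanged.  This is the channel-mixing half of a
#' depthwise-separable convolution.
#'
#' @param x input feature map, array with dim `(N, C_in, H, W)`.
#' @param kernels `C_out x C_in` mixing matrix, or an equivalent
#'   `(C_out, C_in, 1, 1)` array.
#' @param bias optional numeric vector of length `C_out`.
#' @return array with dim `(N, C_out, H, W)`.
#' @export
pointwise_conv2d <- function(x, kernels, bias = NULL) {
  d <- assert_tensor4(x)
  if (is.matrix(kernels)) kernels <- array(kernels, c(dim(kernels), 1L, 1L))
  kd <- dim(kernels)
  if (length(kd) != 4 || kd[3] != 1 || kd[4] != 1)
    stop("`kernels` must be 1x1 filters: a C_out x C_in matrix", call. = FALSE)
  if (kd[2] != d[2])
    stop(sprintf("mixing matrix expects %d input channels, got %d",
                 kd[2], d[2]), call. = FALSE)
  conv2d(x, kernels, bias = bias, stride = 1L, pad = 0L, groups = 1L)
}
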