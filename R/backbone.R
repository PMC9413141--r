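# Backbone block: the large-kernel residual convolution unit. The 7x7
# receptive field is factorized into consecutive 7x1 and 1x7 convolutions,
# which cuts the weight count of the pair from 49*C^2 to 14*C^2; a
# batch-norm, a 1x1 convolution, Mish, and a second (zero-initialized) 1x1
# convolution complete the residual branch.

#' Weight-count reduction of spatial kernel factorization
#'
#' Percent reduction in convolution weights when one k x k kernel is
#' replaced by consecutive k x 1 and 1 x k kernels at fixed channel counts
#' (biases excluded): `100 * (1 - 2k / k^2)`. For k = 7 this is about 71.4%,
#' i.e. "approximately 72%".
#'
#' @param k odd positive kernel size.
#' @return Percent reduction (negative for k = 1, where factorization
#'   doubles the weights).
#' @examples
#' param_reduction_percent(7)   # ~71.43
#' @export
param_reduction_percent <- function(k) {
  if (length(k) != 1 || is.na(k) || k < 1 || k %% 2 != 1)
    stop_valid("k must be a single odd integer >= 1")
  100 * (1 - 2 * k / k^2)
}

#' Apply a factorized large-kernel convolution pair
#'
#' Convolves a feature map with a k x 1 kernel followed by a 1 x k kernel,
#' both same-padded, preserving the spatial dimensions. Weight matrices use
#' the layer layout (rows = kernel taps x input channels, columns = output
#' channels); all-ones weights with a delta-impulse input show the k x k
#' receptive field of the pair.
#'
#' @param x (H, W, C) array or H x W matrix.
#' @param w_vert (k * C) x Cmid weight matrix of the k x 1 convolution.
#' @param w_horiz (k * Cmid) x Cout weight matrix of the 1 x k convolution.
#' @param k kernel size (default 7).
#' @return (H, W, Cout) array.
#' @export
factorized_large_kernel <- function(x, w_vert, w_horiz, k = 7L) {
  x <- as_map3(x)
  C <- dim(x)[3]
  if (nrow(w_vert) != k * C) stop_dim("w_vert rows must equal k * C")
  cmid <- ncol(w_vert)
  if (nrow(w_horiz) != k * cmid) stop_dim("w_horiz rows must equal k * Cmid")
  h <- cpp_conv2d_fwd(x, w_vert, numeric(cmid), as.integer(k), 1L, 1L, 1L, FALSE)
  cpp_conv2d_fwd(h, w_horiz, numeric(ncol(w_horiz)), 1L, as.integer(k), 1L, 1L, FALSE)
}

#' Construct a backbone block
#'
#' The residual local-feature block: consecutive 7x1 and 1x7 convolutions
#' (no bias), batch normalization, a 1x1 convolution, Mish, a second 1x1
#' convolution (zero-initialized, so the fresh block is the identity), and
#' an element-wise residual connection. Channel count and spatial size are
#' preserved.
#'
#' @param C channel count.
#' @param k large-kernel size (default 7).
#' @param factorized if `FALSE`, use a single k x k convolution instead of
#'   the factorized pair (the comparison variant for weight counting).
#' @return A module with `$forward(x, train)` and `$backward(gy)`.
#' @export
backbone_block <- function(C, k = 7L, factorized = TRUE) {
  m <- new_module("backbone_block")
  m$C <- C; m$k <- as.integer(k); m$factorized <- factorized
  if (factorized) {
    m$conv_a <- conv_layer(C, C, k, 1, bias = FALSE)
    m$conv_b <- conv_layer(C, C, 1, k, bias = FALSE)
    convs <- list(m$conv_a, m$conv_b)
  } else {
    m$conv_a <- conv_layer(C, C, k, k, bias = FALSE)
    convs <- list(m$conv_a)
  }
  m$bn <- bn_layer(C)
  m$conv1 <- conv_layer(C, C, 1, 1)
  m$act <- mish_layer()
  m$conv2 <- conv_layer(C, C, 1, 1, init = "zero")
  m$children <- c(convs, list(m$bn, m$conv1, m$act, m$conv2))
  m$forward <- function(x, train = FALSE) {
    h <- m$conv_a$forward(x, train)
    if (m$factorized) h <- m$conv_b$forward(h, train)
    h <- m$bn$forward(h, train)
    h <- m$conv1$forward(h, train)
    h <- m$act$forward(h, train)
    h <- m$conv2$forward(h, train)
    h + x
  }
  m$backward <- function(gy) {
    g <- m$conv2$backward(gy)
    g <- m$act$backward(g)
    g <- m$conv1$backward(g)
    g <- m$bn$backward(g)
    if (m$factorized) g <- m$conv_b$backward(g)
    g <- m$conv_a$backward(g)
    g + gy
  }
  m
}

#' Forward pass of a backbone block
#'
#' @param block a module from [backbone_block()].
#' @param x (H, W, C) array or matrix.
#' @param train logical; use batch statistics (training) or running
#'   statistics (inference) in the batch-norm.
#' @return Array with the dimensions of `x`.
#' @export
backbone_forward <- function(block, x, train = FALSE) {
  block$forward(as_map3(x), train)
}
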