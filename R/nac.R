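# Nodule-adaptive convolution (NAC): four parallel convolution branches with
# effective receptive fields 1, 5, 7 and 11 (a 1x1 convolution plus 3x3
# convolutions dilated 2, 3 and 5), mixed by input-conditioned weights on
# the probability simplex (global average pool -> fully connected ->
# softmax). The mixture adapts the receptive field to the nodule scale.

#' Effective spatial extent of a dilated kernel
#'
#' `(kernel - 1) * dilation + 1`: the span in pixels covered per axis by a
#' dilated convolution. The four NAC branches (kernel 1; kernel 3 dilated
#' 2, 3, 5) span 1, 5, 7 and 11 pixels.
#'
#' @param kernel odd positive kernel size.
#' @param dilation positive integer dilation rate.
#' @return Integer extent in pixels.
#' @examples
#' effective_kernel_extent(3, 5)   # 11
#' @export
effective_kernel_extent <- function(kernel, dilation) {
  if (length(kernel) != 1 || is.na(kernel) || kernel < 1 || kernel %% 2 != 1)
    stop_valid("kernel must be a single odd integer >= 1")
  if (length(dilation) != 1 || is.na(dilation) || dilation < 1)
    stop_valid("dilation must be a single positive integer")
  as.integer((kernel - 1) * dilation + 1)
}

#' Construct a nodule-adaptive convolution block
#'
#' @param C channel count (preserved).
#' @param kernels,dilations parallel vectors defining the K branches
#'   (default kernels 1,3,3,3 with dilations 1,2,3,5).
#' @return A module with `$forward(x, train)`, `$backward(gy)`; setting
#'   `$force_alpha` to a fixed weight vector bypasses the weight head (a
#'   test hook for degenerate mixtures).
#' @export
nac_block <- function(C, kernels = c(1L, 3L, 3L, 3L),
                      dilations = c(1L, 2L, 3L, 5L)) {
  if (length(kernels) != length(dilations)) stop_config("kernels and dilations differ in length")
  K <- length(kernels)
  m <- new_module("nac_block")
  m$C <- C; m$K <- K; m$kernels <- as.integer(kernels); m$dilations <- as.integer(dilations)
  m$branch_conv <- lapply(seq_len(K), function(k)
    conv_layer(C, C, kernels[k], kernels[k], dil = dilations[k], bias = FALSE))
  m$branch_bn <- lapply(seq_len(K), function(k) bn_layer(C))
  m$fc <- linear_layer(C, K)
  m$g_conv <- conv_layer(C, C, 1, 1, bias = FALSE)
  m$g_bn <- bn_layer(C)
  m$children <- c(m$branch_conv, m$branch_bn, list(m$fc, m$g_conv, m$g_bn))
  m$force_alpha <- NULL

  m$forward <- function(x, train = FALSE) {
    d <- dim(x)
    n <- d[1] * d[2]
    pooled <- colMeans(matrix(x, n, d[3]))
    logits <- m$fc$forward(pooled, train)
    a <- exp(logits - max(logits)); alpha <- a / sum(a)
    if (!is.null(m$force_alpha)) alpha <- m$force_alpha
    branches <- vector("list", m$K)
    pre <- vector("list", m$K)
    y3p <- 0
    for (k in seq_len(m$K)) {
      h <- m$branch_conv[[k]]$forward(x, train)
      h <- m$branch_bn[[k]]$forward(h, train)
      pre[[k]] <- h
      branches[[k]] <- mish(h)
      y3p <- y3p + alpha[k] * branches[[k]]
    }
    gpre <- m$g_bn$forward(m$g_conv$forward(y3p, train), train)
    m$cache <- list(d = d, alpha = alpha, branches = branches, pre = pre,
                    gpre = gpre)
    mish(gpre)
  }

  m$backward <- function(gy) {
    cc <- m$cache; d <- cc$d; n <- d[1] * d[2]
    g <- gy * mish_grad(cc$gpre)
    gy3p <- m$g_conv$backward(m$g_bn$backward(g))
    gx <- array(0, d)
    galpha <- numeric(m$K)
    for (k in seq_len(m$K)) {
      galpha[k] <- sum(cc$branches[[k]] * gy3p)
      gb <- cc$alpha[k] * gy3p * mish_grad(cc$pre[[k]])
      gx <- gx + m$branch_conv[[k]]$backward(m$branch_bn[[k]]$backward(gb))
    }
    if (is.null(m$force_alpha)) {
      glogit <- cc$alpha * (galpha - sum(cc$alpha * galpha))
      gpool <- m$fc$backward(glogit)
      gx <- gx + array(rep(gpool, each = n) / n, d)
    }
    gx
  }
  m
}

#' Input-conditioned branch weights of a NAC block
#'
#' Global average pool over space, fully connected layer, softmax over the
#' K branches; the weights are non-negative and sum to 1 by construction.
#'
#' @param block a module from [nac_block()].
#' @param x (H, W, C) array or matrix.
#' @return Numeric vector of K branch weights on the simplex.
#' @export
branch_weights <- function(block, x) {
  x <- as_map3(x)
  d <- dim(x)
  pooled <- colMeans(matrix(x, d[1] * d[2], d[3]))
  logits <- drop(crossprod(block$fc$w$value, pooled)) + block$fc$b$value
  a <- exp(logits - max(logits))
  a / sum(a)
}

#' Forward pass of a NAC block
#'
#' @param block a module from [nac_block()].
#' @param x (H, W, C) array or matrix.
#' @param train logical; batch vs running statistics in the batch-norms.
#' @return Array with the dimensions of `x`.
#' @export
nac_forward <- function(block, x, train = FALSE) {
  block$forward(as_map3(x), train)
}
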