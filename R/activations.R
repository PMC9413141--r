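#' Mish activation
#'
#' The smooth self-gated activation \eqn{y = x \tanh(\mathrm{softplus}(x))}
#' used throughout the network in place of ReLU. It is monotone for
#' \eqn{x \ge 0}, bounded below by about \eqn{-0.30884}, and smooth
#' everywhere, which helps gradient flow through the deep residual blocks.
#' Evaluated in C++ with a softplus reformulation that is stable for large
#' \eqn{|x|}.
#'
#' @param x numeric scalar or array.
#' @return The activation, same shape as `x`.
#' @examples
#' mish(0)            # exactly 0
#' mish(c(-20, 20))   # ~0 and ~20: the function is linear for large x
#' @export
mish <- function(x) {
  y <- as.numeric(cpp_mish(as.numeric(x)))
  if (!is.null(dim(x))) array(y, dim(x)) else y
}

# d mish / dx, used by the backward passes
mish_grad <- function(x) {
  y <- as.numeric(cpp_mish_grad(as.numeric(x)))
  if (!is.null(dim(x))) array(y, dim(x)) else y
}

# numerically stable log(1 + exp(x)), kept for reference computations
softplus <- function(x) {
  out <- x
  low <- x <= 30
  out[low] <- log1p(exp(x[low]))
  out
}
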