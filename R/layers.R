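# Minimal layer system: each layer is an environment with forward()/backward()
# closures; backward() accumulates parameter gradients in place (so gradients
# can be summed over a minibatch before an optimizer step) and returns the
# gradient with respect to the layer input. Feature maps are (H, W, C) arrays.

new_param <- function(value) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- value * 0
  class(e) <- "lca_param"
  e
}

new_module <- function(type) {
  m <- new.env(parent = emptyenv())
  m$params <- list()
  m$children <- list()
  class(m) <- c(type, "lca_module")
  m
}

collect_params <- function(mod) {
  out <- mod$params
  for (ch in mod$children) out <- c(out, collect_params(ch))
  out
}

zero_grads <- function(params) {
  for (p in params) p$grad <- p$grad * 0
  invisible(NULL)
}

get_weights <- function(mod) lapply(collect_params(mod), function(p) p$value)

set_weights <- function(mod, w) {
  ps <- collect_params(mod)
  stopifnot(length(ps) == length(w))
  for (i in seq_along(ps)) ps[[i]]$value <- w[[i]]
  invisible(mod)
}

n_weights <- function(mod) sum(vapply(collect_params(mod), function(p) length(p$value), 0))

# ---- convolution ----------------------------------------------------------

conv_layer <- function(cin, cout, kh, kw, dil = 1L, bias = TRUE,
                       init = c("he", "zero")) {
  init <- match.arg(init)
  m <- new_module("conv_layer")
  fan_in <- kh * kw * cin
  w0 <- if (init == "zero") matrix(0, fan_in, cout)
        else matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout)
  m$w <- new_param(w0)
  m$params <- list(m$w)
  if (bias) {
    m$b <- new_param(numeric(cout))
    m$params <- c(m$params, list(m$b))
  }
  m$kh <- as.integer(kh); m$kw <- as.integer(kw); m$dil <- as.integer(dil)
  m$cin <- cin; m$cout <- cout; m$bias <- bias
  m$is11 <- kh == 1 && kw == 1
  m$forward <- function(x, train = FALSE) {
    if (m$is11) {
      m$cache_x <- x
      return(cpp_conv2d_fwd(x, m$w$value,
                            if (m$bias) m$b$value else numeric(m$cout),
                            1L, 1L, 1L, 1L, m$bias))
    }
    r <- cpp_conv2d_fwd_cache(x, m$w$value,
                              if (m$bias) m$b$value else numeric(m$cout),
                              m$kh, m$kw, m$dil, m$dil, m$bias)
    m$cache_xc <- r$xc
    m$cache_d <- dim(x)
    r$y
  }
  m$backward <- function(gy) {
    if (m$is11) {
      r <- cpp_conv2d_bwd(m$cache_x, m$w$value, gy, 1L, 1L, 1L, 1L)
    } else {
      d <- m$cache_d
      r <- cpp_conv2d_bwd_cached(m$cache_xc, m$w$value, gy, d[1], d[2], d[3],
                                 m$kh, m$kw, m$dil, m$dil)
    }
    m$w$grad <- m$w$grad + r$gw
    if (m$bias) m$b$grad <- m$b$grad + as.numeric(r$gb)
    r$gx
  }
  m
}

# ---- batch normalization (per-channel over space) -------------------------
# The training loop accumulates gradients over single-sample passes, so the
# batch statistics are per-map; inference uses the same per-map statistics
# (instance-norm semantics), which keeps train and test behavior identical
# and checkpoints stateless.

bn_layer <- function(C, eps = 1e-5) {
  m <- new_module("bn_layer")
  m$gamma <- new_param(rep(1, C)); m$beta <- new_param(numeric(C))
  m$params <- list(m$gamma, m$beta)
  m$eps <- eps; m$C <- C
  m$forward <- function(x, train = FALSE) {
    d <- dim(x); n <- d[1] * d[2]
    xm <- matrix(x, n, d[3])
    mu <- colMeans(xm)
    xc <- xm - matrix(mu, n, d[3], byrow = TRUE)
    v <- colMeans(xc * xc)
    invstd <- 1 / sqrt(v + m$eps)
    xhat <- xc * matrix(invstd, n, d[3], byrow = TRUE)
    m$cache <- list(xhat = xhat, invstd = invstd, d = d)
    y <- xhat * matrix(m$gamma$value, n, d[3], byrow = TRUE) +
      matrix(m$beta$value, n, d[3], byrow = TRUE)
    array(y, d)
  }
  m$backward <- function(gy) {
    cc <- m$cache; d <- cc$d; n <- d[1] * d[2]
    gym <- matrix(gy, n, d[3])
    m$gamma$grad <- m$gamma$grad + colSums(gym * cc$xhat)
    m$beta$grad <- m$beta$grad + colSums(gym)
    gsc <- matrix(m$gamma$value * cc$invstd, n, d[3], byrow = TRUE)
    s1 <- colMeans(gym)
    s2 <- colMeans(gym * cc$xhat)
    gx <- gsc * (gym - matrix(s1, n, d[3], byrow = TRUE) -
                   cc$xhat * matrix(s2, n, d[3], byrow = TRUE))
    array(gx, d)
  }
  m
}

# ---- layer normalization (per-pixel over channels) ------------------------

ln_layer <- function(C, eps = 1e-5) {
  m <- new_module("ln_layer")
  m$gamma <- new_param(rep(1, C)); m$beta <- new_param(numeric(C))
  m$params <- list(m$gamma, m$beta)
  m$eps <- eps; m$C <- C
  m$forward <- function(x, train = FALSE) {
    d <- dim(x); n <- d[1] * d[2]
    xm <- matrix(x, n, d[3])
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    invstd <- 1 / sqrt(v + m$eps)
    xhat <- xc * invstd
    m$cache <- list(xhat = xhat, invstd = invstd, d = d)
    y <- xhat * matrix(m$gamma$value, n, d[3], byrow = TRUE) +
      matrix(m$beta$value, n, d[3], byrow = TRUE)
    array(y, d)
  }
  m$backward <- function(gy) {
    cc <- m$cache; d <- cc$d; n <- d[1] * d[2]; C <- d[3]
    gym <- matrix(gy, n, C)
    m$gamma$grad <- m$gamma$grad + colSums(gym * cc$xhat)
    m$beta$grad <- m$beta$grad + colSums(gym)
    gh <- gym * matrix(m$gamma$value, n, C, byrow = TRUE)
    s1 <- rowMeans(gh)
    s2 <- rowMeans(gh * cc$xhat)
    gx <- cc$invstd * (gh - s1 - cc$xhat * s2)
    array(gx, d)
  }
  m
}

# ---- fully connected ------------------------------------------------------

linear_layer <- function(cin, cout) {
  m <- new_module("linear_layer")
  m$w <- new_param(matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout))
  m$b <- new_param(numeric(cout))
  m$params <- list(m$w, m$b)
  m$forward <- function(x, train = FALSE) {  # x: numeric vector length cin
    m$cache_x <- x
    drop(crossprod(m$w$value, x)) + m$b$value
  }
  m$backward <- function(gy) {
    m$w$grad <- m$w$grad + outer(m$cache_x, gy)
    m$b$grad <- m$b$grad + gy
    drop(m$w$value %*% gy)
  }
  m
}

# ---- mish as a module -----------------------------------------------------

mish_layer <- function() {
  m <- new_module("mish_layer")
  m$forward <- function(x, train = FALSE) { m$cache_x <- x; mish(x) }
  m$backward <- function(gy) gy * mish_grad(m$cache_x)
  m
}

# ---- 2x2 max pooling ------------------------------------------------------

maxpool_layer <- function() {
  m <- new_module("maxpool_layer")
  m$forward <- function(x, train = FALSE) {
    d <- dim(x)
    r <- cpp_maxpool2_fwd(x)
    m$cache <- list(idx = r$idx, H = d[1], W = d[2])
    r$y
  }
  m$backward <- function(gy) cpp_maxpool2_bwd(gy, m$cache$idx, m$cache$H, m$cache$W)
  m
}

# ---- nearest-neighbour 2x upsampling --------------------------------------

upsample_layer <- function() {
  m <- new_module("upsample_layer")
  m$forward <- function(x, train = FALSE) {
    d <- dim(x)
    m$cache_d <- d
    x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , drop = FALSE]
  }
  m$backward <- function(gy) {
    d <- m$cache_d
    io <- seq(1, 2 * d[1], by = 2); jo <- seq(1, 2 * d[2], by = 2)
    gy[io, jo, , drop = FALSE] + gy[io + 1, jo, , drop = FALSE] +
      gy[io, jo + 1, , drop = FALSE] + gy[io + 1, jo + 1, , drop = FALSE]
  }
  m
}
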