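# Shared fixtures: small numeric-gradient helper, tiny phantom datasets,
# and a memoized desk-scale training run reused by the end-to-end tests.

num_grad <- function(f, x, gy, h = 1e-6) {
  g <- array(0, dim(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- sum((f(xp) - f(xm)) * gy) / (2 * h)
  }
  g
}

random_mask <- function(h, w, p = 0.3) matrix(rbinom(h * w, 1, p), h, w)

# dense reference attention: materializes the full M1 x M2 logit matrix in
# plain R, independent of the C++ blockwise path
dense_attention <- function(Q, K, V, qpos, kpos, table, radius) {
  scale <- 1 / sqrt(ncol(Q))
  L <- Q %*% t(K) * scale
  for (i in seq_len(nrow(Q))) {
    dr <- pmin(pmax(qpos[i, 1] - kpos[, 1], -radius), radius)
    dc <- pmin(pmax(qpos[i, 2] - kpos[, 2], -radius), radius)
    L[i, ] <- L[i, ] + table[cbind(dr + radius + 1, dc + radius + 1)]
  }
  P <- exp(L - apply(L, 1, max))
  P <- P / rowSums(P)
  P %*% V
}

desk_net_config <- function(...) {
  lca_net_config(depth = 4, widths = c(8L, 16L, 32L, 64L), input_size = 64L,
                 attn_max_hw = 16L, ...)
}

desk_control <- function(...) {
  lca_train_control(epochs = 30L, batch_size = 1L, seed = 42L, ...)
}

desk_spec <- function() phantom_spec(image_size = 64L, edge_blur_sigma = 0.5)

# train once per session; both the learning-check and the ablation-direction
# tests reuse these fits
.desk_cache <- new.env(parent = emptyenv())

desk_data <- function() {
  if (is.null(.desk_cache$data)) {
    spec <- desk_spec()
    .desk_cache$data <- list(train = generate_dataset(200, spec, seed = 1000L),
                             val = generate_dataset(50, spec, seed = 5000L),
                             test = generate_dataset(50, spec, seed = 9000L))
  }
  .desk_cache$data
}

desk_fit <- function(which = c("full", "backbone_only")) {
  which <- match.arg(which)
  key <- paste0("fit_", which)
  if (is.null(.desk_cache[[key]])) {
    d <- desk_data()
    cfg <- if (which == "full") desk_net_config()
           else desk_net_config(use_attention = FALSE, use_nac = FALSE)
    .desk_cache[[key]] <- lca_fit(d$train, d$val, net = cfg, control = desk_control())
  }
  .desk_cache[[key]]
}

desk_test_dice <- function(which = "full") {
  fit <- desk_fit(which)
  evaluate(fit, desk_data()$test)$summary$dice
}
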