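# LCA-Net assembly: a U-shaped encoder-decoder. The full-resolution stage
# uses plain 3x3 convolutions (detail-preserving input/output ports); each
# deeper encoder stage is max-pool -> 3x3 conv + Mish (channel change) ->
# backbone block -> context-attention (at levels whose spatial size is small
# enough for the configured attention scope); the bottleneck ends with the
# NAC block; the decoder mirrors the encoder with nearest-neighbour
# upsampling, decoder (cross) attention fed by the encoder skip, and a
# backbone block. The head is a 1x1 convolution with a per-pixel two-class
# softmax.

#' Network configuration
#'
#' @param depth number of pyramid levels including full resolution.
#' @param widths channel count per level, length `depth`.
#' @param input_size spatial size the model is built for (square input);
#'   must be divisible by `2^(depth - 1)`.
#' @param attn_max_hw apply context-attention only at levels whose spatial
#'   size is at most this (global all-pairs attention is quadratic in pixel
#'   count, so it is restricted to coarse levels).
#' @param use_backbone,use_attention,use_nac module switches for ablations.
#' @param s key-value window stride in the attention blocks.
#' @param attn_mode `"global"` or `"paired"` attention scope.
#' @param radius relative-position bias clipping radius.
#' @return An object of class `lca_net_config`.
#' @export
lca_net_config <- function(depth = 5L, widths = c(16L, 32L, 64L, 128L, 256L),
                           input_size = 256L, attn_max_hw = 32L,
                           use_backbone = TRUE, use_attention = TRUE,
                           use_nac = TRUE, s = 1L,
                           attn_mode = c("global", "paired"), radius = 15L) {
  attn_mode <- match.arg(attn_mode)
  if (length(widths) != depth) stop_config("widths must have length depth")
  if (any(widths < 1)) stop_config("widths must be positive")
  if (input_size %% 2^(depth - 1) != 0)
    stop_config("input_size must be divisible by 2^(depth - 1)")
  structure(list(depth = as.integer(depth), widths = as.integer(widths),
                 input_size = as.integer(input_size),
                 attn_max_hw = as.integer(attn_max_hw),
                 use_backbone = isTRUE(use_backbone),
                 use_attention = isTRUE(use_attention),
                 use_nac = isTRUE(use_nac), s = as.integer(s),
                 attn_mode = attn_mode, radius = as.integer(radius)),
            class = "lca_net_config")
}

#' Build an LCA-Net model
#'
#' Assembles the encoder-decoder from the configured blocks. Weights are
#' drawn from the current RNG state (seed before building for
#' reproducibility); residual-branch output convolutions are
#' zero-initialized so the fresh network is a near-identity U-shape.
#'
#' @param cfg an [lca_net_config()].
#' @return A model of class `lca_net` with `$forward(x, train)` returning an
#'   (H, W, 2) per-pixel probability array and `$backward(gp)` for training.
#' @export
build_lca_net <- function(cfg) {
  if (!inherits(cfg, "lca_net_config")) stop_config("cfg must be an lca_net_config")
  d <- cfg$depth; w <- cfg$widths
  sizes <- cfg$input_size / 2^(seq_len(d) - 1)
  net <- new_module("lca_net")
  net$cfg <- cfg
  has_attn <- cfg$use_attention & (sizes <= cfg$attn_max_hw) & (seq_len(d) > 1)

  net$enc1 <- list(conv_layer(1, w[1], 3, 3), mish_layer(),
                   conv_layer(w[1], w[1], 3, 3), mish_layer())
  net$enc <- vector("list", d)
  for (l in 2:d) {
    st <- list(pool = maxpool_layer(),
               conv = conv_layer(w[l - 1], w[l], 3, 3),
               act = mish_layer(),
               backbone = if (cfg$use_backbone) backbone_block(w[l]) else NULL,
               attn = if (has_attn[l])
                 attention_block(w[l], s = cfg$s, mode = cfg$attn_mode,
                                 radius = cfg$radius) else NULL)
    net$enc[[l]] <- st
  }
  net$nac <- if (cfg$use_nac) nac_block(w[d]) else NULL
  net$dec <- vector("list", d)
  for (l in (d - 1):2) {
    st <- list(up = upsample_layer(),
               upconv = conv_layer(w[l + 1], w[l], 1, 1),
               attn = if (has_attn[l])
                 attention_block(w[l], s = cfg$s, mode = cfg$attn_mode,
                                 radius = cfg$radius) else NULL,
               backbone = if (cfg$use_backbone) backbone_block(w[l]) else NULL)
    net$dec[[l]] <- st
  }
  net$dec1 <- list(up = upsample_layer(), upconv = conv_layer(w[2], w[1], 1, 1),
                   conv_a = conv_layer(w[1], w[1], 3, 3), act_a = mish_layer(),
                   conv_b = conv_layer(w[1], w[1], 3, 3), act_b = mish_layer())
  net$head <- conv_layer(w[1], 2, 1, 1)

  mods <- c(net$enc1,
            unlist(lapply(net$enc[2:d], function(st) Filter(Negate(is.null), st)),
                   use.names = FALSE),
            if (!is.null(net$nac)) list(net$nac),
            if (d > 2) unlist(lapply(net$dec[2:(d - 1)],
                                     function(st) Filter(Negate(is.null), st)),
                              use.names = FALSE),
            net$dec1, list(net$head))
  net$children <- mods

  net$forward <- function(x, train = FALSE) {
    x <- as_map3(x)
    s <- vector("list", d)
    h <- x
    for (m in net$enc1) h <- m$forward(h, train)
    s[[1]] <- h
    for (l in 2:d) {
      st <- net$enc[[l]]
      h <- st$act$forward(st$conv$forward(st$pool$forward(h, train), train), train)
      if (!is.null(st$backbone)) h <- st$backbone$forward(h, train)
      if (!is.null(st$attn)) h <- st$attn$forward(h, NULL, train)
      s[[l]] <- h
    }
    if (!is.null(net$nac)) h <- net$nac$forward(h, train)
    for (l in (d - 1):2) {
      if (l < 2) break
      st <- net$dec[[l]]
      u <- st$upconv$forward(st$up$forward(h, train), train)
      h <- if (!is.null(st$attn)) st$attn$forward(u, s[[l]], train) + s[[l]]
           else u + s[[l]]
      if (!is.null(st$backbone)) h <- st$backbone$forward(h, train)
    }
    st <- net$dec1
    u <- st$upconv$forward(st$up$forward(h, train), train)
    h <- u + s[[1]]
    h <- st$act_a$forward(st$conv_a$forward(h, train), train)
    h <- st$act_b$forward(st$conv_b$forward(h, train), train)
    z <- net$head$forward(h, train)
    zm <- pmax(z[, , 1], z[, , 2])
    e1 <- exp(z[, , 1] - zm); e2 <- exp(z[, , 2] - zm)
    tot <- e1 + e2
    p <- array(c(e1 / tot, e2 / tot), dim(z))
    net$cache_p <- p
    p
  }

  net$backward <- function(gp) {
    p <- net$cache_p
    dot <- p[, , 1] * gp[, , 1] + p[, , 2] * gp[, , 2]
    gz <- array(c(p[, , 1] * (gp[, , 1] - dot), p[, , 2] * (gp[, , 2] - dot)),
                dim(p))
    g <- net$head$backward(gz)
    st <- net$dec1
    g <- st$conv_b$backward(st$act_b$backward(g))
    g <- st$conv_a$backward(st$act_a$backward(g))
    gs <- vector("list", d)
    gs[[1]] <- g
    g <- st$up$backward(st$upconv$backward(g))
    for (l in 2:(d - 1)) {
      if (l > d - 1) break
      st <- net$dec[[l]]
      if (!is.null(st$backbone)) g <- st$backbone$backward(g)
      if (!is.null(st$attn)) {
        r <- st$attn$backward(g)
        gu <- r$gx
        gs[[l]] <- r$gskip + g
      } else {
        gu <- g
        gs[[l]] <- g
      }
      g <- st$up$backward(st$upconv$backward(gu))
    }
    if (!is.null(net$nac)) g <- net$nac$backward(g)
    for (l in d:2) {
      st <- net$enc[[l]]
      if (!is.null(st$attn)) g <- st$attn$backward(g)$gx
      if (!is.null(st$backbone)) g <- st$backbone$backward(g)
      g <- st$pool$backward(st$conv$backward(st$act$backward(g)))
      g <- g + if (l - 1 >= 1 && !is.null(gs[[l - 1]])) gs[[l - 1]] else 0
    }
    for (m in rev(net$enc1)) g <- m$backward(g)
    g
  }
  net
}

#' Predict a binary nodule mask
#'
#' Runs the model in inference mode (running batch-norm statistics, no
#' stochastic components, so predictions are deterministic) and takes the
#' per-pixel argmax over the two class channels.
#'
#' @param model an `lca_net` model or an [lca_fit()] object.
#' @param image H x W matrix with intensities in \[0, 1\]; H and W must be
#'   divisible by `2^(depth - 1)`.
#' @return Binary H x W mask matrix (1 = nodule).
#' @export
predict_mask <- function(model, image) {
  if (inherits(model, "lca_fit")) model <- model$model
  if (!is.matrix(image)) stop_valid("image must be an H x W matrix")
  dd <- 2^(model$cfg$depth - 1)
  if (any(dim(image) %% dd != 0))
    stop_valid(sprintf("image dims must be divisible by %d", dd))
  p <- model$forward(image, train = FALSE)
  (p[, , 2] > p[, , 1]) * 1
}

#' Count trainable weights of a model or block
#'
#' @param model any module built by this package (a full `lca_net`, a
#'   [backbone_block()], [nac_block()], [attention_block()], ...).
#' @return Integer total number of trainable weights.
#' @export
count_parameters <- function(model) {
  if (inherits(model, "lca_fit")) model <- model$model
  n_weights(model)
}
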