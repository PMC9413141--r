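# Context-attention block: 8x8 query windows attend to overlapping 10x10
# key-value windows (stride s) with a learned relative-position bias. In the
# encoder the block self-attends; in the decoder the query comes from the
# same-level encoder skip and key-value from the deeper decoder stream.
#
# Maps are reflect-padded on the bottom/right so H and W become multiples of
# 8 (and at least 16 when the input is smaller than the 10-pixel key-value
# window); outputs are cropped back. Two attention scopes are available:
# "global" (every query pixel attends to every key-value pixel, the M1 x M2
# layout the bias shape implies) and "paired" (each 8x8 query window attends
# only to its aligned 10x10 key-value window with a 1-pixel halo), the
# tractable variant for large maps.

padded_dim <- function(n) {
  np <- 8L * as.integer(ceiling(n / 8))
  if (np < 10L) np <- 16L
  np
}

pad_map <- function(x, Hp, Wp, halo = 0L) {
  d <- dim(x)
  ri <- reflect_idx((-halo):(Hp + halo - 1L), d[1])
  ci <- reflect_idx((-halo):(Wp + halo - 1L), d[2])
  x[ri, ci, , drop = FALSE]
}

# backward of pad_map: scatter-add padded gradients to source pixels
unpad_grad <- function(gpad, H, W, halo = 0L) {
  d <- dim(gpad)
  ri <- reflect_idx((-halo):(d[1] - halo - 1L), H)
  ci <- reflect_idx((-halo):(d[2] - halo - 1L), W)
  m <- rowsum(matrix(gpad, d[1], d[2] * d[3]), group = ri)
  a <- array(m, c(H, d[2], d[3]))
  ap <- aperm(a, c(2, 1, 3))
  m2 <- rowsum(matrix(ap, d[2], H * d[3]), group = ci)
  aperm(array(m2, c(W, H, d[3])), c(2, 1, 3))
}

# flat (column-major) indices and 0-based (row, col) positions of the query
# tiling: non-overlapping 8x8 windows, pixels column-major within a window
query_pattern <- function(Hp, Wp) {
  nwi <- Hp %/% 8L; nwj <- Wp %/% 8L
  wi <- rep(0:(nwi - 1L), times = nwj); wj <- rep(0:(nwj - 1L), each = nwi)
  oi <- rep(0:7, times = 8); oj <- rep(0:7, each = 8)
  rows <- outer(oi, wi * 8L, `+`); cols <- outer(oj, wj * 8L, `+`)
  list(idx = as.integer(rows) + as.integer(cols) * Hp + 1L,
       pos = cbind(as.integer(rows), as.integer(cols)),
       n_patches = nwi * nwj)
}

# how many stride-s 10x10 windows cover each 1-D coordinate
window_mult <- function(Hp, s) {
  r0 <- seq(0L, Hp - 10L, by = s)
  vapply(0:(Hp - 1L), function(r) sum(r0 <= r & r0 >= r - 9L), 0L)
}

# unique-pixel key-value layout: softmax over the overlapping duplicated
# windows equals softmax over unique pixels with a log-multiplicity bias
# (duplicated rows share content and position, hence logits), so the module
# attends over Hp*Wp keys instead of N2*100
kv_unique_pattern <- function(Hp, Wp, s) {
  mr <- window_mult(Hp, s); mc <- window_mult(Wp, s)
  rows <- rep(0:(Hp - 1L), times = Wp); cols <- rep(0:(Wp - 1L), each = Hp)
  keep <- mr[rows + 1L] > 0 & mc[cols + 1L] > 0
  list(idx = which(keep),
       pos = cbind(rows[keep], cols[keep]),
       logmult = log(mr[rows + 1L][keep]) + log(mc[cols + 1L][keep]))
}

# overlapping 10x10 key-value windows at stride s
kv_pattern <- function(Hp, Wp, s) {
  r0 <- seq(0L, Hp - 10L, by = s); c0 <- seq(0L, Wp - 10L, by = s)
  wi <- rep(r0, times = length(c0)); wj <- rep(c0, each = length(r0))
  oi <- rep(0:9, times = 10); oj <- rep(0:9, each = 10)
  rows <- outer(oi, wi, `+`); cols <- outer(oj, wj, `+`)
  list(idx = as.integer(rows) + as.integer(cols) * Hp + 1L,
       pos = cbind(as.integer(rows), as.integer(cols)),
       n_patches = length(r0) * length(c0))
}

#' Partition a feature map into query patches
#'
#' Reflect-pads the map so both spatial dimensions are multiples of 8 (and
#' at least 16 when smaller than the key-value window), then tiles it into
#' non-overlapping 8x8 query windows.
#'
#' @param q feature map, an (H, W, C) array or H x W matrix.
#' @return An object of class `patch_set` with fields `mat` (flattened
#'   pixels x channels), `pos` (0-based pixel positions on the padded map),
#'   `window`, `stride`, `n_patches` (N1) and `flat_len` (M1 = N1 * 64).
#' @examples
#' ps <- split_query(array(rnorm(256 * 256), c(256, 256, 1)))
#' ps$n_patches   # 1024 windows
#' ps$flat_len    # 65536 query pixels
#' @export
split_query <- function(q) {
  q <- as_map3(q)
  d <- dim(q)
  Hp <- padded_dim(d[1]); Wp <- padded_dim(d[2])
  qp <- pad_map(q, Hp, Wp)
  pat <- query_pattern(Hp, Wp)
  structure(list(mat = matrix(qp, Hp * Wp, d[3])[pat$idx, , drop = FALSE],
                 pos = pat$pos, window = 8L, stride = 8L,
                 n_patches = pat$n_patches, flat_len = length(pat$idx),
                 padded = c(Hp, Wp), dims = d),
            class = "patch_set")
}

#' Partition a feature map into overlapping key-value patches
#'
#' As [split_query()] but with 10x10 windows slid at stride `s`, so windows
#' overlap and pixels are repeated; N2 = ((H-10)/s + 1) * ((W-10)/s + 1) on
#' the padded map.
#'
#' @param kv feature map, an (H, W, C) array or matrix.
#' @param s positive integer stride of the sliding key-value window.
#' @return A `patch_set` (see [split_query()]); `flat_len` is M2 = N2 * 100.
#' @export
split_kv <- function(kv, s = 1L) {
  if (s < 1) stop_valid("stride s must be a positive integer")
  kv <- as_map3(kv)
  d <- dim(kv)
  Hp <- padded_dim(d[1]); Wp <- padded_dim(d[2])
  kp <- pad_map(kv, Hp, Wp)
  pat <- kv_pattern(Hp, Wp, as.integer(s))
  structure(list(mat = matrix(kp, Hp * Wp, d[3])[pat$idx, , drop = FALSE],
                 pos = pat$pos, window = 10L, stride = as.integer(s),
                 n_patches = pat$n_patches, flat_len = length(pat$idx),
                 padded = c(Hp, Wp), dims = d),
            class = "patch_set")
}

#' Zero-initialized relative position bias table
#'
#' The learned additive logit bias depends only on the clipped 2-D offset
#' between a query pixel and a key pixel, so it is stored as a
#' (2 * radius + 1) square table.
#'
#' @param radius clipping radius for offsets (default 15 pixels).
#' @return A numeric matrix of zeros.
#' @export
rel_pos_table <- function(radius = 15L) {
  matrix(0, 2L * radius + 1L, 2L * radius + 1L)
}

#' Scaled dot-product attention over patch sets
#'
#' Computes softmax((Q K' + phi) / sqrt(C')) V where the bias phi between a
#' query pixel and a key pixel is looked up from `bias` by their clipped
#' relative offset. Every output row is a convex combination of value rows.
#'
#' @param qp,kp,vp `patch_set` objects from [split_query()] / [split_kv()];
#'   `kp` and `vp` must share the same layout.
#' @param bias square bias table as from [rel_pos_table()], or `NULL` for no
#'   bias.
#' @return Matrix of attended features, `qp$flat_len` rows x C' columns.
#' @export
scaled_attention <- function(qp, kp, vp, bias = NULL) {
  if (!identical(kp$pos, vp$pos)) stop_dim("key and value patch sets differ in layout")
  if (ncol(qp$mat) != ncol(kp$mat)) stop_dim("query/key embedding widths differ")
  if (is.null(bias)) bias <- rel_pos_table()
  radius <- (nrow(bias) - 1L) %/% 2L
  cpp_attn_fwd(qp$mat, kp$mat, vp$mat,
               qp$pos, kp$pos, bias, numeric(nrow(kp$mat)), radius)
}

# full softmax matrix, for tests/diagnostics on small maps
attention_probs <- function(qp, kp, bias = NULL) {
  if (is.null(bias)) bias <- rel_pos_table()
  radius <- (nrow(bias) - 1L) %/% 2L
  cpp_attn_probs(qp$mat, kp$mat, qp$pos, kp$pos, bias,
                 numeric(nrow(kp$mat)), radius)
}

# ---- the block as a trainable module --------------------------------------

#' Construct a context-attention block
#'
#' A trainable residual block: layer-normalize, project to query/key/value
#' with 1x1 convolutions at embedding width `c_embed`, run windowed
#' attention with relative position bias, project back (zero-initialized, so
#' a freshly built block is the identity), then a second LayerNorm + 1x1
#' convolution residual stage. With a `skip` map at forward time the block
#' is the decoder (cross) variant: the query comes from `skip`, key-value
#' from the main input.
#'
#' @param C channel count of the input feature map.
#' @param c_embed embedding width C' (default `max(1, C/2)`).
#' @param s key-value window stride (default 1).
#' @param mode `"global"` (all query pixels attend to all key-value pixels)
#'   or `"paired"` (each 8x8 query window attends to its aligned 10x10
#'   key-value window with a 1-pixel halo).
#' @param radius relative-position clipping radius.
#' @return A module; call [context_attention_forward()] on it.
#' @export
attention_block <- function(C, c_embed = NULL, s = 1L,
                            mode = c("global", "paired"), radius = 15L) {
  mode <- match.arg(mode)
  if (is.null(c_embed)) c_embed <- max(1L, C %/% 2L)
  m <- new_module("attention_block")
  m$C <- C; m$ce <- c_embed; m$s <- as.integer(s); m$mode <- mode
  m$radius <- as.integer(radius)
  m$ln_x <- ln_layer(C); m$ln_q <- ln_layer(C); m$ln2 <- ln_layer(C)
  m$convq <- conv_layer(C, c_embed, 1, 1)
  m$convk <- conv_layer(C, c_embed, 1, 1)
  m$convv <- conv_layer(C, c_embed, 1, 1)
  m$convo <- conv_layer(c_embed, C, 1, 1, init = "zero")
  m$convo2 <- conv_layer(C, C, 1, 1, init = "zero")
  m$table <- new_param(rel_pos_table(radius))
  m$children <- list(m$ln_x, m$ln_q, m$ln2, m$convq, m$convk, m$convv,
                     m$convo, m$convo2)
  m$params <- list(m$table)
  m$pat_cache <- list()

  pattern_for <- function(H, W) {
    key <- paste(H, W, m$s, m$mode, sep = "_")
    if (!is.null(m$pat_cache[[key]])) return(m$pat_cache[[key]])
    Hp <- padded_dim(H); Wp <- padded_dim(W)
    qpat <- query_pattern(Hp, Wp)
    if (m$mode == "global") {
      kpat <- kv_unique_pattern(Hp, Wp, m$s)
    } else {
      # per query window: 10x10 kv window with 1-px halo, indices into the
      # (Hp+2) x (Wp+2) halo-padded map; positions on the base grid
      nwi <- Hp %/% 8L; nwj <- Wp %/% 8L
      wi <- rep(0:(nwi - 1L), times = nwj); wj <- rep(0:(nwj - 1L), each = nwi)
      oi <- rep(0:9, times = 10); oj <- rep(0:9, each = 10)
      rows <- outer(oi, wi * 8L, `+`); cols <- outer(oj, wj * 8L, `+`)
      # rows/cols are halo-map coordinates (0-based); base position = -1 offset
      kpat <- list(idx_mat = matrix(as.integer(rows) + as.integer(cols) * (Hp + 2L) + 1L,
                                    100, nwi * nwj),
                   pos_base = list(rows = rows - 1L, cols = cols - 1L),
                   n_patches = nwi * nwj)
    }
    pat <- list(Hp = Hp, Wp = Wp, qpat = qpat, kpat = kpat)
    m$pat_cache[[key]] <- pat
    pat
  }

  m$forward <- function(x, skip = NULL, train = FALSE) {
    d <- dim(x)
    if (!is.null(skip) && !identical(dim(skip)[1:2], d[1:2]))
      stop_dim("skip and input must share spatial dimensions")
    xn <- m$ln_x$forward(x, train)
    kmap <- m$convk$forward(xn, train)
    vmap <- m$convv$forward(xn, train)
    qsrc <- if (is.null(skip)) xn else m$ln_q$forward(skip, train)
    qmap <- m$convq$forward(qsrc, train)
    pat <- pattern_for(d[1], d[2])
    Hp <- pat$Hp; Wp <- pat$Wp
    qpad <- pad_map(qmap, Hp, Wp)
    cache <- list(d = d, pat = pat, has_skip = !is.null(skip))
    if (m$mode == "global") {
      kpad <- pad_map(kmap, Hp, Wp); vpad <- pad_map(vmap, Hp, Wp)
      Q <- matrix(qpad, Hp * Wp, m$ce)[pat$qpat$idx, , drop = FALSE]
      K <- matrix(kpad, Hp * Wp, m$ce)[pat$kpat$idx, , drop = FALSE]
      V <- matrix(vpad, Hp * Wp, m$ce)[pat$kpat$idx, , drop = FALSE]
      rows <- cpp_attn_fwd(Q, K, V, pat$qpat$pos, pat$kpat$pos,
                           m$table$value, pat$kpat$logmult, m$radius)
      omat <- matrix(0, Hp * Wp, m$ce)
      omat[pat$qpat$idx, ] <- rows
      cache$QKV <- list(Q = Q, K = K, V = V)
    } else {
      kpad <- pad_map(kmap, Hp, Wp, halo = 1L)
      vpad <- pad_map(vmap, Hp, Wp, halo = 1L)
      kmat <- matrix(kpad, (Hp + 2L) * (Wp + 2L), m$ce)
      vmat <- matrix(vpad, (Hp + 2L) * (Wp + 2L), m$ce)
      qmat <- matrix(qpad, Hp * Wp, m$ce)
      omat <- matrix(0, Hp * Wp, m$ce)
      nwin <- pat$qpat$n_patches
      Qw <- vector("list", nwin); Kw <- vector("list", nwin); Vw <- vector("list", nwin)
      for (w in seq_len(nwin)) {
        qrows <- pat$qpat$idx[((w - 1L) * 64L + 1L):(w * 64L)]
        kidx <- pat$kpat$idx_mat[, w]
        Qw[[w]] <- qmat[qrows, , drop = FALSE]
        Kw[[w]] <- kmat[kidx, , drop = FALSE]
        Vw[[w]] <- vmat[kidx, , drop = FALSE]
        qpos <- pat$qpat$pos[((w - 1L) * 64L + 1L):(w * 64L), , drop = FALSE]
        kpos <- cbind(pat$kpat$pos_base$rows[, w], pat$kpat$pos_base$cols[, w])
        omat[qrows, ] <- cpp_attn_fwd(Qw[[w]], Kw[[w]], Vw[[w]], qpos, kpos,
                                      m$table$value, numeric(100L), m$radius)
      }
      cache$QKV <- list(Qw = Qw, Kw = Kw, Vw = Vw)
    }
    a <- array(omat, c(Hp, Wp, m$ce))[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
    y1p <- x + m$convo$forward(a, train)
    y1 <- y1p + m$convo2$forward(m$ln2$forward(y1p, train), train)
    m$cache <- cache
    y1
  }

  m$backward <- function(gy) {
    cc <- m$cache; d <- cc$d; pat <- cc$pat
    Hp <- pat$Hp; Wp <- pat$Wp
    gy1p <- gy + m$ln2$backward(m$convo2$backward(gy))
    ga <- m$convo$backward(gy1p)
    # re-pad the cropped attention-map gradient (crop backward = zero-pad)
    gpadmat <- matrix(0, Hp * Wp, m$ce)
    full <- array(0, c(Hp, Wp, m$ce))
    full[seq_len(d[1]), seq_len(d[2]), ] <- ga
    gpadmat[] <- matrix(full, Hp * Wp, m$ce)
    if (m$mode == "global") {
      gRows <- gpadmat[pat$qpat$idx, , drop = FALSE]
      r <- cpp_attn_bwd(cc$QKV$Q, cc$QKV$K, cc$QKV$V,
                        pat$qpat$pos, pat$kpat$pos, m$table$value,
                        pat$kpat$logmult, m$radius, gRows)
      m$table$grad <- m$table$grad + r$gTable
      gqpadm <- matrix(0, Hp * Wp, m$ce); gqpadm[pat$qpat$idx, ] <- r$gQ
      gkpadm <- matrix(0, Hp * Wp, m$ce); gkpadm[pat$kpat$idx, ] <- r$gK
      gvpadm <- matrix(0, Hp * Wp, m$ce); gvpadm[pat$kpat$idx, ] <- r$gV
      gqmap <- unpad_grad(array(gqpadm, c(Hp, Wp, m$ce)), d[1], d[2])
      gkmap <- unpad_grad(array(gkpadm, c(Hp, Wp, m$ce)), d[1], d[2])
      gvmap <- unpad_grad(array(gvpadm, c(Hp, Wp, m$ce)), d[1], d[2])
    } else {
      gqpadm <- matrix(0, Hp * Wp, m$ce)
      gkh <- matrix(0, (Hp + 2L) * (Wp + 2L), m$ce)
      gvh <- matrix(0, (Hp + 2L) * (Wp + 2L), m$ce)
      nwin <- pat$qpat$n_patches
      for (w in seq_len(nwin)) {
        qrows <- pat$qpat$idx[((w - 1L) * 64L + 1L):(w * 64L)]
        kidx <- pat$kpat$idx_mat[, w]
        qpos <- pat$qpat$pos[((w - 1L) * 64L + 1L):(w * 64L), , drop = FALSE]
        kpos <- cbind(pat$kpat$pos_base$rows[, w], pat$kpat$pos_base$cols[, w])
        r <- cpp_attn_bwd(cc$QKV$Qw[[w]], cc$QKV$Kw[[w]], cc$QKV$Vw[[w]],
                          qpos, kpos, m$table$value, numeric(100L), m$radius,
                          gpadmat[qrows, , drop = FALSE])
        m$table$grad <- m$table$grad + r$gTable
        gqpadm[qrows, ] <- gqpadm[qrows, ] + r$gQ
        gkh <- gkh + scatter_rows(r$gK, kidx, nrow(gkh))
        gvh <- gvh + scatter_rows(r$gV, kidx, nrow(gvh))
      }
      gqmap <- unpad_grad(array(gqpadm, c(Hp, Wp, m$ce)), d[1], d[2])
      gkmap <- unpad_grad(array(gkh, c(Hp + 2L, Wp + 2L, m$ce)), d[1], d[2], halo = 1L)
      gvmap <- unpad_grad(array(gvh, c(Hp + 2L, Wp + 2L, m$ce)), d[1], d[2], halo = 1L)
    }
    gqsrc <- m$convq$backward(gqmap)
    gxn <- m$convk$backward(gkmap) + m$convv$backward(gvmap)
    gskip <- NULL
    if (cc$has_skip) {
      gskip <- m$ln_q$backward(gqsrc)
    } else {
      gxn <- gxn + gqsrc
    }
    gx <- gy1p + m$ln_x$backward(gxn)
    list(gx = gx, gskip = gskip)
  }
  m
}

#' Run a context-attention block
#'
#' Forward pass of an [attention_block()]. Without `skip` the block
#' self-attends (encoder variant); with `skip` the query is drawn from
#' `skip` and key-value from `x` (decoder variant). Output dimensions equal
#' those of `x`.
#'
#' @param block a module from [attention_block()].
#' @param x input feature map, (H, W, C) array.
#' @param skip optional feature map with the same spatial dimensions.
#' @param train logical; training-mode statistics.
#' @return Feature map with the dimensions of `x`.
#' @export
context_attention_forward <- function(block, x, skip = NULL, train = FALSE) {
  block$forward(as_map3(x), if (is.null(skip)) NULL else as_map3(skip), train)
}
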