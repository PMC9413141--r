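# Segmentation losses. A probability map is an (H, W, 2) array of per-pixel
# class probabilities (background, nodule) summing to 1 at each pixel; the
# truth is an (H, W, 2) one-hot array. Each loss comes with a closed-form
# gradient with respect to the probability map, used by the training loop.

check_prob_pair <- function(p, r) {
  if (!identical(dim(p), dim(r))) stop_dim("probability map and truth differ in shape")
  if (length(dim(p)) != 3 || dim(p)[3] != 2)
    stop_dim("expected (H, W, 2) arrays")
}

#' Class-imbalance segmentation loss
#'
#' The package's own pixel loss for foreground/background imbalance. For the
#' true-class probability \eqn{p} at a pixel the per-pixel term is
#' \eqn{-\log(p(1-p)^2 + p^2/2)}: the \eqn{(1-p)^2} factor up-weights
#' misclassified pixels (as in focal-type losses) and the \eqn{p^2/2}
#' fine-tuning term keeps well-classified pixels contributing. The loss is
#' averaged over pixels (division by \eqn{H W} only). Its minimum is
#' \eqn{\log 2}, attained at \eqn{p = 1}, not 0; the training curves are
#' offset by that constant. The log argument is clamped below at `eps`
#' because the raw expression diverges at \eqn{p = 0}.
#'
#' @param p (H, W, 2) probability array.
#' @param r (H, W, 2) one-hot truth array.
#' @param eps clamp on the log argument (default `1e-7`).
#' @param variant `"standard"` reads the fine-tuning term as \eqn{p^2/2};
#'   `"halved"` divides the whole inner expression by 2 instead.
#' @return Non-negative scalar loss.
#' @examples
#' p <- array(c(0, 1), c(1, 1, 2))   # certain foreground
#' r <- array(c(0, 1), c(1, 1, 2))
#' lca_loss(p, r)   # log(2): the loss floor
#' @export
lca_loss <- function(p, r, eps = 1e-7, variant = c("standard", "halved")) {
  variant <- match.arg(variant)
  check_prob_pair(p, r)
  g <- if (variant == "standard") p * (1 - p)^2 + p^2 / 2
       else (p * (1 - p)^2 + p^2) / 2
  -sum(r * log(pmax(g, eps))) / (dim(p)[1] * dim(p)[2])
}

lca_loss_grad <- function(p, r, eps = 1e-7, variant = "standard") {
  g <- if (variant == "standard") p * (1 - p)^2 + p^2 / 2
       else (p * (1 - p)^2 + p^2) / 2
  dg <- if (variant == "standard") 3 * p^2 - 3 * p + 1
        else (3 * p^2 - 4 * p + 1 + 2 * p) / 2   # d/dp of (p(1-p)^2 + p^2)/2
  gr <- -r * ifelse(g > eps, dg / g, 0) / (dim(p)[1] * dim(p)[2])
  array(gr, dim(p))
}

#' Binary cross-entropy loss on a two-class probability map
#'
#' Standard pixel-mean cross-entropy \eqn{-\frac{1}{HW}\sum R \log p}, with
#' the probability clamped below at `eps`.
#'
#' @inheritParams lca_loss
#' @return Non-negative scalar.
#' @export
bce_loss <- function(p, r, eps = 1e-7) {
  check_prob_pair(p, r)
  -sum(r * log(pmax(p, eps))) / (dim(p)[1] * dim(p)[2])
}

bce_loss_grad <- function(p, r, eps = 1e-7) {
  array(-r / pmax(p, eps) / (dim(p)[1] * dim(p)[2]), dim(p))
}

#' Soft Dice loss on the foreground channel
#'
#' One minus the soft Dice overlap between the foreground probability and
#' the foreground indicator, with smoothing `eps_d` added to numerator and
#' denominator so empty masks are well defined.
#'
#' @inheritParams lca_loss
#' @param eps_d smoothing constant (default 1).
#' @return Scalar in \[0, 1\].
#' @export
dice_loss <- function(p, r, eps_d = 1.0) {
  check_prob_pair(p, r)
  fg <- p[, , 2]; t <- r[, , 2]
  1 - (2 * sum(fg * t) + eps_d) / (sum(fg) + sum(t) + eps_d)
}

dice_loss_grad <- function(p, r, eps_d = 1.0) {
  fg <- p[, , 2]; t <- r[, , 2]
  num <- 2 * sum(fg * t) + eps_d
  den <- sum(fg) + sum(t) + eps_d
  gfg <- -(2 * t * den - num) / den^2
  g <- array(0, dim(p)); g[, , 2] <- gfg
  g
}

#' Select a loss by name
#'
#' @param name one of `"lca"`, `"bce"`, `"dice"`.
#' @return A list with elements `name`, `loss(p, r)` and `grad(p, r)` (the
#'   gradient with respect to the probability map).
#' @export
loss_factory <- function(name) {
  switch(name,
    lca = list(name = "lca", loss = lca_loss, grad = lca_loss_grad),
    bce = list(name = "bce", loss = bce_loss, grad = bce_loss_grad),
    dice = list(name = "dice", loss = dice_loss, grad = dice_loss_grad),
    stop_config(sprintf("unknown loss '%s' (use lca, bce or dice)", name))
  )
}
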