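# Ultrasound-like phantom generator. Each phantom is a speckled grayscale
# image containing one low-contrast nodule with a blurred ("weak") edge,
# plus a pixel-accurate binary mask. The generative model: a smooth
# low-frequency background reflectivity field, darkened inside a randomly
# oriented (slightly boundary-perturbed) ellipse by `contrast_drop`, with
# the darkening profile Gaussian-blurred so the image edge is weak, then
# multiplied by gamma-distributed speckle. The mask is the geometric
# ellipse support BEFORE blurring: the weak edge is a property of the image
# only, mirroring expert annotation semantics.

#' Phantom generation parameters
#'
#' @param image_size square image side in pixels.
#' @param size_class `"small"`, `"medium"`, `"large"` (area fractions
#'   0.5-2%, 2-8%, 8-25% of the image) or `"random"`.
#' @param placement `"center"`, `"edge"` (nodule contour touches the image
#'   border), or `"random"`.
#' @param contrast_drop length-2 range (or scalar) of the relative mean
#'   intensity gap between nodule and background, drawn uniformly.
#' @param edge_blur_sigma Gaussian blur of the nodule boundary, pixels.
#' @param speckle_shape gamma shape of the multiplicative speckle (mean 1,
#'   coefficient of variation `1/sqrt(shape)`; default 100: the display-image speckle contrast of the resized clinical frames the phantom miniaturizes).
#' @param bg_level,bg_amplitude mean and amplitude of the smooth background
#'   reflectivity field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_size = 256L,
                         size_class = c("random", "small", "medium", "large"),
                         placement = c("random", "center", "edge"),
                         contrast_drop = c(0.05, 0.3),
                         edge_blur_sigma = 1.5,
                         speckle_shape = 100,
                         bg_level = 0.5, bg_amplitude = 0.02) {
  size_class <- match.arg(size_class)
  placement <- match.arg(placement)
  if (image_size < 16) stop_valid("image_size must be at least 16")
  if (length(contrast_drop) == 1) contrast_drop <- rep(contrast_drop, 2)
  if (any(contrast_drop < 0) || any(contrast_drop > 1) ||
      contrast_drop[1] > contrast_drop[2])
    stop_valid("contrast_drop must be an increasing range within [0, 1]")
  structure(list(image_size = as.integer(image_size), size_class = size_class,
                 placement = placement, contrast_drop = contrast_drop,
                 edge_blur_sigma = edge_blur_sigma,
                 speckle_shape = speckle_shape,
                 bg_level = bg_level, bg_amplitude = bg_amplitude),
            class = "phantom_spec")
}

size_class_range <- function(cls) {
  switch(cls, small = c(0.005, 0.02), medium = c(0.02, 0.08),
         large = c(0.08, 0.25), stop_valid(sprintf("unknown size class '%s'", cls)))
}

# separable Gaussian blur with edge renormalization (so flat fields stay flat)
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  k <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  g <- exp(-((seq_len(k) - (k + 1) / 2)^2) / (2 * sigma^2))
  g <- g / sum(g)
  wv <- matrix(g, k, 1); wh <- matrix(g, k, 1)
  blur1 <- function(m) {
    a <- array(m, c(dim(m), 1L))
    a <- cpp_conv2d_fwd(a, wv, 0, k, 1L, 1L, 1L, FALSE)
    a <- cpp_conv2d_fwd(a, wh, 0, 1L, k, 1L, 1L, FALSE)
    a[, , 1]
  }
  num <- blur1(x)
  den <- blur1(matrix(1, nrow(x), ncol(x)))
  num / den
}

# one draw of the nodule geometry; returns mask or NULL if infeasible
draw_nodule_mask <- function(n, frac, placement) {
  aspect <- runif(1, 0.5, 1)
  r_a <- sqrt(frac * n^2 / (pi * aspect))
  r_b <- aspect * r_a
  if (2 * r_a > 0.95 * n) return(NULL)
  theta <- runif(1, 0, pi)
  namp <- 3
  amp <- runif(namp, 0, 0.08)
  phase <- runif(namp, 0, 2 * pi)
  if (placement == "center") {
    cx <- n / 2 + runif(1, -0.05 * n, 0.05 * n)
    cy <- n / 2 + runif(1, -0.05 * n, 0.05 * n)
  } else if (placement == "edge") {
    side <- sample(4, 1)
    off <- runif(1, 0.1, 0.6) * c(r_a, r_b)[1 + side %% 2]
    cx <- switch(side, off, n - off, runif(1, 0.3 * n, 0.7 * n),
                 runif(1, 0.3 * n, 0.7 * n))
    cy <- switch(side, runif(1, 0.3 * n, 0.7 * n), runif(1, 0.3 * n, 0.7 * n),
                 off, n - off)
  } else {
    cx <- runif(1, 0.15 * n, 0.85 * n)
    cy <- runif(1, 0.15 * n, 0.85 * n)
  }
  xs <- matrix(rep(seq_len(n) - 0.5, n), n, n) - cy
  ys <- matrix(rep(seq_len(n) - 0.5, each = n), n, n) - cx
  u <- cos(theta) * ys + sin(theta) * xs
  v <- -sin(theta) * ys + cos(theta) * xs
  s <- sqrt((u / r_a)^2 + (v / r_b)^2)
  phi <- atan2(v / r_b, u / r_a)
  modr <- 1 + Reduce(`+`, lapply(seq_len(namp), function(k)
    amp[k] * cos((k + 1) * phi + phase[k])))
  (s <= modr) * 1
}

#' Generate one ultrasound-like phantom
#'
#' @param spec a [phantom_spec()].
#' @param seed optional integer; if given, the draw is reproducible.
#' @return An object of class `phantom_sample`: a list with `image` (H x W
#'   matrix in \[0, 1\]), `mask` (binary H x W matrix) and `params` (the
#'   realized size class, placement, contrast and area fraction).
#' @examples
#' s <- generate_phantom(phantom_spec(image_size = 64), seed = 1)
#' mean(s$image); mean(s$mask)
#' @export
generate_phantom <- function(spec, seed = NULL) {
  if (!inherits(spec, "phantom_spec")) stop_valid("spec must be a phantom_spec")
  if (!is.null(seed)) set.seed(seed)
  n <- spec$image_size
  cls <- if (spec$size_class == "random")
    sample(c("small", "medium", "large"), 1) else spec$size_class
  plc <- if (spec$placement == "random")
    sample(c("center", "edge"), 1) else spec$placement
  rng <- size_class_range(cls)
  mask <- NULL
  for (try in 1:60) {
    frac <- runif(1, rng[1], rng[2])
    m <- draw_nodule_mask(n, frac, plc)
    if (is.null(m)) next
    af <- mean(m)
    border_ok <- plc != "edge" ||
      any(m[1, ] == 1) || any(m[n, ] == 1) || any(m[, 1] == 1) || any(m[, n] == 1)
    if (af >= rng[1] && af <= rng[2] && border_ok) { mask <- m; break }
  }
  if (is.null(mask)) stop_valid("could not place a nodule satisfying the spec")
  drop_val <- runif(1, spec$contrast_drop[1], spec$contrast_drop[2])
  # draw the smooth field on a padded grid and crop, so its statistics are
  # stationary up to the image border (border pixels otherwise average fewer
  # noise samples and fluctuate more, which would corrupt edge-placed nodules)
  pad <- as.integer(ceiling(3 * n / 8))
  np <- n + 2L * pad
  field <- matrix(rnorm(np * np), np, np)
  field <- gaussian_blur(field, n / 8)[pad + seq_len(n), pad + seq_len(n)]
  field <- spec$bg_level + spec$bg_amplitude * field / stats::sd(field)
  profile <- gaussian_blur(mask, spec$edge_blur_sigma)
  refl <- field * (1 - drop_val * profile)
  speckle <- matrix(rgamma(n * n, shape = spec$speckle_shape,
                           rate = spec$speckle_shape), n, n)
  img <- pmin(pmax(refl * speckle, 0), 1)
  structure(list(image = img, mask = mask,
                 params = list(size_class = cls, placement = plc,
                               contrast_drop = drop_val, area_fraction = mean(mask),
                               seed = seed)),
            class = "phantom_sample")
}

#' Generate a phantom dataset
#'
#' Draws `n` phantoms with per-sample derived seeds. When the spec leaves
#' `size_class` or `placement` as `"random"`, they are balanced round-robin
#' over the classes (small/medium/large) and placements (center/edge)
#' instead of drawn independently, so every dataset covers all conditions.
#'
#' @param n number of samples.
#' @param spec a [phantom_spec()].
#' @param seed integer base seed; sample i uses seed `seed + i - 1`.
#' @return List of `phantom_sample` objects.
#' @export
generate_dataset <- function(n, spec, seed = 1L) {
  if (n < 1) stop_valid("n must be positive")
  classes <- c("small", "medium", "large")
  placements <- c("center", "edge")
  lapply(seq_len(n), function(i) {
    sp <- spec
    if (spec$size_class == "random") sp$size_class <- classes[(i - 1) %% 3 + 1]
    if (spec$placement == "random") sp$placement <- placements[(i - 1) %% 2 + 1]
    generate_phantom(sp, seed = seed + i - 1L)
  })
}

#' 8:1:1 train/validation/test split
#'
#' Shuffles indices and partitions them 80/10/10: the training set takes
#' `floor(0.8 n)`, the remainder is split equally with an odd remainder's
#' extra item going to validation. For n = 7288 the sizes are
#' (5830, 729, 729).
#'
#' @param n_total number of samples (at least 10).
#' @param seed shuffle seed.
#' @return List with integer index vectors `train`, `val`, `test`
#'   (disjoint, exhaustive).
#' @export
split_811 <- function(n_total, seed = 1L) {
  if (n_total < 10) stop_valid("n_total must be at least 10")
  set.seed(seed)
  idx <- sample.int(n_total)
  n_train <- floor(0.8 * n_total)
  rem <- n_total - n_train
  n_val <- ceiling(rem / 2)
  list(train = idx[seq_len(n_train)],
       val = idx[n_train + seq_len(n_val)],
       test = idx[(n_train + n_val + 1):n_total])
}

#' Write a phantom dataset as PNG pairs with a manifest
#'
#' Images and masks are written as 8-bit grayscale PNGs
#' (`img_%05d.png` / `mask_%05d.png`) with a `manifest.csv` recording the
#' generation parameters of each sample.
#'
#' @param samples list of `phantom_sample` objects.
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_phantom_dataset <- function(samples, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    png::writePNG(s$image, file.path(dir, sprintf("img_%05d.png", i)))
    png::writePNG(s$mask, file.path(dir, sprintf("mask_%05d.png", i)))
    data.frame(id = i, size_class = s$params$size_class,
               placement = s$params$placement,
               area_fraction = s$params$area_fraction,
               seed = if (is.null(s$params$seed)) NA else s$params$seed)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir dataset directory containing `img_*.png` / `mask_*.png`.
#' @return List of samples (image matrix in \[0,1\], binary mask matrix).
#' @export
read_phantom_dataset <- function(dir) {
  imgs <- sort(list.files(dir, pattern = "^img_\\d+\\.png$", full.names = TRUE))
  if (length(imgs) == 0) stop_valid(sprintf("no phantom images under %s", dir))
  lapply(imgs, function(f) {
    mf <- sub("img_", "mask_", f)
    img <- png::readPNG(f); if (length(dim(img)) == 3) img <- img[, , 1]
    msk <- png::readPNG(mf); if (length(dim(msk)) == 3) msk <- msk[, , 1]
    list(image = img, mask = (msk > 0.5) * 1)
  })
}
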