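# Training: augmentation, the lca_fit() model-fitting entry point with its
# S3 methods, evaluation, and the ablation driver.

#' Training hyperparameters
#'
#' Defaults follow the published recipe: class-imbalance ("lca") loss,
#' AdaBound optimizer at initial learning rate 1e-3 with cosine annealing
#' over the full schedule, batch size 16, augmentation applied with
#' probability 10/11 (rotation uniform in +/-10 degrees, horizontal flip
#' with probability 0.5). `epochs` defaults to 200; small desk runs use 30.
#'
#' @param loss `"lca"`, `"bce"` or `"dice"`.
#' @param optimizer `"adabound"`, `"adam"` or `"sgd"`.
#' @param lr initial learning rate.
#' @param batch_size gradient-accumulation batch size.
#' @param epochs training epochs (cosine period).
#' @param augment_prob probability the augmentation pipeline is applied.
#' @param rotation_range rotation half-range in degrees.
#' @param hflip_prob horizontal-flip probability inside the pipeline.
#' @param seed RNG seed for weights, shuffling and augmentation.
#' @param final_lr,bound_gamma AdaBound final learning rate and bound
#'   convergence speed.
#' @param momentum SGD momentum.
#' @param beta1,beta2,adam_eps Adam/AdaBound moment parameters.
#' @param lca_variant reading of the loss fine-tuning term (see
#'   [lca_loss()]).
#' @return An object of class `lca_train_control`.
#' @export
lca_train_control <- function(loss = "lca", optimizer = "adabound",
                              lr = 1e-3, batch_size = 16L, epochs = 200L,
                              augment_prob = 10 / 11, rotation_range = 10,
                              hflip_prob = 0.5, seed = 1L,
                              final_lr = 0.1, bound_gamma = 1e-3,
                              momentum = 0.9, beta1 = 0.9, beta2 = 0.999,
                              adam_eps = 1e-8, lca_variant = "standard") {
  if (augment_prob < 0 || augment_prob > 1 || hflip_prob < 0 || hflip_prob > 1)
    stop_config("probabilities must lie in [0, 1]")
  if (lr <= 0 || batch_size < 1 || epochs < 1)
    stop_config("lr, batch_size and epochs must be positive")
  loss_factory(loss)  # validates the name early
  structure(list(loss = loss, optimizer = optimizer, lr = lr,
                 batch_size = as.integer(batch_size), epochs = as.integer(epochs),
                 augment_prob = augment_prob, rotation_range = rotation_range,
                 hflip_prob = hflip_prob, seed = as.integer(seed),
                 final_lr = final_lr, bound_gamma = bound_gamma,
                 momentum = momentum, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, lca_variant = lca_variant),
            class = "lca_train_control")
}

# rotate about the image centre; bilinear or nearest, zero fill
rotate_map <- function(m, theta_deg, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(m); w <- ncol(m)
  th <- theta_deg * pi / 180
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  ii <- matrix(rep(seq_len(h), w), h, w) - cy
  jj <- matrix(rep(seq_len(w), each = h), h, w) - cx
  si <- cos(th) * ii - sin(th) * jj + cy
  sj <- sin(th) * ii + cos(th) * jj + cx
  out <- matrix(0, h, w)
  if (method == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= h & rj >= 1 & rj <= w
    out[ok] <- m[cbind(ri[ok], rj[ok])]
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    gather <- function(a, b) {
      ok <- a >= 1 & a <= h & b >= 1 & b <= w
      v <- numeric(length(a)); v[ok] <- m[cbind(a[ok], b[ok])]
      v
    }
    v00 <- gather(i0, j0); v10 <- gather(i0 + 1, j0)
    v01 <- gather(i0, j0 + 1); v11 <- gather(i0 + 1, j0 + 1)
    out[] <- (1 - fi) * (1 - fj) * v00 + fi * (1 - fj) * v10 +
      (1 - fi) * fj * v01 + fi * fj * v11
  }
  out
}

#' Augment an image/mask pair
#'
#' With probability `augment_prob` the pair is rotated by an angle drawn
#' uniformly from the configured range (bilinear for the image, nearest for
#' the mask, zero fill) and then horizontally flipped with the configured
#' probability; both receive identical geometric transforms and the mask
#' stays binary. Randomness uses the current R RNG state.
#'
#' @param sample list with `image` (matrix) and `mask` (binary matrix).
#' @param control an [lca_train_control()].
#' @return Augmented sample (same structure).
#' @export
augment <- function(sample, control) {
  if (runif(1) >= control$augment_prob) return(sample)
  theta <- runif(1, -control$rotation_range, control$rotation_range)
  img <- rotate_map(sample$image, theta, "bilinear")
  msk <- rotate_map(sample$mask, theta, "nearest")
  if (runif(1) < control$hflip_prob) {
    img <- img[, rev(seq_len(ncol(img)))]
    msk <- msk[, rev(seq_len(ncol(msk)))]
  }
  sample$image <- img
  sample$mask <- msk
  sample
}

one_hot_mask <- function(mask) {
  array(c(1 - mask, mask), c(dim(mask), 2L))
}

dice_of_masks <- function(pred, true) {
  num <- 2 * sum(pred * true)
  den <- 2 * sum(pred * true) + sum(pred * (1 - true)) + sum((1 - pred) * true)
  if (den == 0) return(100)
  100 * num / den
}

#' Fit an LCA-Net segmentation model
#'
#' Trains the network on image/mask pairs with the published recipe:
#' chosen loss, optimizer, cosine-annealed learning rate, gradient
#' accumulation over `batch_size` samples, stochastic augmentation. The
#' best checkpoint by validation Dice is kept (no early stopping). All
#' randomness is seeded from `control$seed`, so a fit is reproducible.
#'
#' @param train list of samples, each `list(image = matrix in [0, 1],
#'   mask = binary matrix)`; or the result of [generate_dataset()].
#' @param val optional validation list of the same structure; when absent,
#'   the final-epoch weights are kept.
#' @param net an [lca_net_config()].
#' @param control an [lca_train_control()].
#' @param verbose print one line per epoch.
#' @return An object of class `lca_fit`: the trained model plus a per-epoch
#'   `history` data frame (epoch, lr, train_loss, val_loss, val_dice) and
#'   `best_epoch`.
#' @export
lca_fit <- function(train, val = NULL, net = lca_net_config(),
                    control = lca_train_control(), verbose = FALSE) {
  if (length(train) == 0) stop_valid("empty training set")
  set.seed(control$seed)
  model <- build_lca_net(net)
  params <- collect_params(model)
  opt <- make_optimizer(control$optimizer, params, control)
  lf <- loss_factory(control$loss)
  n <- length(train)
  hist <- vector("list", control$epochs)
  best_dice <- -Inf; best_w <- NULL; best_epoch <- NA_integer_
  for (epoch in seq_len(control$epochs)) {
    lr <- cosine_lr(control$lr, epoch, control$epochs)
    ord <- sample.int(n)
    tot_loss <- 0
    for (b0 in seq(1, n, by = control$batch_size)) {
      batch <- ord[b0:min(b0 + control$batch_size - 1, n)]
      zero_grads(params)
      for (i in batch) {
        smp <- augment(train[[i]], control)
        p <- model$forward(smp$image, train = TRUE)
        r <- one_hot_mask(smp$mask)
        l <- lf$loss(p, r)
        if (!is.finite(l))
          stop(sprintf("non-finite loss at epoch %d (sample %d): diverged", epoch, i))
        tot_loss <- tot_loss + l
        model$backward(lf$grad(p, r))
      }
      for (pp in params) pp$grad <- pp$grad / length(batch)
      opt$step(lr)
    }
    train_loss <- tot_loss / n
    val_loss <- NA_real_; val_dice <- NA_real_
    if (!is.null(val) && length(val) > 0) {
      vl <- 0; vd <- 0
      for (smp in val) {
        p <- model$forward(smp$image, train = FALSE)
        vl <- vl + lf$loss(p, one_hot_mask(smp$mask))
        vd <- vd + dice_of_masks((p[, , 2] > p[, , 1]) * 1, smp$mask)
      }
      val_loss <- vl / length(val); val_dice <- vd / length(val)
      if (val_dice > best_dice) {
        best_dice <- val_dice; best_epoch <- epoch
        best_w <- lapply(params, function(p) p$value)
      }
    }
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr, train_loss = train_loss,
                                val_loss = val_loss, val_dice = val_dice)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  train %.4f  val %.4f  dice %.2f",
                      epoch, lr, train_loss, val_loss, val_dice))
  }
  if (!is.null(best_w)) {
    for (i in seq_along(params)) params[[i]]$value <- best_w[[i]]
  } else {
    best_epoch <- control$epochs
  }
  structure(list(model = model, net = net, control = control,
                 history = do.call(rbind, hist), best_epoch = best_epoch,
                 n_train = n, n_val = length(val)),
            class = "lca_fit")
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf("LCA-Net fit: depth %d, widths %s, %s parameters\n",
              x$net$depth, paste(x$net$widths, collapse = "/"),
              format(count_parameters(x$model), big.mark = ",")))
  cat(sprintf("  blocks: backbone=%s attention=%s nac=%s\n",
              x$net$use_backbone, x$net$use_attention, x$net$use_nac))
  cat(sprintf("  trained %d epochs on %d samples (loss %s, optimizer %s)\n",
              x$control$epochs, x$n_train, x$control$loss, x$control$optimizer))
  h <- x$history
  if (!all(is.na(h$val_dice)))
    cat(sprintf("  best validation Dice %.2f%% at epoch %d\n",
                max(h$val_dice, na.rm = TRUE), x$best_epoch))
  invisible(x)
}

#' @export
summary.lca_fit <- function(object, ...) {
  h <- object$history
  out <- list(parameters = count_parameters(object$model),
              epochs = nrow(h),
              final_train_loss = h$train_loss[nrow(h)],
              best_epoch = object$best_epoch,
              best_val_dice = if (all(is.na(h$val_dice))) NA
                              else max(h$val_dice, na.rm = TRUE))
  class(out) <- "summary.lca_fit"
  out
}

#' @export
print.summary.lca_fit <- function(x, ...) {
  cat(sprintf("parameters: %d\nepochs: %d\nfinal train loss: %.4f\n",
              x$parameters, x$epochs, x$final_train_loss))
  if (!is.na(x$best_val_dice))
    cat(sprintf("best val dice: %.2f%% (epoch %d)\n", x$best_val_dice, x$best_epoch))
  invisible(x)
}

#' Predict masks or probability maps from a fit
#'
#' @param object an [lca_fit()].
#' @param newdata a single image matrix, or a list of samples/images.
#' @param type `"mask"` for binary masks, `"prob"` for (H, W, 2)
#'   probability arrays.
#' @param ... unused.
#' @return A mask/probability array, or a list of them.
#' @export
predict.lca_fit <- function(object, newdata, type = c("mask", "prob"), ...) {
  type <- match.arg(type)
  one <- function(img) {
    if (is.list(img)) img <- img$image
    if (type == "mask") predict_mask(object$model, img)
    else object$model$forward(img, train = FALSE)
  }
  if (is.matrix(newdata)) one(newdata) else lapply(newdata, one)
}

#' Plot training curves
#'
#' Loss (train and validation) and validation Dice against epoch.
#'
#' @param x an [lca_fit()].
#' @param ... passed to [graphics::matplot()].
#' @export
plot.lca_fit <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"), xlab = "epoch",
                    ylab = "loss", main = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  if (!all(is.na(h$val_dice))) {
    graphics::plot(h$epoch, h$val_dice, type = "l", xlab = "epoch",
                   ylab = "validation Dice (%)", main = "validation Dice")
  }
  invisible(x)
}

#' Evaluate a model on a dataset
#'
#' Predicts a mask for every image and scores it against the reference with
#' the seven confusion-matrix metrics; the summary row aggregates per-image
#' means by default.
#'
#' @param fit an [lca_fit()] or `lca_net` model.
#' @param dataset non-empty list of samples (`image`, `mask`).
#' @param mode aggregation mode, see [aggregate_metrics()].
#' @param csv_path,json_path optional output files (per-image CSV, summary
#'   JSON).
#' @return List with `per_image` (data frame) and `summary`
#'   (`metrics_report`).
#' @export
evaluate <- function(fit, dataset, mode = "per-image-mean",
                     csv_path = NULL, json_path = NULL) {
  if (length(dataset) == 0) stop_valid("empty dataset")
  model <- if (inherits(fit, "lca_fit")) fit$model else fit
  preds <- lapply(dataset, function(s) predict_mask(model, s$image))
  trues <- lapply(dataset, `[[`, "mask")
  tab <- metrics_table(preds, trues)
  pairs <- Map(function(p, t) list(pred = p, true = t), preds, trues)
  summ <- aggregate_metrics(pairs, mode = mode)
  write_metrics_report(tab, csv_path, json_path, summary = unclass(summ))
  list(per_image = tab, summary = summ)
}

#' Train and evaluate a grid of configurations
#'
#' Runs each named configuration on identical data and seed and tabulates
#' the test metrics — the harness behind module-selection, loss and
#' optimizer comparisons. Each grid entry may override fields of the
#' network config (e.g. `use_attention`) and/or the training control (e.g.
#' `loss`, `optimizer`).
#'
#' @param grid named list (length >= 2) of override lists.
#' @param train,val,test datasets as for [lca_fit()].
#' @param net base [lca_net_config()].
#' @param control base [lca_train_control()].
#' @param verbose print progress.
#' @return Data frame: one row per configuration with the flags used, the
#'   seven test metrics, and a `failed` flag (a failing member run leaves a
#'   flagged row rather than aborting the grid).
#' @export
run_ablation <- function(grid, train, val, test, net = lca_net_config(),
                         control = lca_train_control(), verbose = FALSE) {
  if (length(grid) < 2) stop_valid("an ablation grid needs at least 2 configurations")
  if (is.null(names(grid)) || any(names(grid) == ""))
    stop_valid("grid entries must be named")
  rows <- lapply(names(grid), function(nm) {
    ov <- grid[[nm]]
    ncfg <- net; ctl <- control
    for (f in names(ov)) {
      if (f %in% names(ncfg)) ncfg[[f]] <- ov[[f]]
      else if (f %in% names(ctl)) ctl[[f]] <- ov[[f]]
      else stop_config(sprintf("unknown override '%s' in grid entry '%s'", f, nm))
    }
    base <- data.frame(config = nm,
                       backbone = ncfg$use_backbone,
                       attention = ncfg$use_attention,
                       nac = ncfg$use_nac,
                       loss = ctl$loss, optimizer = ctl$optimizer)
    res <- tryCatch({
      fit <- lca_fit(train, val, net = ncfg, control = ctl, verbose = verbose)
      ev <- evaluate(fit, test)
      s <- ev$summary
      cbind(base, data.frame(dice = s$dice, pa = s$pa, jaccard = s$jaccard,
                             precision = s$precision, recall = s$recall,
                             fpr = s$fpr, fnr = s$fnr, failed = FALSE))
    }, error = function(e) {
      cbind(base, data.frame(dice = NA, pa = NA, jaccard = NA, precision = NA,
                             recall = NA, fpr = NA, fnr = NA, failed = TRUE))
    })
    res
  })
  do.call(rbind, rows)
}
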