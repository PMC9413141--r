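# Optimizers over the flat parameter list. All keep per-parameter state in
# parallel lists and read accumulated gradients from p$grad.

make_optimizer <- function(name, params, control) {
  n <- length(params)
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  opt$name <- name
  b1 <- control$beta1; b2 <- control$beta2; eps <- control$adam_eps
  if (name == "sgd") {
    opt$v <- lapply(params, function(p) p$value * 0)
    opt$step <- function(lr) {
      for (i in seq_len(n)) {
        opt$v[[i]] <- control$momentum * opt$v[[i]] + params[[i]]$grad
        params[[i]]$value <- params[[i]]$value - lr * opt$v[[i]]
      }
    }
  } else if (name == "adam") {
    opt$m <- lapply(params, function(p) p$value * 0)
    opt$v <- lapply(params, function(p) p$value * 0)
    opt$step <- function(lr) {
      opt$t <- opt$t + 1L
      bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
      for (i in seq_len(n)) {
        g <- params[[i]]$grad
        opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
        opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
        params[[i]]$value <- params[[i]]$value -
          lr * (opt$m[[i]] / bc1) / (sqrt(opt$v[[i]] / bc2) + eps)
      }
    }
  } else if (name == "adabound") {
    # Adam with step sizes clipped into a band that shrinks onto final_lr,
    # so training starts Adam-like and ends SGD-like
    opt$m <- lapply(params, function(p) p$value * 0)
    opt$v <- lapply(params, function(p) p$value * 0)
    base_lr <- control$lr
    opt$step <- function(lr) {
      opt$t <- opt$t + 1L
      bc1 <- 1 - b1^opt$t; bc2 <- 1 - b2^opt$t
      flr <- control$final_lr * lr / base_lr
      lb <- flr * (1 - 1 / (control$bound_gamma * opt$t + 1))
      ub <- flr * (1 + 1 / (control$bound_gamma * opt$t))
      for (i in seq_len(n)) {
        g <- params[[i]]$grad
        opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
        opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
        step <- lr / bc1 / (sqrt(opt$v[[i]] / bc2) + eps)
        step <- pmin(pmax(step, lb), ub)
        params[[i]]$value <- params[[i]]$value - step * opt$m[[i]]
      }
    }
  } else {
    stop_config(sprintf("unknown optimizer '%s' (use adabound, adam or sgd)", name))
  }
  opt
}

# cosine annealing from lr0 to ~0 over n_epochs, no restarts
cosine_lr <- function(lr0, epoch, n_epochs) {
  0.5 * lr0 * (1 + cos(pi * (epoch - 1) / n_epochs))
}
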