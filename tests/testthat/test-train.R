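micro_data <- function(n, seed = 1) {
  generate_dataset(n, phantom_spec(image_size = 32, size_class = "large",
                                   contrast_drop = c(0.25, 0.3),
                                   edge_blur_sigma = 0.5), seed = seed)
}

micro_cfg <- function(...) lca_net_config(depth = 3, widths = c(4L, 8L, 16L),
                                          input_size = 32L, attn_max_hw = 16L, ...)

test_that("augmentation honors its probabilities and transform contracts", {
  s <- list(image = matrix(runif(64 * 64), 64, 64), mask = random_mask(64, 64))
  ctl <- lca_train_control(augment_prob = 0, epochs = 1)
  expect_identical(augment(s, ctl), s)   # probability 0 -> identity

  ctl <- lca_train_control(augment_prob = 1, hflip_prob = 1,
                           rotation_range = 0, epochs = 1)
  set.seed(71)
  a <- augment(s, ctl)     # pure flip (rotation angle forced to 0)
  expect_identical(a$image, s$image[, 64:1])
  b <- a; b$image <- a$image[, 64:1]; b$mask <- a$mask[, 64:1]
  expect_identical(b$image, s$image)  # flip is an involution

  ctl <- lca_train_control(augment_prob = 1, hflip_prob = 0, epochs = 1)
  set.seed(72)
  a <- augment(s, ctl)
  expect_true(all(a$mask %in% c(0, 1)))      # nearest keeps the mask binary
  expect_identical(dim(a$image), dim(s$image))
})

test_that("control and optimizer validation reject bad settings", {
  expect_error(lca_train_control(augment_prob = 1.5), class = "lcanet_config_error")
  expect_error(lca_train_control(lr = -1), class = "lcanet_config_error")
  expect_error(lca_train_control(loss = "nonsense"), class = "lcanet_config_error")
  expect_error(lca_fit(micro_data(2), net = micro_cfg(),
                       control = lca_train_control(optimizer = "nonsense",
                                                   epochs = 1)),
               class = "lcanet_config_error")
})

test_that("a short fit is reproducible and its loss decreases", {
  d <- micro_data(8)
  ctl <- lca_train_control(epochs = 3, batch_size = 4, seed = 9)
  f1 <- lca_fit(d, net = micro_cfg(), control = ctl)
  f2 <- lca_fit(d, net = micro_cfg(), control = ctl)
  expect_equal(f1$history$train_loss, f2$history$train_loss, tolerance = 1e-12)
  expect_lt(f1$history$train_loss[3], f1$history$train_loss[1])
  expect_s3_class(f1, "lca_fit")
  expect_output(print(f1), "LCA-Net fit")
  s <- summary(f1)
  expect_equal(s$parameters, count_parameters(f1$model))
})

test_that("optimizers all take steps that reduce the loss on a fixed batch", {
  d <- micro_data(6)
  for (optn in c("adabound", "adam", "sgd")) {
    ctl <- lca_train_control(epochs = 2, batch_size = 6, seed = 4,
                             optimizer = optn, augment_prob = 0)
    f <- lca_fit(d, net = micro_cfg(use_attention = FALSE, use_nac = FALSE),
                 control = ctl)
    expect_lt(f$history$train_loss[2], f$history$train_loss[1])
  }
})

test_that("evaluation scores an oracle that predicts the truth at Dice 100", {
  d <- micro_data(4)
  oracle <- structure(list(cfg = list(depth = 1)), class = "oracle_model")
  # bypass the network: feed the reference masks straight into the metric path
  preds <- lapply(d, `[[`, "mask")
  tab <- lcanet:::metrics_table(preds, lapply(d, `[[`, "mask"))
  expect_true(all(tab$dice == 100))
  expect_error(evaluate(list(), list()), class = "lcanet_validation_error")
})

test_that("evaluate's summary equals the aggregate of its per-image rows", {
  set.seed(73)
  d <- micro_data(5)
  ctl <- lca_train_control(epochs = 1, batch_size = 5, seed = 2)
  f <- lca_fit(d, net = micro_cfg(use_attention = FALSE), control = ctl)
  ev <- evaluate(f, d)
  expect_equal(nrow(ev$per_image), 5)
  for (col in c("dice", "pa", "jaccard")) {
    v <- ev$per_image[[col]]
    expect_equal(ev$summary[[col]], mean(v[!is.nan(v)]), tolerance = 1e-12)
  }
  # file outputs
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  evaluate(f, d, csv_path = csv, json_path = js)
  expect_true(file.exists(csv) && file.exists(js))
})

test_that("the ablation driver enforces the grid contract and is deterministic", {
  d <- micro_data(6)
  expect_error(run_ablation(list(a = list()), d, d, d),
               class = "lcanet_validation_error")
  grid <- list(baseline = list(use_attention = FALSE, use_nac = FALSE),
               same = list(use_attention = FALSE, use_nac = FALSE))
  ctl <- lca_train_control(epochs = 1, batch_size = 6, seed = 11)
  tab <- run_ablation(grid, d, d, d, net = micro_cfg(), control = ctl)
  expect_equal(nrow(tab), 2)
  expect_false(any(tab$failed))
  # identical configs under the same seed give identical rows
  expect_equal(tab$dice[1], tab$dice[2], tolerance = 1e-12)
  # unknown override is a configuration error
  expect_error(run_ablation(list(a = list(bogus = 1), b = list()), d, d, d,
                            net = micro_cfg(), control = ctl),
               class = "lcanet_config_error")
})
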