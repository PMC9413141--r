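test_that("confusion counts match hand-enumerated grids and reject bad input", {
  # identical masks: no errors of either kind
  m <- random_mask(6, 6)
  cc <- confusion_counts(m, m)
  expect_equal(cc$fp, 0)
  expect_equal(cc$fn, 0)
  expect_equal(cc$tp + cc$fp + cc$fn + cc$tn, 36)

  # all-positive prediction against empty truth
  cc <- confusion_counts(matrix(1, 10, 10), matrix(0, 10, 10))
  expect_equal(unclass(cc), list(tp = 0, fp = 100, fn = 0, tn = 0))

  # hand-built 10x10 grid: 6 overlapping, 2 spurious, 2 missed positives
  true <- matrix(0, 10, 10); true[3:4, 3:6] <- 1          # 8 positives
  pred <- matrix(0, 10, 10); pred[3:4, 4:6] <- 1; pred[8, 8:9] <- 1
  cc <- confusion_counts(pred, true)
  expect_equal(unclass(cc), list(tp = 6, fp = 2, fn = 2, tn = 90))

  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)),
               class = "lcanet_dim_error")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               class = "lcanet_validation_error")
})

test_that("metric formulas reproduce hand-derived values and conventions", {
  m <- compute_metrics(list(tp = 6, fp = 2, fn = 2, tn = 90))
  expect_equal(m$dice, 75)
  expect_equal(m$pa, 96)
  expect_equal(m$jaccard, 60)
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.75)
  expect_equal(m$fpr, 2 / 92)
  expect_equal(m$fnr, 0.25)

  perfect <- compute_metrics(list(tp = 5, fp = 0, fn = 0, tn = 7))
  expect_equal(perfect$dice, 100)
  expect_equal(perfect$pa, 100)
  expect_equal(perfect$jaccard, 100)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$fnr, 0)

  # Dice-Jaccard identity at tp=fp=fn=1
  m <- compute_metrics(list(tp = 1, fp = 1, fn = 1, tn = 0))
  expect_equal(m$dice, 50)
  expect_equal(m$jaccard, 100 / 3, tolerance = 1e-12)
  expect_equal(m$dice / 100, 2 * (1 / 3) / (1 + 1 / 3), tolerance = 1e-12)

  # zero denominators yield NaN sentinels, never errors
  m <- compute_metrics(list(tp = 0, fp = 0, fn = 3, tn = 5))
  expect_true(is.nan(m$precision))
  expect_false(is.nan(m$recall))
  m <- compute_metrics(list(tp = 0, fp = 4, fn = 0, tn = 0))
  expect_true(is.nan(m$recall))
  expect_true(is.nan(m$fnr))
})

test_that("metric identities hold on random masks and match brute force", {
  set.seed(7)
  for (i in 1:100) {
    pred <- random_mask(16, 16, runif(1, 0.1, 0.9))
    true <- random_mask(16, 16, runif(1, 0.1, 0.9))
    m <- compute_metrics(confusion_counts(pred, true))
    J <- m$jaccard / 100
    expect_equal(m$dice / 100, 2 * J / (1 + J), tolerance = 1e-12)
    expect_equal(m$recall, 1 - m$fnr, tolerance = 1e-12)
    # symmetric metrics are invariant to swapping pred and true
    ms <- compute_metrics(confusion_counts(true, pred))
    expect_equal(ms$dice, m$dice)
    expect_equal(ms$pa, m$pa)
    expect_equal(ms$jaccard, m$jaccard)
    # brute-force per-pixel recount
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (px in seq_along(pred)) {
      if (pred[px] == 1 && true[px] == 1) tp <- tp + 1
      if (pred[px] == 1 && true[px] == 0) fp <- fp + 1
      if (pred[px] == 0 && true[px] == 1) fn <- fn + 1
      if (pred[px] == 0 && true[px] == 0) tn <- tn + 1
    }
    mb <- compute_metrics(list(tp = tp, fp = fp, fn = fn, tn = tn))
    expect_equal(unclass(m), unclass(mb))
  }
})

test_that("aggregation modes agree on symmetric input and differ when sizes differ", {
  set.seed(11)
  a <- list(pred = random_mask(8, 8), true = random_mask(8, 8))
  one <- compute_metrics(confusion_counts(a$pred, a$true))
  expect_equal(unclass(aggregate_metrics(list(a), "per-image-mean")), unclass(one))
  expect_equal(unclass(aggregate_metrics(list(a), "pooled")), unclass(one))
  expect_equal(unclass(aggregate_metrics(list(a, a), "per-image-mean")), unclass(one))
  expect_equal(unclass(aggregate_metrics(list(a, a), "pooled")), unclass(one))

  # two 4x4 pairs with very different positive counts: hand arithmetic
  t1 <- matrix(0, 4, 4); t1[1:2, 1:2] <- 1         # 4 positives
  p1 <- matrix(0, 4, 4); p1[1:2, 1] <- 1           # tp=2 fn=2 -> dice 2*2/(4+2)
  t2 <- matrix(0, 4, 4); t2[1, 1] <- 1
  p2 <- t2                                         # dice 100
  pairs <- list(list(pred = p1, true = t1), list(pred = p2, true = t2))
  per <- aggregate_metrics(pairs, "per-image-mean")
  pool <- aggregate_metrics(pairs, "pooled")
  expect_equal(per$dice, (100 * 4 / 6 + 100) / 2)
  expect_equal(pool$dice, 100 * 2 * 3 / (2 * 3 + 0 + 2))
  expect_false(isTRUE(all.equal(per$dice, pool$dice)))

  expect_error(aggregate_metrics(list()), class = "lcanet_validation_error")
})

test_that("report writer emits readable CSV and JSON", {
  set.seed(3)
  preds <- list(random_mask(8, 8), random_mask(8, 8))
  trues <- list(random_mask(8, 8), random_mask(8, 8))
  tab <- lcanet:::metrics_table(preds, trues)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_metrics_report(tab, csv, js)
  back <- read.csv(csv)
  expect_equal(back$dice, tab$dice)
  expect_named(back, c("image_id", "dice", "pa", "jaccard", "precision",
                       "recall", "fpr", "fnr"))
  summ <- jsonlite::read_json(js)
  expect_equal(summ$dice, mean(tab$dice), tolerance = 1e-8)
})
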