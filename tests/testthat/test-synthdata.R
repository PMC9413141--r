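test_that("phantom generation is deterministic given a seed", {
  sp <- phantom_spec(image_size = 64)
  a <- generate_phantom(sp, seed = 7)
  b <- generate_phantom(sp, seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  d1 <- generate_dataset(6, sp, seed = 3)
  d2 <- generate_dataset(6, sp, seed = 3)
  expect_identical(lapply(d1, `[[`, "image"), lapply(d2, `[[`, "image"))
})

test_that("phantoms respect size classes, placement and contrast", {
  sp <- phantom_spec(image_size = 64, size_class = "medium", placement = "center")
  fr <- vapply(1:100, function(i) mean(generate_phantom(sp, seed = i)$mask), 0)
  expect_true(all(fr >= 0.02 & fr <= 0.08))

  spe <- phantom_spec(image_size = 64, placement = "edge")
  for (i in 1:20) {
    m <- generate_phantom(spe, seed = i)$mask
    border <- c(m[1, ], m[64, ], m[, 1], m[, 64])
    expect_gt(sum(border), 0)
  }

  # nodule interior darker than background by at least half the drawn drop
  sp <- phantom_spec(image_size = 64, size_class = "large",
                     contrast_drop = c(0.2, 0.3))
  for (i in 1:10) {
    s <- generate_phantom(sp, seed = i)
    inside <- mean(s$image[s$mask == 1])
    outside <- mean(s$image[s$mask == 0])
    rel_gap <- (outside - inside) / outside
    expect_gt(rel_gap, s$params$contrast_drop / 2)
  }
})

test_that("the mask is one connected component", {
  flood_size <- function(m) {
    seed <- which(m == 1, arr.ind = TRUE)[1, ]
    seen <- matrix(FALSE, nrow(m), ncol(m))
    stack <- list(seed); seen[seed[1], seed[2]] <- TRUE; n <- 0
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL; n <- n + 1
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        q <- p + d
        if (q[1] >= 1 && q[1] <= nrow(m) && q[2] >= 1 && q[2] <= ncol(m) &&
            m[q[1], q[2]] == 1 && !seen[q[1], q[2]]) {
          seen[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    n
  }
  sp <- phantom_spec(image_size = 64)
  for (i in 1:10) {
    m <- generate_phantom(sp, seed = 100 + i)$mask
    expect_equal(flood_size(m), sum(m))
  }
})

test_that("round-robin balancing covers the size classes", {
  d <- generate_dataset(12, phantom_spec(image_size = 64), seed = 2)
  cls <- vapply(d, function(s) s$params$size_class, "")
  expect_equal(unname(table(cls)[c("small", "medium", "large")]),
               rep(4L, 3), ignore_attr = TRUE)
})

test_that("speckle variance scales with the squared mean on flat fields", {
  # pure multiplicative gamma speckle on constant levels mu: var ~ mu^2/shape
  set.seed(61)
  shape <- 6
  mus <- c(0.2, 0.4, 0.6)
  vars <- vapply(mus, function(mu) {
    var(mu * rgamma(20000, shape, rate = shape))
  }, 0)
  expect_equal(vars / mus^2, rep(1 / shape, 3), tolerance = 0.05)
  # and the generator's background regions show higher variance than the
  # (darker) nodule interior on average, consistent with multiplicativity
  sp <- phantom_spec(image_size = 64, size_class = "large",
                     contrast_drop = c(0.3, 0.3), edge_blur_sigma = 0.5)
  vb <- vn <- numeric(10)
  for (i in 1:10) {
    s <- generate_phantom(sp, seed = 200 + i)
    vb[i] <- var(s$image[s$mask == 0]); vn[i] <- var(s$image[s$mask == 1])
  }
  expect_gt(mean(vb), mean(vn))
})

test_that("8:1:1 split is exact, disjoint and exhaustive across sizes", {
  s <- split_811(7288, seed = 1)
  expect_equal(lengths(s), c(train = 5830L, val = 729L, test = 729L))
  expect_equal(lengths(split_811(10)), c(train = 8L, val = 1L, test = 1L))
  expect_equal(lengths(split_811(100)), c(train = 80L, val = 10L, test = 10L))
  for (n in c(10, 11, 13, 57, 100, 1234, 9999)) {
    s <- split_811(n, seed = n)
    all_idx <- sort(c(s$train, s$val, s$test))
    expect_equal(all_idx, seq_len(n))
    expect_equal(length(s$train), floor(0.8 * n))
    rem <- n - length(s$train)
    expect_equal(length(s$val), ceiling(rem / 2))   # odd remainder -> validation
    expect_equal(length(s$test), floor(rem / 2))
  }
  expect_error(split_811(9), class = "lcanet_validation_error")
})

test_that("PNG round-trip preserves masks exactly and images to 8-bit", {
  d <- generate_dataset(3, phantom_spec(image_size = 32), seed = 5)
  dir <- tempfile()
  manifest <- write_phantom_dataset(d, dir)
  expect_equal(nrow(read.csv(file.path(dir, "manifest.csv"))), 3)
  back <- read_phantom_dataset(dir)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, d[[i]]$mask)
    expect_lt(max(abs(back[[i]]$image - d[[i]]$image)), 1 / 255)
  }
})
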