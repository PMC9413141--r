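test_that("patch counts follow the closed-form window formulas", {
  # query tiling: N1 = (H/8)(W/8), M1 = 64 N1
  ps <- split_query(array(0, c(256, 256, 1)))
  expect_equal(ps$n_patches, 1024)
  expect_equal(ps$flat_len, 65536)
  ps <- split_query(array(0, c(16, 16, 1)))
  expect_equal(ps$n_patches, 4)
  # an 8x8 map must first be padded to 16 to admit a 10x10 key-value window
  ps <- split_query(array(0, c(8, 8, 1)))
  expect_equal(ps$padded, c(16, 16))
  # remainders are ceiling-padded: 20 -> 24 -> 9 tiles
  ps <- split_query(array(0, c(20, 20, 1)))
  expect_equal(ps$padded, c(24, 24))
  expect_equal(ps$n_patches, 9)

  # key-value windows: N2 = ((H-10)/s + 1)^2 on the padded map
  ks <- split_kv(array(0, c(16, 16, 1)), s = 1)
  expect_equal(ks$n_patches, 49)
  expect_equal(ks$flat_len, 4900)
  ks <- split_kv(array(0, c(10, 10, 1)), s = 1)
  expect_equal(ks$padded, c(16, 16))  # 10 is not a multiple of 8
  ks <- split_kv(array(0, c(32, 32, 1)), s = 2)
  expect_equal(ks$n_patches, 144)
  expect_error(split_kv(array(0, c(16, 16, 1)), s = 0),
               class = "lcanet_validation_error")
})

test_that("attention output matches a dense brute-force oracle", {
  set.seed(21)
  for (hw in list(c(16, 16), c(12, 16), c(8, 8))) {
    x <- array(rnorm(hw[1] * hw[2] * 4), c(hw[1], hw[2], 4))
    qp <- split_query(x); kp <- split_kv(x, s = 1)
    tab <- rel_pos_table(15)
    tab[] <- rnorm(length(tab), sd = 0.2)
    out <- scaled_attention(qp, kp, kp, bias = tab)
    ref <- dense_attention(qp$mat, kp$mat, kp$mat, qp$pos, kp$pos, tab, 15)
    expect_lt(max(abs(out - ref)) / max(abs(ref)), 1e-5)
  }
})

test_that("softmax rows are a convex combination: rows sum to 1, constant values pass through", {
  set.seed(22)
  x <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  qp <- split_query(x); kp <- split_kv(x, s = 1)
  P <- lcanet:::attention_probs(qp, kp)
  expect_equal(rowSums(P), rep(1, nrow(P)), tolerance = 1e-6)
  expect_true(all(P >= 0))

  # all value rows identical -> every output row equals that vector
  vconst <- kp
  vconst$mat <- matrix(rep(c(2, -1, 0.5), each = nrow(kp$mat)), nrow(kp$mat), 3)
  out <- scaled_attention(qp, kp, vconst)
  expect_equal(out, matrix(rep(c(2, -1, 0.5), each = nrow(qp$mat)), nrow(qp$mat), 3),
               tolerance = 1e-9)
})

test_that("a dominating logit saturates the softmax onto its value row", {
  # one query pixel, keys engineered so key 1 wins by a +30 margin
  qp <- structure(list(mat = matrix(c(30, 0), 1, 2), pos = cbind(0L, 0L),
                       window = 8L, stride = 8L, n_patches = 1, flat_len = 1,
                       padded = c(8L, 8L), dims = c(1L, 1L, 2L)),
                  class = "patch_set")
  K <- matrix(c(sqrt(2), 0, 0, 0, 0, 0), 3, 2)  # logits ~ (30, 0, 0) after scaling
  kp <- structure(list(mat = K, pos = cbind(0:2, 0L), window = 10L, stride = 1L,
                       n_patches = 1, flat_len = 3, padded = c(16L, 16L),
                       dims = c(16L, 16L, 2L)),
                  class = "patch_set")
  vp <- kp; vp$mat <- matrix(c(5, -3, 1, 7, 2, 0), 3, 2)
  out <- scaled_attention(qp, kp, vp)
  expect_equal(drop(out), c(5, 7), tolerance = 1e-9)
})

test_that("relative position bias depends only on the offset between pixels", {
  # two key pixels at identical content and identical offset from the query
  # must receive identical attention; different offsets with non-zero table
  # must not
  tab <- rel_pos_table(15)
  tab[16 + 1, 16 + 0] <- 3   # offset (dr=1, dc=0) favored
  qp <- structure(list(mat = matrix(0, 1, 2), pos = cbind(5L, 5L)),
                  class = "patch_set")
  kp <- structure(list(mat = matrix(0, 3, 2),
                       pos = cbind(c(4L, 4L, 6L), c(5L, 5L, 5L))),
                  class = "patch_set")
  P <- lcanet:::attention_probs(qp, kp, bias = tab)
  expect_equal(P[1, 1], P[1, 2], tolerance = 1e-12)  # same offset, same weight
  expect_gt(P[1, 1], P[1, 3])                        # biased offset wins
})

test_that("a freshly built attention block is the identity and preserves shape", {
  set.seed(23)
  x <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  blk <- attention_block(6)
  y <- context_attention_forward(blk, x)
  expect_identical(dim(y), dim(x))
  # zero-initialized output projections -> pure residual
  expect_equal(y, x, tolerance = 1e-12)

  x2 <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  blk2 <- attention_block(8, mode = "paired")
  expect_identical(dim(context_attention_forward(blk2, x2)), dim(x2))
})

test_that("encoder self-attention equals the decoder variant fed its own input", {
  set.seed(24)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4))
  blk <- attention_block(4)
  # make the block non-trivial
  blk$convo$w$value[] <- rnorm(length(blk$convo$w$value), sd = 0.3)
  blk$convo2$w$value[] <- rnorm(length(blk$convo2$w$value), sd = 0.3)
  blk$table$value[] <- rnorm(length(blk$table$value), sd = 0.1)
  enc <- context_attention_forward(blk, x)
  dec <- context_attention_forward(blk, x, skip = x)
  expect_equal(enc, dec, tolerance = 1e-10)
})

test_that("block gradients agree with finite differences on a small map", {
  set.seed(25)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  for (mode in c("global", "paired")) {
    blk <- attention_block(2, mode = mode, radius = 15)
    blk$convo$w$value[] <- rnorm(length(blk$convo$w$value), sd = 0.3)
    blk$convo2$w$value[] <- rnorm(length(blk$convo2$w$value), sd = 0.3)
    blk$table$value[] <- rnorm(length(blk$table$value), sd = 0.1)
    y <- blk$forward(x, NULL, TRUE)
    gy <- array(rnorm(length(y)), dim(y))
    gx <- blk$backward(gy)$gx
    gn <- num_grad(function(z) blk$forward(z, NULL, TRUE), x, gy, h = 1e-5)
    expect_lt(max(abs(gx - gn)), 1e-4)
  }
})
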