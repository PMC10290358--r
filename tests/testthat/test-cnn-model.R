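test_that("spec traces spatial dimensions through the two pooling stages", {
  m <- build_model(model_spec(tile_size = 32, in_channels = 3,
                              conv_channels = c(8, 16), kernel_size = 3,
                              pooling = "max", pool_size = 2))
  expect_equal(m$dims$flatten, 16 * 8 * 8) # 32 -> 16 -> 8 with same padding
  # parameter count: conv1 + conv2 + fc, plus biases
  expect_equal(n_parameters(m),
               (3 * 3 * 3 * 8 + 8) + (3 * 3 * 8 * 16 + 16) +
                 (1024 * 2 + 2))

  # boundary case: tile 4 pooled twice to spatial size 1
  m4 <- build_model(model_spec(tile_size = 4))
  expect_equal(m4$dims$after_pool2, 1)

  expect_error(model_spec(tile_size = 30), "divisible")
  expect_error(model_spec(kernel_size = 4), "odd")
})

test_that("initialisation is deterministic given the spec seed", {
  a <- build_model(model_spec(seed = 5))
  b <- build_model(model_spec(seed = 5))
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$w1, build_model(model_spec(seed = 6))$params$w1))
})

test_that("softmax head yields normalized, shift-invariant probabilities", {
  m <- build_model(model_spec(seed = 2))
  set.seed(3)
  tiles <- lapply(1:4, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  p <- predict_proba(m, tiles)
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))

  # zero final layer -> equal logits -> (0.5, 0.5) for every input
  m0 <- m
  m0$params$wfc[] <- 0
  m0$params$bfc[] <- 0
  expect_equal(unname(predict_proba(m0, tiles)),
               matrix(0.5, 4, 2), tolerance = 1e-12)

  # adding a constant to both logits leaves the probabilities unchanged
  mshift <- m
  mshift$params$bfc <- m$params$bfc + 7.3
  expect_equal(predict_proba(mshift, tiles), p, tolerance = 1e-9)
})

test_that("forward pass matches an independent scalar chain on a 1x1 kernel net", {
  spec <- model_spec(tile_size = 4, in_channels = 1, conv_channels = c(1, 1),
                     kernel_size = 1, pooling = "average", pool_size = 2,
                     seed = 0)
  m <- build_model(spec)
  m$params$w1 <- matrix(2, 1, 1);   m$params$b1 <- 0.1
  m$params$w2 <- matrix(0.5, 1, 1); m$params$b2 <- 0
  m$params$wfc <- matrix(c(1, -1), 1, 2)
  m$params$bfc <- c(0, 0)
  v <- 0.3
  # independent scalar oracle of the chain conv-relu-pool-conv-relu-pool-fc
  h1 <- max(v * 2 + 0.1, 0)       # conv1 + relu (constant field)
  h2 <- h1                        # average pool of a constant
  h3 <- max(h1 * 0.5, 0)          # conv2 + relu
  h4 <- h3                        # second pool
  logits <- c(h4 * 1, h4 * -1)
  expect_p <- exp(logits[1]) / sum(exp(logits))
  got <- predict_proba(m, array(v, c(4, 4, 1)))
  expect_equal(unname(got[1, "reed"]), expect_p, tolerance = 1e-12)
})

test_that("average and max pooling agree on constant fields, max dominates on varying ones", {
  # single nonnegative-weight conv path on a nonnegative input:
  # max pooling response >= average pooling response; with a 1x1 kernel no
  # padding is involved, so a constant tile gives a constant feature field
  # on which the two poolings agree exactly
  mk <- function(pooling) {
    s <- model_spec(tile_size = 4, in_channels = 1, conv_channels = c(1, 1),
                    kernel_size = 1, pooling = pooling, seed = 0)
    mm <- build_model(s)
    mm$params$w1 <- matrix(1, 1, 1); mm$params$b1 <- 0
    mm$params$w2 <- matrix(1, 1, 1); mm$params$b2 <- 0
    mm$params$wfc <- matrix(c(1, 0), 1, 2); mm$params$bfc <- c(0, 0)
    mm
  }
  set.seed(9)
  tile <- array(runif(16), c(4, 4, 1))
  p_max <- predict_proba(mk("max"), tile)[1, "reed"]
  p_avg <- predict_proba(mk("average"), tile)[1, "reed"]
  expect_gte(p_max, p_avg)

  const_tile <- array(0.6, c(4, 4, 1))
  expect_equal(predict_proba(mk("max"), const_tile),
               predict_proba(mk("average"), const_tile), tolerance = 1e-12)
})

test_that("batched prediction equals concatenated single-tile predictions", {
  m <- build_model(model_spec(seed = 8))
  set.seed(10)
  tiles <- lapply(1:5, function(i) array(runif(32 * 32 * 3), c(32, 32, 3)))
  batched <- predict_proba(m, tiles)
  singles <- do.call(rbind, lapply(tiles, function(t) predict_proba(m, t)))
  expect_equal(batched, singles, tolerance = 1e-6)
})

test_that("shape mismatches are reported with expected vs received", {
  m <- build_model(model_spec(seed = 1))
  expect_error(predict_proba(m, array(0, c(16, 16, 3))),
               "expected 32x32x3.*received 16x16x3")
})

test_that("checkpoints round-trip spec, parameters and predictions", {
  m <- build_model(model_spec(conv_channels = c(4, 6), seed = 3))
  m$params$w1[1, 1] <- pi # perturb away from init
  path <- withr::local_tempfile(fileext = ".json")
  write_checkpoint(m, path)
  back <- read_checkpoint(path)
  expect_equal(unclass(back$spec), unclass(m$spec))
  expect_equal(back$params, m$params, tolerance = 1e-12)
  tile <- array(0.25, c(32, 32, 3))
  expect_equal(predict_proba(back, tile), predict_proba(m, tile),
               tolerance = 1e-12)
})
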