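test_that("plan_tiles places regular starts plus a flush shift-to-fit window", {
  p <- plan_tiles(64, 64, 32, 0.5)
  expect_equal(nrow(p$windows), 9)
  expect_equal(sort(unique(p$windows$row0)), c(0, 16, 32))
  expect_equal(sort(unique(p$windows$col0)), c(0, 16, 32))

  p1 <- plan_tiles(32, 32, 32, 0.5)
  expect_equal(nrow(p1$windows), 1)
  expect_equal(c(p1$windows$row0, p1$windows$col0), c(0, 0))

  p2 <- plan_tiles(70, 70, 32, 0.5)
  expect_equal(nrow(p2$windows), 16)
  expect_equal(sort(unique(p2$windows$row0)), c(0, 16, 32, 38))
  expect_equal(max(p2$windows$row0) + 32, 70) # flush with the far edge

  # row-major listing, no duplicates
  expect_false(any(duplicated(p2$windows[c("row0", "col0")])))
  expect_equal(p2$windows$row0, rep(c(0, 16, 32, 38), each = 4))
})

test_that("window counts match a brute-force enumerator and cover every pixel", {
  set.seed(42)
  for (i in 1:30) {
    h <- sample(32:100, 1); w <- sample(32:100, 1)
    ts <- sample(c(16, 32), 1)
    ov <- sample(c(0, 0.25, 0.5), 1)
    plan <- plan_tiles(h, w, ts, ov)
    expect_equal(nrow(plan$windows), brute_force_window_count(h, w, ts, ov),
                 info = sprintf("h=%d w=%d tile=%d ov=%g", h, w, ts, ov))
    cnt <- matrix(0L, h, w)
    for (j in seq_len(nrow(plan$windows))) {
      ri <- plan$windows$row0[j] + 1:ts
      ci <- plan$windows$col0[j] + 1:ts
      cnt[ri, ci] <- cnt[ri, ci] + 1L
    }
    expect_true(all(cnt >= 1L))
  }
})

test_that("plan_tiles rejects undersized rasters and degenerate strides", {
  expect_error(plan_tiles(30, 64, 32, 0.5), "too small")
  expect_error(plan_tiles(64, 16, 32, 0.5), "too small")
  expect_error(plan_tiles(64, 64, 16, 0.99), "stride")
  expect_error(plan_tiles(64, 64, 32, 1), "overlap_fraction")
})

test_that("extract_tiles copies pixels unmodified in plan order", {
  # constant image -> every tile constant
  img <- array(0.37, c(64, 64, 3))
  plan <- plan_tiles(64, 64, 32, 0.5)
  tiles <- extract_tiles(img, plan)
  expect_length(tiles, 9)
  expect_true(all(vapply(tiles, function(t) all(t == 0.37), logical(1))))

  # 2x2 checkerboard upscaled to 64x64: corner tiles are single-colour
  cb <- matrix(c(0, 1, 1, 0), 2, 2)[rep(1:2, each = 32), rep(1:2, each = 32)]
  cbt <- extract_tiles(promote_channels(cb), plan)
  expect_true(all(cbt[[1]] == 0))      # top-left block
  expect_true(all(cbt[[9]] == 0))      # bottom-right block
  expect_true(all(cbt[[3]] == 1))      # top-right block

  # random image: tile 16 of the 70x70 plan equals a direct slice
  set.seed(1)
  rimg <- array(runif(70 * 70 * 3), c(70, 70, 3))
  p70 <- plan_tiles(70, 70, 32, 0.5)
  t16 <- extract_tiles(rimg, p70)[[16]]
  expect_identical(t16, rimg[39:70, 39:70, , drop = FALSE])

  expect_error(extract_tiles(array(0, c(60, 64, 3)), plan), "plan was built")
})

test_that("stitch_probabilities averages exactly the covering windows", {
  # one window covering the whole image
  p1 <- plan_tiles(32, 32, 32, 0.5)
  f1 <- stitch_probabilities(p1, 0.8)
  expect_true(all(f1 == 0.8))

  # two windows overlapping on a strip: mean of two on the overlap
  p2 <- plan_tiles(32, 48, 32, 0.5)
  expect_equal(nrow(p2$windows), 2)
  f2 <- stitch_probabilities(p2, c(0, 1))
  expect_true(all(f2[, 1:16] == 0))
  expect_true(all(f2[, 17:32] == 0.5))
  expect_true(all(f2[, 33:48] == 1))

  # uniform input stitches to a uniform field
  p3 <- plan_tiles(64, 64, 32, 0.5)
  expect_true(all(stitch_probabilities(p3, rep(0.3, 9)) == 0.3))

  expect_error(stitch_probabilities(p3, rep(0.3, 8)), "expected 9")
  expect_error(stitch_probabilities(p1, 1.2), "\\[0, 1\\]")
})

test_that("tile means of a constant image re-stitch to the constant exactly", {
  img <- array(0.42, c(70, 70, 3))
  plan <- plan_tiles(70, 70, 32, 0.5)
  means <- vapply(extract_tiles(img, plan), mean, numeric(1))
  expect_true(all(stitch_probabilities(plan, means) == 0.42))
})

test_that("tile plans round-trip through CSV", {
  plan <- plan_tiles(70, 64, 32, 0.25)
  path <- withr::local_tempfile(fileext = ".csv")
  write_tile_plan(plan, path)
  back <- read_tile_plan(path)
  expect_equal(back$windows, plan$windows)
  expect_equal(back$stride, plan$stride)
})
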