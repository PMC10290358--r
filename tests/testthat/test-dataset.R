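test_that("build_dataset tiles every source and inherits labels with provenance", {
  reed <- list(make_texture("reed", 64, 64, seed = 1))
  water <- list(make_texture("water", 64, 64, seed = 2))
  ds <- build_dataset(reed, water, tile_size = 32, overlap = 0.5)
  expect_equal(nrow(ds$meta), 18)
  expect_equal(as.vector(table(ds$meta$label)), c(9, 9))
  expect_equal(length(unique(ds$meta$tile_id)), 18)
  expect_equal(length(unique(ds$meta$source_image_id)), 2)
  expect_equal(dim(ds$tiles), c(32, 32, 3, 18))

  # a 32x32 image per class yields exactly one tile each
  ds1 <- build_dataset(list(make_texture("reed", 32, 32, seed = 3)),
                       list(make_texture("water", 32, 32, seed = 4)),
                       tile_size = 32)
  expect_equal(nrow(ds1$meta), 2)

  # tile content matches direct extraction from its source
  plan <- plan_tiles(64, 64, 32, 0.5)
  expect_identical(ds$tiles[, , , 1], extract_tiles(reed[[1]], plan)[[1]][, , ])
})

test_that("a missing class is named in the error", {
  reed <- lapply(1:3, function(i) make_texture("reed", 32, 32, seed = i))
  expect_error(build_dataset(reed, list()), "missing non_reed")
  expect_error(build_dataset(list(), reed), "missing reed")
})

test_that("grayscale sources are promoted to three channels", {
  g <- matrix(runif(32 * 32), 32, 32)
  ds <- build_dataset(list(g), list(matrix(0.5, 32, 32)), tile_size = 32)
  expect_equal(dim(ds$tiles)[3], 3)
  expect_equal(ds$tiles[, , 1, 1], ds$tiles[, , 2, 1])
})

test_that("default corpus tiles to 180 records per class", {
  ds <- default_dataset()
  expect_equal(as.vector(table(ds$meta$label)), c(180, 180))
  expect_equal(length(unique(ds$meta$source_image_id)), 40)
})

test_that("the shuffled split is a deterministic exact partition", {
  ds200 <- fake_tile_set(200)
  sp <- shuffle_split(ds200, seed = 1)
  expect_length(sp$train_ids, 140)
  expect_length(sp$val_ids, 60)

  sp10 <- shuffle_split(fake_tile_set(10), seed = 1)
  expect_length(sp10$train_ids, 7)
  expect_length(sp10$val_ids, 3)

  # identical seeds agree; different seeds differ (n = 100)
  ds100 <- fake_tile_set(100)
  expect_identical(shuffle_split(ds100, seed = 4)$train_ids,
                   shuffle_split(ds100, seed = 4)$train_ids)
  expect_false(identical(sort(shuffle_split(ds100, seed = 4)$train_ids),
                         sort(shuffle_split(ds100, seed = 5)$train_ids)))
})

test_that("partition is disjoint and exhaustive with round-half-up sizes", {
  for (n in c(1:20, sample(21:1000, 40))) {
    ds <- fake_tile_set(n)
    # train_fraction 0.7 requires n >= 2 for a nonempty val side; n = 1 puts
    # the single tile in train
    sp <- shuffle_split(ds, seed = n)
    expect_length(intersect(sp$train_ids, sp$val_ids), 0)
    expect_setequal(c(sp$train_ids, sp$val_ids), ds$meta$tile_id)
    expect_length(sp$train_ids, floor(0.7 * n + 0.5))
  }
})

test_that("class balance is preserved in expectation over seeds", {
  ds <- fake_tile_set(100) # 50/50 balanced by construction
  shares <- vapply(1:200, function(s) {
    sp <- shuffle_split(ds, seed = s)
    mean(ds$meta$label[ds$meta$tile_id %in% sp$train_ids] == "reed")
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.5), 0.05)
})

test_that("group_by_source keeps each source image on one side", {
  ds <- default_dataset()
  for (s in 1:5) {
    sp <- shuffle_split(ds, seed = s, mode = "group_by_source")
    train_src <- unique(ds$meta$source_image_id[ds$meta$tile_id %in% sp$train_ids])
    val_src <- unique(ds$meta$source_image_id[ds$meta$tile_id %in% sp$val_ids])
    expect_length(intersect(train_src, val_src), 0)
    expect_gt(length(val_src), 0)
  }
})

test_that("the manifest CSV lists every tile with its split side", {
  ds <- fake_tile_set(20)
  sp <- shuffle_split(ds, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_manifest(ds, sp, path)
  m <- read.csv(path)
  expect_equal(nrow(m), 20)
  expect_named(m, c("tile_id", "source_image_id", "label", "split"))
  expect_equal(sum(m$split == "train"), 14)
})
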