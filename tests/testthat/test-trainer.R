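# A tiny linearly separable corpus: constant dark vs constant bright tiles.
toy_corpus <- function(n_per_class = 20, size = 8) {
  dark <- lapply(seq_len(n_per_class),
                 function(i) array(0.2 + i * 1e-4, c(size, size, 3)))
  bright <- lapply(seq_len(n_per_class),
                   function(i) array(0.8 - i * 1e-4, c(size, size, 3)))
  build_dataset(bright, dark, tile_size = size)
}

test_that("training history spans the requested epochs and learns a separable toy", {
  ds <- toy_corpus()
  split <- shuffle_split(ds, seed = 1)
  fit <- train_model(build_model(model_spec(tile_size = 8, seed = 1)),
                     ds, split, epochs = 30, batch_size = 4, seed = 1)
  h <- fit$history
  expect_equal(h$epochs, 30)
  expect_length(h$train_loss, 30)
  expect_length(h$val_loss, 30)
  expect_length(h$val_accuracy, 30)
  expect_true(all(is.finite(h$train_loss)) && all(h$train_loss >= 0))
  expect_true(all(h$val_accuracy >= 0 & h$val_accuracy <= 1))
  # separable two-point problem for this capacity: solved within 30 epochs
  expect_equal(h$val_accuracy[30], 1.0)
  # monotone sanity on the training loss
  expect_lt(h$train_loss[30], h$train_loss[1])
  expect_true(fit$trained)
})

test_that("a zero learning rate leaves parameters untouched", {
  ds <- toy_corpus(6)
  split <- shuffle_split(ds, seed = 2)
  m0 <- build_model(model_spec(tile_size = 8, seed = 2))
  fit <- train_model(m0, ds, split, epochs = 4, learning_rate = 0, seed = 2)
  expect_equal(fit$params, m0$params, tolerance = 1e-15)
  expect_equal(length(unique(fit$history$val_accuracy)), 1)
})

test_that("identical seeds reproduce identical histories", {
  ds <- toy_corpus(6)
  split <- shuffle_split(ds, seed = 3)
  run <- function() train_model(build_model(model_spec(tile_size = 8, seed = 3)),
                                ds, split, epochs = 3, seed = 3)
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$params, b$params)
})

test_that("evaluate_model matches closed forms and the confusion-matrix accuracy", {
  ds <- toy_corpus(10, size = 32)
  ids <- ds$meta$tile_id

  # uninformative head: (0.5, 0.5) always -> loss = ln 2, accuracy = share
  # of the class favoured by the argmax tie-break
  m_half <- pinned_model(0.5)
  ev <- evaluate_model(m_half, ds, ids)
  expect_equal(ev$loss, log(2), tolerance = 1e-9)

  # p(true class) = 0.9 on all-reed ids -> loss = -ln 0.9
  m_09 <- pinned_model(0.9)
  reed_ids <- ds$meta$tile_id[ds$meta$label == "reed"][1:10]
  ev9 <- evaluate_model(m_09, ds, reed_ids)
  expect_equal(ev9$loss, -log(0.9), tolerance = 1e-9)
  expect_equal(ev9$accuracy, 1.0)

  # near-one-hot correct predictions: accuracy 1, loss ~ 0
  m_hot <- pinned_model(1)
  evh <- evaluate_model(m_hot, ds, reed_ids)
  expect_equal(evh$accuracy, 1.0)
  expect_lt(evh$loss, 1e-9)

  # accuracy identity with the confusion matrix on identical predictions
  m <- default_fit(1)
  val <- subset_tiles(default_dataset(), m$split$val_ids)
  pred <- predict(m, val, type = "class")
  cm <- confusion_counts(val$meta$label, pred)
  expect_identical(summary_metrics(cm)$accuracy,
                   evaluate_model(m, val, val$meta$tile_id)$accuracy)
})

test_that("degenerate training inputs raise informative errors", {
  ds <- toy_corpus(6)
  split <- shuffle_split(ds, seed = 4)
  # force a single-class training partition
  reed_only <- split
  reed_only$train_ids <- ds$meta$tile_id[ds$meta$label == "reed"]
  reed_only$val_ids <- setdiff(ds$meta$tile_id, reed_only$train_ids)
  expect_error(train_model(build_model(model_spec(tile_size = 8)),
                           ds, reed_only), "single class")
  expect_error(evaluate_model(pinned_model(0.5, 8), ds, character(0)),
               "nonempty")
})

test_that("history CSV lists one row per epoch", {
  ds <- toy_corpus(6)
  fit <- train_model(build_model(model_spec(tile_size = 8, seed = 5)),
                     ds, shuffle_split(ds, seed = 5), epochs = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_history(fit$history, path)
  tab <- read.csv(path)
  expect_equal(nrow(tab), 3)
  expect_named(tab, c("epoch", "train_loss", "val_loss", "val_accuracy"))
})
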