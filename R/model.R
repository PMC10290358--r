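#' Architecture hyperparameters for the reed classifier
#'
#' The network is the compact patch classifier: two convolution layers each
#' followed by a pooling layer, then one fully connected layer with a
#' two-unit softmax head giving a class probability for reed and non-reed.
#' Convolutions are same-padding with ReLU activations; pooling is max or
#' average over `pool_size x pool_size` regions with stride `pool_size`.
#'
#' @param tile_size Input tile side in pixels; must be divisible by
#'   `pool_size^2` so both pooling stages land on integer sizes.
#' @param in_channels Input channels (3 for RGB).
#' @param conv_channels Integer pair: feature maps of the first and second
#'   convolution layer.
#' @param kernel_size Odd convolution kernel side in pixels.
#' @param pooling `"max"` or `"average"`.
#' @param pool_size Pooling window side (= stride).
#' @param seed Integer seed for the deterministic weight initialisation.
#' @return Object of class `reed_cnn_spec`.
#' @export
model_spec <- function(tile_size = 32, in_channels = 3,
                       conv_channels = c(8, 16), kernel_size = 3,
                       pooling = c("max", "average"), pool_size = 2,
                       seed = 0) {
  pooling <- match.arg(pooling)
  tile_size <- as.integer(tile_size)
  pool_size <- as.integer(pool_size)
  kernel_size <- as.integer(kernel_size)
  if (length(conv_channels) != 2L || any(conv_channels < 1))
    stop("conv_channels must be two positive counts")
  if (kernel_size %% 2L == 0L) stop("kernel_size must be odd (same padding)")
  if (tile_size %% pool_size^2 != 0L)
    stop("tile_size must be divisible by pool_size^2 = ", pool_size^2,
         " (minimum admissible size ", pool_size^2, ")")
  structure(list(tile_size = tile_size, in_channels = as.integer(in_channels),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = kernel_size, pooling = pooling,
                 pool_size = pool_size, n_classes = 2L,
                 seed = as.integer(seed)),
            class = "reed_cnn_spec")
}

# Spatial bookkeeping: sizes after each stage and the flatten length.
spec_dims <- function(spec) {
  s1 <- spec$tile_size %/% spec$pool_size
  s2 <- s1 %/% spec$pool_size
  list(after_pool1 = s1, after_pool2 = s2,
       flatten = s2 * s2 * spec$conv_channels[2L])
}

# Seeded uniform fan-in initialisation: W ~ U(-1/sqrt(fan_in), 1/sqrt(fan_in)),
# biases zero. Deterministic given spec$seed.
init_params <- function(spec) {
  k <- spec$kernel_size
  d <- spec_dims(spec)
  fan1 <- k * k * spec$in_channels
  fan2 <- k * k * spec$conv_channels[1L]
  with_seed(spec$seed, list(
    w1 = matrix(stats::runif(fan1 * spec$conv_channels[1L],
                             -1 / sqrt(fan1), 1 / sqrt(fan1)),
                fan1, spec$conv_channels[1L]),
    b1 = numeric(spec$conv_channels[1L]),
    w2 = matrix(stats::runif(fan2 * spec$conv_channels[2L],
                             -1 / sqrt(fan2), 1 / sqrt(fan2)),
                fan2, spec$conv_channels[2L]),
    b2 = numeric(spec$conv_channels[2L]),
    wfc = matrix(stats::runif(d$flatten * spec$n_classes,
                              -1 / sqrt(d$flatten), 1 / sqrt(d$flatten)),
                 d$flatten, spec$n_classes),
    bfc = numeric(spec$n_classes)
  ))
}

#' Build the classifier in its untrained state
#'
#' Layer sequence: conv1 -> pool1 -> conv2 -> pool2 -> flatten -> fully
#' connected -> softmax. Parameter initialisation is deterministic given
#' `spec$seed`; two builds with the same spec are bit-identical.
#'
#' @param spec A [model_spec()].
#' @return Object of class `reed_cnn` with `trained = FALSE`.
#' @seealso [reed_cnn()] to build and train in one call.
#' @export
build_model <- function(spec = model_spec()) {
  stopifnot(inherits(spec, "reed_cnn_spec"))
  params <- init_params(spec)
  structure(list(spec = spec, params = params, dims = spec_dims(spec),
                 trained = FALSE, history = NULL,
                 classes = c("reed", "non_reed")),
            class = "reed_cnn")
}

#' Number of trainable parameters
#'
#' @param model A `reed_cnn`.
#' @return Integer count, a pure function of the model spec.
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "reed_cnn"))
  sum(vapply(model$params, length, integer(1)))
}

# Full forward pass. x: (size, size, C, N). Returns probs (N x 2) and,
# if keep_cache, the layer caches needed for backprop.
forward_pass <- function(model, x, keep_cache = FALSE) {
  p <- model$params
  s <- model$spec
  c1 <- conv_forward(x, p$w1, p$b1)
  r1 <- relu_forward(c1$out)
  pl1 <- pool_forward(r1$out, s$pool_size,
                      if (s$pooling == "max") "max" else "average")
  c2 <- conv_forward(pl1$out, p$w2, p$b2)
  r2 <- relu_forward(c2$out)
  pl2 <- pool_forward(r2$out, s$pool_size,
                      if (s$pooling == "max") "max" else "average")
  n <- dim(x)[4L]
  xf <- t(matrix(pl2$out, nrow = model$dims$flatten, ncol = n))
  logits <- sweep(xf %*% p$wfc, 2L, p$bfc, "+")
  probs <- softmax_rows(logits)
  res <- list(probs = probs, logits = logits)
  if (keep_cache)
    res$cache <- list(c1 = c1$cache, r1 = r1$cache, pl1 = pl1$cache,
                      c2 = c2$cache, r2 = r2$cache, pl2 = pl2$cache,
                      xf = xf, n = n)
  res
}

# Backward pass from dlogits (N x 2); returns gradients named as params.
backward_pass <- function(model, cache, dlogits) {
  p <- model$params
  dwfc <- crossprod(cache$xf, dlogits)
  dbfc <- colSums(dlogits)
  dxf <- tcrossprod(dlogits, p$wfc)
  od2 <- dim_after_pool2(model, cache$n)
  dpl2 <- array(t(dxf), od2)
  dr2 <- pool_backward(dpl2, cache$pl2)
  dc2 <- relu_backward(dr2, cache$r2)
  g2 <- conv_backward(dc2, cache$c2)
  dr1 <- pool_backward(g2$dx, cache$pl1)
  dc1 <- relu_backward(dr1, cache$r1)
  g1 <- conv_backward(dc1, cache$c1)
  list(w1 = g1$dw, b1 = g1$db, w2 = g2$dw, b2 = g2$db,
       wfc = dwfc, bfc = dbfc)
}

dim_after_pool2 <- function(model, n) {
  s2 <- model$dims$after_pool2
  c(s2, s2, model$spec$conv_channels[2L], n)
}

# Coerce a list of tiles / single tile / 4-D array to a batch array,
# validating shape against the model spec.
as_tile_batch <- function(model, tiles) {
  s <- model$spec
  if (is.list(tiles)) {
    tiles <- lapply(tiles, function(t) {
      if (length(dim(t)) == 2L) promote_channels(t) else t
    })
    d <- dim(tiles[[1L]])
    arr <- array(unlist(tiles), c(d, length(tiles)))
  } else if (length(dim(tiles)) == 3L) {
    arr <- array(tiles, c(dim(tiles), 1L))
  } else {
    arr <- tiles
  }
  d <- dim(arr)
  if (d[1L] != s$tile_size || d[2L] != s$tile_size ||
      d[3L] != s$in_channels)
    stop("tile shape mismatch: expected ", s$tile_size, "x", s$tile_size,
         "x", s$in_channels, ", received ",
         paste(d[1:3], collapse = "x"))
  arr
}

#' Class probabilities for tiles
#'
#' Runs the forward pass and returns the softmax class probabilities; each row
#' sums to one and output order matches input order. A pure function of the
#' model parameters and the input.
#'
#' @param model A `reed_cnn`.
#' @param tiles List of `size x size x C` arrays, a single such array, a
#'   4-D batch array, or a `tile_set`.
#' @param batch_size Tiles per forward batch (memory knob; does not affect
#'   results).
#' @return Numeric matrix with columns `reed` and `non_reed`.
#' @export
predict_proba <- function(model, tiles, batch_size = 256) {
  stopifnot(inherits(model, "reed_cnn"))
  if (inherits(tiles, "tile_set")) tiles <- tiles$tiles
  x <- as_tile_batch(model, tiles)
  n <- dim(x)[4L]
  out <- matrix(NA_real_, n, 2L,
                dimnames = list(NULL, c("reed", "non_reed")))
  for (start in seq.int(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    out[idx, ] <- forward_pass(model, x[, , , idx, drop = FALSE])$probs
  }
  out
}

#' Save or load a model checkpoint
#'
#' Single-file JSON checkpoint with a versioned header; the spec round-trips
#' losslessly and parameters are stored at full decimal precision
#' (reproduced to within double rounding, relative error below 1e-12).
#'
#' @param model A `reed_cnn`.
#' @param path Checkpoint path (conventionally `.json`).
#' @return `path` invisibly (`write_checkpoint`); a `reed_cnn`
#'   (`read_checkpoint`).
#' @export
write_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "reed_cnn"))
  payload <- list(
    format = "reedcover-checkpoint", version = 1L,
    spec = unclass(model$spec),
    trained = model$trained,
    params = lapply(model$params, function(p)
      list(dim = if (is.matrix(p)) dim(p) else length(p),
           values = as.vector(p))),
    history = if (!is.null(model$history)) unclass(model$history)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$format, "reedcover-checkpoint"))
    stop("not a reedcover checkpoint: ", path)
  spec <- do.call(model_spec, j$spec[c("tile_size", "in_channels",
                                       "conv_channels", "kernel_size",
                                       "pooling", "pool_size", "seed")])
  model <- build_model(spec)
  for (nm in names(model$params)) {
    p <- j$params[[nm]]
    model$params[[nm]] <- if (length(p$dim) == 2L)
      matrix(p$values, p$dim[1L], p$dim[2L]) else as.numeric(p$values)
  }
  model$trained <- isTRUE(j$trained)
  if (!is.null(j$history))
    model$history <- structure(as.list(j$history),
                               class = "training_history")
  model
}

#' @export
print.reed_cnn <- function(x, ...) {
  s <- x$spec
  cat("Reed/non-reed patch classifier (",
      if (x$trained) "trained" else "untrained", ")\n", sep = "")
  cat(sprintf("  input %dx%dx%d -> conv %d -> %s-pool -> conv %d -> %s-pool -> fc %d -> softmax(2)\n",
              s$tile_size, s$tile_size, s$in_channels, s$conv_channels[1L],
              s$pooling, s$conv_channels[2L], s$pooling, x$dims$flatten))
  cat("  parameters:", n_parameters(x), "  init seed:", s$seed, "\n")
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("  trained %d epochs; final val accuracy %.4f, val loss %.4f\n",
                h$epochs, h$val_accuracy[h$epochs], h$val_loss[h$epochs]))
  }
  invisible(x)
}

#' @export
coef.reed_cnn <- function(object, ...) object$params
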