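# Training loop: minibatch Adam on the two-class cross-entropy, with
# per-epoch validation accuracy and loss. Everything is seeded and
# single-threaded, so identical (seed, spec, data) reproduce identical
# histories bit-for-bit.

label_index <- function(labels) {
  y <- match(as.character(labels), c("reed", "non_reed"))
  if (anyNA(y)) stop("labels must be 'reed' or 'non_reed'")
  y
}

cross_entropy <- function(probs, y) {
  -mean(log(pmax(probs[cbind(seq_along(y), y)], 1e-12)))
}

#' Train the classifier on a labelled tile corpus
#'
#' Minimises the categorical cross-entropy of the two-class softmax by
#' minibatch Adam, recording per-epoch training loss, validation loss and
#' validation accuracy ("accuracy" is the fraction of validation tiles whose
#' argmax class matches the label; "loss" the mean negative log probability
#' of the true class). Batch order is reshuffled every epoch from the run
#' seed; the whole run is deterministic given `(seed, spec, data)`.
#'
#' @param model A `reed_cnn` (untrained or to be trained further).
#' @param dataset A `tile_set`.
#' @param split A `split_assignment` covering the dataset; both classes must
#'   be present in the training partition.
#' @param epochs Number of training epochs (default 30).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param seed Integer seed driving batch shuffling.
#' @return The trained `reed_cnn`, with a `training_history` (fields
#'   `train_loss`, `val_loss`, `val_accuracy`, `epochs`, `seed`) attached as
#'   `$history`.
#' @seealso [reed_cnn()] for the one-call interface, [evaluate_model()].
#' @export
train_model <- function(model, dataset, split, epochs = 30,
                        learning_rate = 1e-3, batch_size = 32, seed = 0) {
  stopifnot(inherits(model, "reed_cnn"), inherits(dataset, "tile_set"),
            inherits(split, "split_assignment"))
  if (!all(c(split$train_ids, split$val_ids) %in% dataset$meta$tile_id))
    stop("split refers to tile ids absent from the dataset")
  train <- subset_tiles(dataset, split$train_ids)
  val <- subset_tiles(dataset, split$val_ids)
  y_train <- label_index(train$meta$label)
  if (length(unique(y_train)) < 2L)
    stop("training partition contains a single class; both classes required")
  n <- length(y_train)
  state <- adam_init(model$params)
  hist <- list(train_loss = numeric(epochs), val_loss = numeric(epochs),
               val_accuracy = numeric(epochs), epochs = as.integer(epochs),
               seed = as.integer(seed))
  epoch_perms <- with_seed(seed, lapply(seq_len(epochs),
                                        function(e) sample.int(n)))
  for (epoch in seq_len(epochs)) {
    perm <- epoch_perms[[epoch]]
    batch_losses <- c()
    for (start in seq.int(1L, n, by = batch_size)) {
      idx <- perm[start:min(start + batch_size - 1L, n)]
      xb <- train$tiles[, , , idx, drop = FALSE]
      yb <- y_train[idx]
      fw <- forward_pass(model, xb, keep_cache = TRUE)
      loss <- cross_entropy(fw$probs, yb)
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch)
      batch_losses <- c(batch_losses, loss)
      yhot <- matrix(0, length(yb), 2L)
      yhot[cbind(seq_along(yb), yb)] <- 1
      dlogits <- (fw$probs - yhot) / length(yb)
      grads <- backward_pass(model, fw$cache, dlogits)
      upd <- adam_step(model$params, grads, state, lr = learning_rate)
      model$params <- upd$params
      state <- upd$state
    }
    ev <- evaluate_model(model, val, val$meta$tile_id)
    hist$train_loss[epoch] <- mean(batch_losses)
    hist$val_loss[epoch] <- ev$loss
    hist$val_accuracy[epoch] <- ev$accuracy
  }
  model$trained <- TRUE
  model$history <- structure(hist, class = "training_history")
  model
}

#' Accuracy and mean cross-entropy on a set of tiles
#'
#' @param model A `reed_cnn`.
#' @param dataset A `tile_set`.
#' @param ids Nonempty character vector of tile ids to evaluate.
#' @return List with `accuracy` (fraction of tiles whose argmax class equals
#'   the label) and `loss` (mean negative log probability of the true class).
#' @export
evaluate_model <- function(model, dataset, ids) {
  stopifnot(inherits(dataset, "tile_set"))
  if (length(ids) == 0L) stop("ids must be nonempty")
  sub <- subset_tiles(dataset, ids)
  y <- label_index(sub$meta$label)
  probs <- predict_proba(model, sub$tiles)
  pred <- max.col(probs, ties.method = "first")
  list(accuracy = mean(pred == y), loss = cross_entropy(probs, y))
}

#' Fit the reed-cover patch classifier
#'
#' One-call interface: builds the network from its architecture
#' hyperparameters, splits the corpus 70/30 (shuffled), and trains for 30
#' epochs, mirroring the field protocol of cropping pure-class photographs
#' into fifty-percent-overlapping squares and learning a softmax classifier
#' over them.
#'
#' @param dataset A `tile_set` from [build_dataset()].
#' @param split Optional `split_assignment`; by default a shuffled 70/30
#'   split with `seed`.
#' @param spec Optional [model_spec()]; by default inferred from the tile
#'   shape with `seed` as the initialisation seed.
#' @param epochs,learning_rate,batch_size Training hyperparameters.
#' @param train_fraction Training fraction for the default split.
#' @param seed Integer seed governing split, initialisation and shuffling.
#' @return A trained `reed_cnn`; see [predict.reed_cnn()] and
#'   [plot.reed_cnn()], plus the usual `print`, `summary` and `coef` methods.
#' @examples
#' \donttest{
#' corpus <- make_training_corpus(n_per_class = 4, image_size = 32, seed = 1)
#' ds <- build_dataset(corpus$reed, corpus$non_reed, tile_size = 16)
#' fit <- reed_cnn(ds, spec = model_spec(tile_size = 16), epochs = 3, seed = 1)
#' print(fit)
#' }
#' @export
reed_cnn <- function(dataset, split = NULL, spec = NULL, epochs = 30,
                     learning_rate = 1e-3, batch_size = 32,
                     train_fraction = 0.7, seed = 0) {
  stopifnot(inherits(dataset, "tile_set"))
  d <- dim(dataset$tiles)
  if (is.null(spec))
    spec <- model_spec(tile_size = d[1L], in_channels = d[3L], seed = seed)
  if (is.null(split))
    split <- shuffle_split(dataset, train_fraction = train_fraction,
                           seed = seed)
  model <- build_model(spec)
  model <- train_model(model, dataset, split, epochs = epochs,
                       learning_rate = learning_rate,
                       batch_size = batch_size, seed = seed)
  model$split <- split
  model
}

#' Predict method for reed_cnn models
#'
#' @param object A trained `reed_cnn`.
#' @param newdata Tiles: a `tile_set`, list of arrays, one array, or a 4-D
#'   batch array.
#' @param type `"prob"` for softmax class probabilities, `"class"` for the
#'   argmax label.
#' @param ... Unused.
#' @return A probability matrix (columns `reed`, `non_reed`) or a factor of
#'   class labels.
#' @export
predict.reed_cnn <- function(object, newdata, type = c("prob", "class"),
                             ...) {
  type <- match.arg(type)
  probs <- predict_proba(object, newdata)
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' @export
summary.reed_cnn <- function(object, ...) {
  structure(list(spec = object$spec, dims = object$dims,
                 n_parameters = n_parameters(object),
                 trained = object$trained, history = object$history,
                 split = object$split),
            class = "summary.reed_cnn")
}

#' @export
print.summary.reed_cnn <- function(x, ...) {
  s <- x$spec
  cat("Reed/non-reed patch classifier\n")
  cat(sprintf("  architecture : conv(%d, %dx%d) -> %s-pool(%d) -> conv(%d, %dx%d) -> %s-pool(%d) -> fc(%d -> 2) -> softmax\n",
              s$conv_channels[1L], s$kernel_size, s$kernel_size, s$pooling,
              s$pool_size, s$conv_channels[2L], s$kernel_size, s$kernel_size,
              s$pooling, s$pool_size, x$dims$flatten))
  cat("  tile size    :", s$tile_size, "px,", s$in_channels, "channels\n")
  cat("  parameters   :", x$n_parameters, "\n")
  if (!is.null(x$split))
    cat("  split        :", length(x$split$train_ids), "train /",
        length(x$split$val_ids), "validation (", x$split$mode, ")\n")
  if (!is.null(x$history)) {
    h <- x$history
    cat(sprintf("  training     : %d epochs; val accuracy %.4f, val loss %.4f (final epoch)\n",
                h$epochs, h$val_accuracy[h$epochs], h$val_loss[h$epochs]))
  } else {
    cat("  training     : untrained\n")
  }
  invisible(x)
}

#' Plot accuracy and loss curves
#'
#' @param x A trained `reed_cnn`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.reed_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(seq_len(h$epochs), cbind(h$train_loss, h$val_loss),
                    type = "l", lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::plot(seq_len(h$epochs), h$val_accuracy, type = "l",
                 col = "forestgreen", xlab = "epoch",
                 ylab = "validation accuracy", ylim = c(0, 1))
  invisible(x)
}

#' Write a training history to CSV
#'
#' Columns `epoch,train_loss,val_loss,val_accuracy`.
#'
#' @param history A `training_history` (from `model$history`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  stopifnot(inherits(history, "training_history"))
  utils::write.csv(
    data.frame(epoch = seq_len(history$epochs),
               train_loss = history$train_loss,
               val_loss = history$val_loss,
               val_accuracy = history$val_accuracy),
    path, row.names = FALSE)
  invisible(path)
}

#' @export
print.training_history <- function(x, ...) {
  cat(sprintf("Training history: %d epochs (seed %d)\n", x$epochs, x$seed))
  cat(sprintf("  final train loss %.4f, val loss %.4f, val accuracy %.4f\n",
              x$train_loss[x$epochs], x$val_loss[x$epochs],
              x$val_accuracy[x$epochs]))
  invisible(x)
}
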