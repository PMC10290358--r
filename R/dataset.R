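#' Build a binary-labelled tile corpus from pure-class images
#'
#' Each source image is tiled with [plan_tiles()] (fifty-percent overlap by
#' default); every crop inherits its source image's class label and keeps its
#' source-image provenance. Grayscale sources are promoted to three channels
#' so all tiles share one shape.
#'
#' @param reed_images,nonreed_images Lists of `H x W x C` arrays, one list per
#'   class; every image must be at least `tile_size` in both dimensions.
#' @param tile_size Crop side in pixels.
#' @param overlap Overlap fraction between adjacent crops.
#' @return Object of class `tile_set`: list with `tiles` (array
#'   `size x size x 3 x n`) and `meta` (data frame `tile_id`,
#'   `source_image_id`, `label` with levels `reed`, `non_reed`).
#' @examples
#' corpus <- make_training_corpus(n_per_class = 2, image_size = 32, seed = 1)
#' ds <- build_dataset(corpus$reed, corpus$non_reed, tile_size = 32)
#' table(ds$meta$label)
#' @export
build_dataset <- function(reed_images, nonreed_images, tile_size = 32,
                          overlap = 0.5) {
  if (length(reed_images) == 0L) stop("missing reed class: no images supplied")
  if (length(nonreed_images) == 0L)
    stop("missing non_reed class: no images supplied")
  one_class <- function(images, label, offset) {
    out <- vector("list", length(images))
    for (i in seq_along(images)) {
      img <- promote_channels(images[[i]])
      plan <- plan_tiles(dim(img)[1L], dim(img)[2L], tile_size, overlap)
      tiles <- extract_tiles(img, plan)
      out[[i]] <- list(
        tiles = tiles,
        meta = data.frame(
          source_image_id = sprintf("%s%02d", substr(label, 1, 1),
                                    offset + i),
          label = label, stringsAsFactors = FALSE)[rep(1L, length(tiles)), ]
      )
    }
    out
  }
  parts <- c(one_class(reed_images, "reed", 0L),
             one_class(nonreed_images, "non_reed", 0L))
  tiles <- unlist(lapply(parts, `[[`, "tiles"), recursive = FALSE)
  meta <- do.call(rbind, lapply(parts, `[[`, "meta"))
  n <- length(tiles)
  sz <- dim(tiles[[1L]])
  if (!all(vapply(tiles, function(t) identical(dim(t), sz), logical(1))))
    stop("all source images must produce tiles of identical shape")
  arr <- array(unlist(tiles), c(sz, n))
  meta$tile_id <- sprintf("tile%05d", seq_len(n))
  meta$label <- factor(meta$label, levels = c("reed", "non_reed"))
  rownames(meta) <- NULL
  structure(list(tiles = arr,
                 meta = meta[c("tile_id", "source_image_id", "label")]),
            class = "tile_set")
}

#' @export
print.tile_set <- function(x, ...) {
  tab <- table(x$meta$label)
  cat("Labelled tile set:", nrow(x$meta), "tiles of",
      paste(dim(x$tiles)[1:3], collapse = "x"),
      sprintf("(%s)\n", paste(names(tab), tab, sep = " = ",
                              collapse = ", ")))
  invisible(x)
}

#' Subset a tile set by tile id
#'
#' @param dataset A `tile_set`.
#' @param ids Character vector of tile ids.
#' @return A `tile_set` restricted to `ids`, in the given order.
#' @export
subset_tiles <- function(dataset, ids) {
  stopifnot(inherits(dataset, "tile_set"))
  idx <- match(ids, dataset$meta$tile_id)
  if (anyNA(idx)) stop("unknown tile ids: ",
                       paste(utils::head(ids[is.na(idx)], 3), collapse = ", "))
  structure(list(tiles = dataset$tiles[, , , idx, drop = FALSE],
                 meta = dataset$meta[idx, , drop = FALSE]),
            class = "tile_set")
}

round_half_up <- function(x) floor(x + 0.5)

#' Shuffled train/validation split
#'
#' Randomly shuffles tiles and assigns 70 percent (by default) to training and
#' the rest to validation. `mode = "tile_shuffle"` permutes individual tiles;
#' because fifty-percent-overlapping crops of one photograph share pixels,
#' this leaks information between the partitions, so
#' `mode = "group_by_source"` is offered as the leakage-safe alternative that
#' keeps every source image's tiles on one side.
#'
#' @param dataset A `tile_set`.
#' @param train_fraction Fraction of tiles assigned to training, in (0, 1);
#'   the train partition size is `floor(train_fraction * n + 0.5)`
#'   (round half up) under `tile_shuffle`.
#' @param seed Integer seed; the assignment is deterministic given
#'   `(seed, mode)`.
#' @param mode `"tile_shuffle"` (default) or `"group_by_source"`.
#' @return Object of class `split_assignment`: list with `train_ids`,
#'   `val_ids`, `seed`, `mode`.
#' @export
shuffle_split <- function(dataset, train_fraction = 0.7, seed = 0,
                          mode = c("tile_shuffle", "group_by_source")) {
  stopifnot(inherits(dataset, "tile_set"))
  mode <- match.arg(mode)
  n <- nrow(dataset$meta)
  if (n < 1L) stop("dataset is empty")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  ids <- dataset$meta$tile_id
  if (mode == "tile_shuffle") {
    n_train <- round_half_up(train_fraction * n)
    perm <- with_seed(seed, sample.int(n))
    train_ids <- ids[perm[seq_len(n_train)]]
    val_ids <- ids[perm[setdiff(seq_len(n), seq_len(n_train))]]
  } else {
    src <- dataset$meta$source_image_id
    sources <- unique(src)
    ord <- with_seed(seed, sample(sources))
    target <- round_half_up(train_fraction * n)
    counts <- cumsum(table(src)[ord])
    k <- which(counts >= target)[1L]
    train_src <- ord[seq_len(k)]
    train_ids <- ids[src %in% train_src]
    val_ids <- ids[!src %in% train_src]
    if (length(val_ids) == 0L)
      stop("group_by_source left no validation sources; supply more images")
  }
  structure(list(train_ids = train_ids, val_ids = val_ids,
                 seed = as.integer(seed), mode = mode),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("Split (", x$mode, ", seed ", x$seed, "): ",
      length(x$train_ids), " train / ", length(x$val_ids), " validation\n",
      sep = "")
  invisible(x)
}

#' Write a split manifest CSV
#'
#' One row per tile with columns `tile_id,source_image_id,label,split`.
#'
#' @param dataset A `tile_set`.
#' @param split A `split_assignment` covering the dataset.
#' @param path Output CSV path.
#' @return The manifest data frame, invisibly.
#' @export
write_manifest <- function(dataset, split, path) {
  m <- dataset$meta
  m$split <- ifelse(m$tile_id %in% split$train_ids, "train", "val")
  utils::write.csv(m, path, row.names = FALSE, quote = FALSE)
  invisible(m)
}
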