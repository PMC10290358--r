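# Shared fixtures and independent oracles. Expensive objects (trained
# models, the default corpus) are built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# The default study corpus: 20 + 20 pure-class images of 64x64, tiled at 32
# with fifty-percent overlap, corpus seed 0.
default_dataset <- function() {
  memo("default_dataset", function() {
    corpus <- make_training_corpus(n_per_class = 20, image_size = 64,
                                   seed = 0)
    build_dataset(corpus$reed, corpus$non_reed, tile_size = 32,
                  overlap = 0.5)
  })
}

# A classifier fitted on the default corpus with the given run seed
# (split + init + batch shuffling).
default_fit <- function(seed) {
  memo(paste0("fit_seed_", seed), function() {
    reed_cnn(default_dataset(), seed = seed)
  })
}

# Independent brute-force enumerator of tile windows: walks every admissible
# start with a while loop and applies the shift-to-fit rule directly.
brute_force_starts <- function(extent, tile_size, stride) {
  starts <- integer(0)
  s <- 0L
  while (s + tile_size <= extent) {
    starts <- c(starts, s)
    s <- s + stride
  }
  if (starts[length(starts)] + tile_size < extent)
    starts <- c(starts, extent - tile_size)
  starts
}

brute_force_window_count <- function(h, w, tile_size, overlap) {
  stride <- as.integer(round(tile_size * (1 - overlap)))
  length(brute_force_starts(h, tile_size, stride)) *
    length(brute_force_starts(w, tile_size, stride))
}

# Minimal tile_set built directly in code, for split-partition properties
# where tile content is irrelevant.
fake_tile_set <- function(n, labels = rep(c("reed", "non_reed"),
                                          length.out = n),
                          sources = sprintf("s%02d", rep(seq_len(max(1, n %/% 4)),
                                                         length.out = n))) {
  structure(list(
    tiles = array(0, c(4, 4, 3, n)),
    meta = data.frame(tile_id = sprintf("tile%05d", seq_len(n)),
                      source_image_id = sources,
                      label = factor(labels, levels = c("reed", "non_reed")),
                      stringsAsFactors = FALSE)),
    class = "tile_set")
}

# A model whose softmax output is pinned to fixed probabilities for every
# input: all weights zero, head biases chosen to give the target p_reed.
pinned_model <- function(p_reed = 0.5, tile_size = 32) {
  m <- build_model(model_spec(tile_size = tile_size, seed = 0))
  for (nm in c("w1", "w2", "wfc")) m$params[[nm]][] <- 0
  m$params$b1[] <- 0; m$params$b2[] <- 0
  m$params$bfc <- if (p_reed <= 0 || p_reed >= 1) {
    c(if (p_reed >= 1) 50 else -50, 0)
  } else {
    c(log(p_reed / (1 - p_reed)), 0)
  }
  m$trained <- TRUE
  m
}
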