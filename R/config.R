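# Run configuration and the subcommand layer behind the command-line entry
# point (inst/cli/reedcover.R). Every run writes a manifest beside its
# outputs (config hash, seed, package version, timestamp) so identical
# seeded runs are auditable and reproducible.

#' Default run configuration
#'
#' All pipeline knobs in one serialisable list. Numeric fields are validated
#' against the ranges declared by their owning operations; unknown keys are
#' rejected at parse time.
#'
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    tile_size = 32L, overlap_fraction = 0.5,
    train_fraction = 0.7, split_mode = "tile_shuffle",
    conv_channels = c(8L, 16L), kernel_size = 3L,
    pooling = "max", pool_size = 2L,
    epochs = 30L, learning_rate = 1e-3, batch_size = 32L,
    threshold = 0.5, risk_threshold = 0.6,
    n_per_class = 20L, image_size = 64L,
    scene_height = 256L, scene_width = 256L,
    target_coverage = 0.4, n_patches = 64L,
    seed = 0L,
    input_dir = ".", output_dir = "."
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' @param config A named list.
#' @return The validated `run_config`, with integerish fields coerced.
#' @export
validate_run_config <- function(config) {
  defaults <- default_run_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  merged <- utils::modifyList(unclass(defaults), config)
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(merged$tile_size >= 2, "tile_size must be >= 2")
  chk(merged$overlap_fraction >= 0 && merged$overlap_fraction < 1,
      "overlap_fraction must be in [0, 1)")
  chk(merged$train_fraction > 0 && merged$train_fraction < 1,
      "train_fraction must be in (0, 1)")
  chk(merged$split_mode %in% c("tile_shuffle", "group_by_source"),
      "split_mode must be tile_shuffle or group_by_source")
  chk(length(merged$conv_channels) == 2 && all(merged$conv_channels >= 1),
      "conv_channels must be two positive counts")
  chk(merged$pooling %in% c("max", "average"),
      "pooling must be max or average")
  chk(merged$epochs >= 1, "epochs must be >= 1")
  chk(merged$learning_rate >= 0, "learning_rate must be >= 0")
  chk(merged$batch_size >= 1, "batch_size must be >= 1")
  chk(merged$threshold >= 0 && merged$threshold <= 1,
      "threshold must be in [0, 1]")
  chk(merged$risk_threshold >= 0 && merged$risk_threshold <= 1,
      "risk_threshold must be in [0, 1]")
  chk(merged$target_coverage >= 0 && merged$target_coverage <= 1,
      "target_coverage must be in [0, 1]")
  for (f in c("tile_size", "conv_channels", "kernel_size", "pool_size",
              "epochs", "batch_size", "n_per_class", "image_size",
              "scene_height", "scene_width", "n_patches", "seed"))
    merged[[f]] <- as.integer(merged[[f]])
  structure(merged, class = "run_config")
}

#' Read or write a run configuration as JSON
#'
#' `parse(serialize(config))` reproduces the configuration exactly.
#'
#' @param path JSON file path.
#' @param config A `run_config`.
#' @return A validated `run_config` (`read_run_config`); `path` invisibly
#'   (`write_run_config`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  validate_run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  config <- validate_run_config(config)
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

config_model_spec <- function(config) {
  model_spec(tile_size = config$tile_size, in_channels = 3L,
             conv_channels = config$conv_channels,
             kernel_size = config$kernel_size, pooling = config$pooling,
             pool_size = config$pool_size, seed = config$seed)
}

write_run_manifest <- function(config, out_dir, subcommand) {
  cfg_path <- file.path(out_dir, "effective_config.json")
  write_run_config(config, cfg_path)
  jsonlite::write_json(
    list(subcommand = subcommand,
         config_hash = unname(tools::md5sum(cfg_path)),
         seed = config$seed,
         package_version = as.character(utils::packageVersion("reedcover")),
         timestamp = format(Sys.time(), tz = "UTC")),
    file.path(out_dir, "run_manifest.json"), auto_unbox = TRUE)
  invisible(cfg_path)
}

# Rebuild the seeded synthetic corpus + dataset + split a config describes.
config_dataset <- function(config) {
  corpus <- make_training_corpus(config$n_per_class, config$image_size,
                                 seed = config$seed)
  ds <- build_dataset(corpus$reed, corpus$non_reed,
                      tile_size = config$tile_size,
                      overlap = config$overlap_fraction)
  split <- shuffle_split(ds, train_fraction = config$train_fraction,
                         seed = config$seed, mode = config$split_mode)
  list(dataset = ds, split = split)
}

#' Run one pipeline stage from a configuration
#'
#' Subcommands: `simulate` writes a seeded synthetic corpus and scene
#' (`corpus/`, `images/`, `masks/`, `scenes.csv`); `tile` writes the tile
#' plan CSV for the configured scene size; `split` writes the
#' train/validation manifest; `train` trains the classifier and writes
#' `history.csv` plus a checkpoint; `eval` evaluates the checkpoint on the
#' validation partition and writes `metrics.json`; `covermap` maps a scene
#' (the configured synthetic scene, or `input_dir/scene.png` if present) and
#' writes `coverage.json` with probability and mask rasters; `chem` writes
#' the packaged chemistry tables and range summaries. Each run writes
#' `run_manifest.json` and `effective_config.json` beside its outputs.
#'
#' @param name Subcommand name.
#' @param config A `run_config` (validated here).
#' @return Invisible list of produced artifact paths.
#' @export
run_subcommand <- function(name = c("simulate", "tile", "split", "train",
                                    "eval", "covermap", "chem"),
                           config = default_run_config()) {
  name <- match.arg(name)
  config <- validate_run_config(unclass(config))
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  write_run_manifest(config, out, name)
  artifacts <- switch(
    name,
    simulate = {
      corp_dir <- file.path(out, "corpus")
      img_dir <- file.path(out, "images")
      mask_dir <- file.path(out, "masks")
      for (d in c(file.path(corp_dir, "reed"), file.path(corp_dir, "non_reed"),
                  img_dir, mask_dir))
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
      corpus <- make_training_corpus(config$n_per_class, config$image_size,
                                     seed = config$seed)
      for (i in seq_along(corpus$reed))
        write_raster(corpus$reed[[i]],
                     file.path(corp_dir, "reed", sprintf("reed%02d.png", i)))
      for (i in seq_along(corpus$non_reed))
        write_raster(corpus$non_reed[[i]],
                     file.path(corp_dir, "non_reed",
                               sprintf("nonreed%02d.png", i)))
      scn <- compose_scene(scene_spec(config$scene_height,
                                      config$scene_width,
                                      config$target_coverage,
                                      config$n_patches,
                                      seed = config$seed))
      scene_id <- sprintf("scene%03d", config$seed)
      write_raster(scn$image, file.path(img_dir, paste0(scene_id, ".png")))
      write_raster(scn$mask, file.path(mask_dir, paste0(scene_id, ".png")))
      utils::write.csv(
        data.frame(scene_id = scene_id, seed = config$seed,
                   true_coverage = scn$true_coverage),
        file.path(out, "scenes.csv"), row.names = FALSE)
      list(corpus = corp_dir, images = img_dir, masks = mask_dir,
           scenes = file.path(out, "scenes.csv"))
    },
    tile = {
      plan <- plan_tiles(config$scene_height, config$scene_width,
                         config$tile_size, config$overlap_fraction)
      p <- file.path(out, "tile_plan.csv")
      write_tile_plan(plan, p)
      list(tile_plan = p)
    },
    split = {
      cd <- config_dataset(config)
      p <- file.path(out, "split_manifest.csv")
      write_manifest(cd$dataset, cd$split, p)
      tab <- table(cd$dataset$meta$label,
                   ifelse(cd$dataset$meta$tile_id %in% cd$split$train_ids,
                          "train", "val"))
      message("split class counts:\n",
              paste(utils::capture.output(print(tab)), collapse = "\n"))
      list(manifest = p)
    },
    train = {
      cd <- config_dataset(config)
      model <- build_model(config_model_spec(config))
      model <- train_model(model, cd$dataset, cd$split,
                           epochs = config$epochs,
                           learning_rate = config$learning_rate,
                           batch_size = config$batch_size,
                           seed = config$seed)
      hp <- file.path(out, "history.csv")
      write_history(model$history, hp)
      cp <- file.path(out, "checkpoint.json")
      write_checkpoint(model, cp)
      list(history = hp, checkpoint = cp)
    },
    eval = {
      cp <- file.path(config$input_dir, "checkpoint.json")
      if (!file.exists(cp)) stop("missing checkpoint: ", cp)
      model <- read_checkpoint(cp)
      cd <- config_dataset(config)
      val <- subset_tiles(cd$dataset, cd$split$val_ids)
      pred <- predict(model, val, type = "class")
      cm <- confusion_counts(val$meta$label, pred)
      mp <- file.path(out, "metrics.json")
      write_metrics(cm, mp)
      print(cm)
      list(metrics = mp)
    },
    covermap = {
      cp <- file.path(config$input_dir, "checkpoint.json")
      if (!file.exists(cp)) stop("missing checkpoint: ", cp)
      model <- read_checkpoint(cp)
      scene_file <- file.path(config$input_dir, "scene.png")
      if (file.exists(scene_file)) {
        scene <- read_raster(scene_file)
        scene_id <- "scene.png"
      } else {
        scn <- compose_scene(scene_spec(config$scene_height,
                                        config$scene_width,
                                        config$target_coverage,
                                        config$n_patches,
                                        seed = config$seed))
        scene <- scn$image
        scene_id <- sprintf("synthetic-seed%d", config$seed)
      }
      cov <- coverage_map(model, scene, tile_size = config$tile_size,
                          overlap = config$overlap_fraction,
                          threshold = config$threshold)
      write_probability(cov$probability, file.path(out, "probability.tif"))
      write_raster(cov$mask, file.path(out, "mask.png"))
      cj <- file.path(out, "coverage.json")
      write_coverage(cov, cj, scene_id = scene_id,
                     risk_threshold = config$risk_threshold)
      print(risk_flag(cov, config$risk_threshold, scene_id))
      list(coverage = cj)
    },
    chem = {
      ex <- load_chem_table("extract")
      edx <- load_chem_table("edx")
      rng <- load_chem_table("ranges")
      utils::write.csv(ex, file.path(out, "extract_chemistry.csv"),
                       row.names = FALSE)
      utils::write.csv(edx, file.path(out, "edx_composition.csv"),
                       row.names = FALSE)
      utils::write.csv(rng, file.path(out, "printed_ranges.csv"),
                       row.names = FALSE)
      for (f in c("pH", "conductivity_mS_cm", "soluble_salts_g_L")) {
        r <- range_summary(ex, f)
        message(sprintf("%s: %.3g - %.3g", f, r["min"], r["max"]))
      }
      list(extract = file.path(out, "extract_chemistry.csv"),
           edx = file.path(out, "edx_composition.csv"),
           ranges = file.path(out, "printed_ranges.csv"))
    }
  )
  invisible(artifacts)
}
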