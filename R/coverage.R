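#' Reed coverage map of a full scene
#'
#' Applies the trained patch classifier across a scene: plans
#' fifty-percent-overlap tiles, predicts the reed probability of every tile,
#' averages the per-tile probabilities into a per-pixel field
#' ([stitch_probabilities()]), and thresholds it into a binary reed mask. The
#' coverage fraction is the mean of the mask. With `mode = "vote"` each
#' tile's probability is hardened to 0/1 before stitching (per-tile hard
#' votes) for comparison with the smoother probability averaging.
#'
#' @param model A trained `reed_cnn`.
#' @param scene Numeric array `H x W x C`, both dimensions at least the tile
#'   size.
#' @param tile_size Crop side in pixels (defaults to the model's tile size).
#' @param overlap Overlap fraction between adjacent crops.
#' @param threshold Probability threshold; a pixel is reed when its
#'   probability is `>= threshold` (ties count as reed).
#' @param mode `"mean"` (default) or `"vote"`.
#' @return Object of class `coverage_map`: list with `probability` (matrix in
#'   `[0,1]`), `mask` (binary matrix), `coverage_fraction`, `threshold`,
#'   `tile_size`.
#' @export
coverage_map <- function(model, scene, tile_size = model$spec$tile_size,
                         overlap = 0.5, threshold = 0.5,
                         mode = c("mean", "vote")) {
  stopifnot(inherits(model, "reed_cnn"))
  mode <- match.arg(mode)
  if (length(dim(scene)) == 2L) scene <- promote_channels(scene)
  d <- dim(scene)
  if (d[1L] < tile_size || d[2L] < tile_size)
    stop("scene (", d[1L], "x", d[2L], ") is smaller than the tile; ",
         "minimum scene size is ", tile_size, "x", tile_size)
  plan <- plan_tiles(d[1L], d[2L], tile_size, overlap)
  tiles <- extract_tiles(scene, plan)
  probs <- predict_proba(model, tiles)[, "reed"]
  if (mode == "vote") probs <- as.numeric(probs >= 0.5)
  field <- stitch_probabilities(plan, probs)
  mask <- matrix(as.integer(field >= threshold), d[1L], d[2L])
  structure(list(probability = field, mask = mask,
                 coverage_fraction = mean(mask), threshold = threshold,
                 tile_size = as.integer(tile_size), mode = mode),
            class = "coverage_map")
}

#' @export
print.coverage_map <- function(x, ...) {
  cat(sprintf(
    "Coverage map %dx%d px: reed coverage fraction %.4f (threshold %.2f, tile %d px, %s mode)\n",
    nrow(x$mask), ncol(x$mask), x$coverage_fraction, x$threshold,
    x$tile_size, x$mode))
  invisible(x)
}

#' Flag a scene whose reed coverage reaches a risk threshold
#'
#' A heuristic screen for areas where dense reed expansion may threaten
#' open-water biodiversity: the scene is flagged when its coverage fraction
#' is greater than or equal to `risk_threshold`. No field-validated numeric
#' rule exists for "at risk"; the default 0.6 is an explicit placeholder and
#' should be calibrated per monitoring programme.
#'
#' @param cov A `coverage_map`.
#' @param risk_threshold Coverage fraction in `[0, 1]` at or above which the
#'   scene is flagged.
#' @param scene_id Optional identifier echoed into the report.
#' @return Object of class `risk_report`: list with `flagged`,
#'   `coverage_fraction`, `risk_threshold`, `scene_id`.
#' @export
risk_flag <- function(cov, risk_threshold = 0.6, scene_id = NULL) {
  stopifnot(inherits(cov, "coverage_map"),
            risk_threshold >= 0, risk_threshold <= 1)
  structure(list(flagged = cov$coverage_fraction >= risk_threshold,
                 coverage_fraction = cov$coverage_fraction,
                 risk_threshold = risk_threshold,
                 scene_id = scene_id),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  cat(sprintf("Scene %s: coverage %.4f %s risk threshold %.2f -> %s\n",
              if (is.null(x$scene_id)) "(unnamed)" else x$scene_id,
              x$coverage_fraction,
              if (x$flagged) ">=" else "<", x$risk_threshold,
              if (x$flagged) "FLAGGED" else "not flagged"))
  invisible(x)
}

#' Write a coverage report as JSON
#'
#' @param cov A `coverage_map`.
#' @param path Output JSON path.
#' @param scene_id Optional scene identifier.
#' @param risk_threshold Risk threshold used for the `flagged` field.
#' @return `path`, invisibly.
#' @export
write_coverage <- function(cov, path, scene_id = NULL,
                           risk_threshold = 0.6) {
  rep <- risk_flag(cov, risk_threshold, scene_id)
  jsonlite::write_json(
    list(scene = if (is.null(scene_id)) NA else scene_id,
         coverage_fraction = cov$coverage_fraction,
         threshold = cov$threshold,
         risk_threshold = risk_threshold,
         flagged = rep$flagged),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
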