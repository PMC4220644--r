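#' Default analysis configuration
#'
#' Returns the full nested configuration used by [analyze_image()] and
#' [run_study()], with one block per pipeline stage. Every default is
#' explicit so that a saved configuration file fully determines a run.
#'
#' @details Blocks and defaults:
#' \describe{
#'   \item{segmentation}{`threshold_method` ("otsu" or "manual"),
#'     `manual_threshold` (0--255, used only in manual mode), `polarity`
#'     ("dark_foreground": stained connective tissue is dark in the red
#'     channel), `min_area` (px, components below are dropped; default 20),
#'     `max_area` (px, `Inf` = unbounded), `min_circularity`/`max_circularity`
#'     (0--1 bounds on 4*pi*area/perimeter^2; defaults pass everything),
#'     `connectivity` (4 or 8).}
#'   \item{morisita}{`grid_rows`, `grid_cols`; `NULL` selects the default
#'     12-quadrat grid (3 x 4 for landscape images, 4 x 3 for portrait).}
#'   \item{glcm}{`distance` (px), `angle` (degrees, one of 0/45/90/135),
#'     `levels`, `symmetric`, `log_base` (entropy log base; `NULL` = natural
#'     log), `use_mask` (restrict co-occurrence pairs to the segmented
#'     foreground; default FALSE, full image).}
#'   \item{fractal}{`sizes` (box side lengths in px; `NULL` = powers of two
#'     from 2 to a quarter of the smaller image dimension), `n_origins`,
#'     `seed` (grid-origin jitter), `lacunarity_mode` ("cv" or "cv_squared"),
#'     `use_skeleton` (estimate fractal parameters on the skeleton, default
#'     TRUE).}
#'   \item{stats}{`alpha`, `n_mc` (Monte-Carlo draws for the Dunnett
#'     adjustment), `seed`, `roc_direction` (named per-feature overrides,
#'     "greater_is_positive" or "lesser_is_positive").}
#' }
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    segmentation = list(
      threshold_method = "otsu",
      manual_threshold = 128L,
      polarity = "dark_foreground",
      min_area = 20,
      max_area = Inf,
      min_circularity = 0,
      max_circularity = 1,
      connectivity = 8L
    ),
    morisita = list(grid_rows = NULL, grid_cols = NULL),
    glcm = list(
      distance = 1L,
      angle = 0L,
      levels = 256L,
      symmetric = FALSE,
      log_base = NULL,
      use_mask = FALSE
    ),
    fractal = list(
      sizes = NULL,
      n_origins = 10L,
      seed = 1L,
      lacunarity_mode = "cv",
      use_skeleton = TRUE
    ),
    stats = list(
      alpha = 0.05,
      n_mc = 100000L,
      seed = 1L,
      roc_direction = list()
    )
  )
}

#' Read a YAML configuration file
#'
#' Values in the file override the corresponding entries of
#' [default_config()]; unknown keys are rejected.
#'
#' @param path YAML file with any subset of the configuration blocks.
#' @return Full configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  bad <- setdiff(names(user), names(base))
  if (length(bad))
    stop("unknown configuration block(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (blk in names(user)) {
    bad <- setdiff(names(user[[blk]]), names(base[[blk]]))
    if (length(bad))
      stop("unknown key(s) in [", blk, "]: ", paste(bad, collapse = ", "),
           call. = FALSE)
    base[[blk]][names(user[[blk]])] <- user[[blk]]
  }
  base
}

#' Digest of a configuration
#'
#' Deterministic 64-bit polynomial hash of the YAML serialization, used to
#' stamp every feature record with the exact parameter set that produced it.
#'
#' @param config Configuration list.
#' @return 16-character hexadecimal string.
#' @export
config_hash <- function(config) {
  s <- yaml::as.yaml(config)
  b <- utf8ToInt(s)
  m1 <- 2147483647; m2 <- 2147483629
  h1 <- 17; h2 <- 19
  for (x in b) {                       # h * 31 + x stays below 2^53: exact
    h1 <- (h1 * 31 + x) %% m1
    h2 <- (h2 * 37 + x) %% m2
  }
  sprintf("%08x%08x", h1, h2)
}
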