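#' Extract the red component of an RGB image
#'
#' In blue-trichrome-stained sections the red channel shows the strongest
#' contrast between connective tissue (dark) and parenchyma (bright), so all
#' gray-level analysis starts from it.
#'
#' @param rgb Integer array `[height, width, 3]` with 8-bit values.
#' @return Integer matrix (gray image, 0--255).
#' @export
extract_red_channel <- function(rgb) {
  assert_rgb_image(rgb)
  matrix(as.integer(rgb[, , 1]), dim(rgb)[1], dim(rgb)[2])
}

#' Segmentation configuration
#'
#' Validated stand-alone constructor for the `[segmentation]` block of
#' [default_config()]; see that help page for the meaning of each field.
#'
#' @param threshold_method "otsu" or "manual".
#' @param manual_threshold Intensity cut point for manual mode.
#' @param polarity "dark_foreground" or "bright_foreground".
#' @param min_area,max_area Component area bounds in pixels.
#' @param min_circularity,max_circularity Bounds on 4*pi*area/perimeter^2.
#' @param connectivity 4 or 8.
#' @return Named list.
#' @export
segmentation_config <- function(threshold_method = c("otsu", "manual"),
                                manual_threshold = 128L,
                                polarity = c("dark_foreground", "bright_foreground"),
                                min_area = 20, max_area = Inf,
                                min_circularity = 0, max_circularity = 1,
                                connectivity = 8L) {
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  if (min_area > max_area) stop("min_area must be <= max_area", call. = FALSE)
  if (min_circularity < 0 || max_circularity > 1 || min_circularity > max_circularity)
    stop("circularity bounds must satisfy 0 <= min <= max <= 1", call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8", call. = FALSE)
  list(threshold_method = threshold_method, manual_threshold = manual_threshold,
       polarity = polarity, min_area = min_area, max_area = max_area,
       min_circularity = min_circularity, max_circularity = max_circularity,
       connectivity = as.integer(connectivity))
}

#' Otsu's threshold of a gray image
#'
#' Exhaustively evaluates every cut point `t`, splitting intensities into
#' classes `<= t` and `> t`, and returns the `t` maximizing the
#' between-class variance (ties broken toward the smallest `t`).
#'
#' @param gray Integer matrix with values in `[0, levels - 1]`.
#' @param levels Number of gray levels.
#' @return Integer threshold `t` in `[0, levels - 2]`.
#' @export
otsu_threshold <- function(gray, levels = 256L) {
  assert_gray_image(gray, levels)
  if (length(unique(as.vector(gray))) < 2)
    stop("degenerate image: Otsu thresholding needs >= 2 distinct intensities",
         call. = FALSE)
  h <- tabulate(as.vector(gray) + 1L, nbins = levels)
  p <- h / sum(h)
  g <- seq_len(levels) - 1
  w0 <- cumsum(p)                  # weight of class <= t
  m0 <- cumsum(p * g)              # unnormalized class mean
  mt <- m0[levels]
  t_all <- seq_len(levels - 1)     # cut after level t - 1
  w0t <- w0[t_all]; m0t <- m0[t_all]
  valid <- w0t > 0 & w0t < 1
  sb2 <- rep(-Inf, levels - 1)
  sb2[valid] <- (mt * w0t[valid] - m0t[valid])^2 / (w0t[valid] * (1 - w0t[valid]))
  as.integer(which.max(sb2) - 1L)
}

#' Threshold a gray image into a binary pattern
#'
#' With `dark_foreground` polarity, pixels at or below the threshold become
#' foreground (stained connective tissue is dark in the red channel); with
#' `bright_foreground`, pixels strictly above it do.
#'
#' @param gray Integer matrix (gray image).
#' @param config A [segmentation_config()] (or the `segmentation` block of a
#'   full configuration).
#' @return Logical matrix.
#' @export
threshold_image <- function(gray, config = segmentation_config()) {
  assert_gray_image(gray)
  t <- if (config$threshold_method == "otsu") otsu_threshold(gray)
       else as.numeric(config$manual_threshold)
  if (config$polarity == "dark_foreground") gray <= t else gray > t
}

# Per-component Cauchy-Crofton perimeter estimate from foreground/background
# transition counts along the 4 principal scan directions. Transitions
# against the image border count: a component touching the edge still has a
# boundary there. Returns a vector indexed by component label.
crofton_perimeter <- function(labels) {
  n <- max(labels)
  if (n == 0) return(numeric(0))
  counts <- matrix(0, n, 4)
  tally <- function(a, b, dir) {
    # a, b: label matrices of adjacent pixel pairs along one direction
    diff <- a != b
    for (lab in list(a, b)) {
      v <- lab[diff & lab > 0]
      if (length(v)) {
        t <- tabulate(v, nbins = n)
        counts[, dir] <<- counts[, dir] + t
      }
    }
  }
  nr <- nrow(labels); nc <- ncol(labels)
  z_col <- matrix(0L, nr, 1); z_row <- matrix(0L, 1, nc)
  lr <- cbind(z_col, labels); rr <- cbind(labels, z_col)
  tally(lr, rr, 1)                                   # horizontal runs
  tb <- rbind(z_row, labels); bb <- rbind(labels, z_row)
  tally(tb, bb, 2)                                   # vertical runs
  pd <- function(m, dr, dc) {                        # shifted with 0 padding
    out <- matrix(0L, nr + 2, nc + 2)
    out[seq_len(nr) + 1 + dr, seq_len(nc) + 1 + dc] <- m
    out
  }
  tally(pd(labels, 0, 0), pd(labels, 1, 1), 3)       # 135-degree lines
  tally(pd(labels, 0, 1), pd(labels, 1, 0), 4)       # 45-degree lines
  (pi / 8) * (counts[, 1] + counts[, 2] + (counts[, 3] + counts[, 4]) / sqrt(2))
}

#' Geometric filtering of connected components
#'
#' Labels foreground components at the configured connectivity and removes
#' those whose area lies outside `[min_area, max_area]` or whose circularity
#' (`4*pi*area/perimeter^2`, Cauchy-Crofton perimeter, capped at 1) lies
#' outside `[min_circularity, max_circularity]`. Surviving pixels are
#' unchanged, so the filter is idempotent and never adds pixels.
#'
#' @param pattern Logical matrix.
#' @param config A [segmentation_config()].
#' @return Logical matrix.
#' @export
geometric_filter <- function(pattern, config = segmentation_config()) {
  assert_binary_pattern(pattern)
  if (!any(pattern)) return(pattern)
  labels <- .cc_label(pattern, config$connectivity)
  n <- max(labels)
  area <- tabulate(labels[labels > 0], nbins = n)
  circ <- pmin(1, 4 * pi * area / crofton_perimeter(labels)^2)
  keep <- area >= config$min_area & area <= config$max_area &
    circ >= config$min_circularity & circ <= config$max_circularity
  out <- pattern
  out[labels > 0 & !keep[pmax(labels, 1)]] <- FALSE
  out
}

#' Area fraction of a binary pattern
#'
#' @param pattern Logical matrix.
#' @return Foreground pixel count divided by total pixel count.
#' @export
area_fraction <- function(pattern) {
  assert_binary_pattern(pattern)
  if (length(pattern) == 0) stop("zero-size image", call. = FALSE)
  mean(pattern)
}

#' Topology-preserving skeletonization
#'
#' Iterative Zhang-Suen-style thinning to a 1-pixel-wide skeleton, applied
#' sequentially within each sub-iteration so that every deleted pixel is
#' individually removable; this preserves the number of connected components
#' and makes the operation idempotent. The skeleton is a subset of the input
#' foreground.
#'
#' @param pattern Logical matrix.
#' @return Logical matrix (the skeleton).
#' @export
skeletonize <- function(pattern) {
  assert_binary_pattern(pattern)
  .thin_pattern(pattern)
}
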