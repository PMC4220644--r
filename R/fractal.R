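default_box_sizes <- function(pattern) {
  m <- min(dim(pattern))
  top <- m %/% 4
  if (top < 2) stop("image too small for the default box-size ladder", call. = FALSE)
  2^(1:floor(log2(top)))
}

# origin (0,0) first, then n - 1 uniform offsets modulo the smallest size
make_origins <- function(sizes, n_origins, seed) {
  smin <- min(sizes)
  org <- matrix(0L, n_origins, 2)
  if (n_origins > 1) {
    org[-1, ] <- withr::with_seed(as.integer(seed), {
      cbind(sample.int(smin, n_origins - 1, replace = TRUE) - 1L,
            sample.int(smin, n_origins - 1, replace = TRUE) - 1L)
    })
  }
  org
}

#' Count occupied boxes of a square grid over a binary pattern
#'
#' The grid of `size x size` boxes tiles the plane starting from `origin`
#' (row/column offsets in `[0, size)`), so every pixel belongs to exactly
#' one box; boxes partially outside the image still count if they contain a
#' foreground pixel.
#'
#' @param pattern Logical matrix.
#' @param size Box side length in pixels.
#' @param origin Integer vector `c(row_offset, col_offset)`, offsets in
#'   `[0, size)`.
#' @return Number of boxes containing at least one foreground pixel.
#' @export
box_counts <- function(pattern, size, origin = c(0L, 0L)) {
  assert_binary_pattern(pattern)
  if (size < 1 || size > max(dim(pattern)))
    stop("size must be in [1, max(image dims)]", call. = FALSE)
  if (any(origin < 0) || any(origin >= size))
    stop("origin offsets must lie in [0, size)", call. = FALSE)
  idx <- which(pattern) - 1L
  if (!length(idx)) return(0L)
  r <- idx %% nrow(pattern)
  c <- idx %/% nrow(pattern)
  br <- floor((r - origin[1]) / size)      # -1 for pixels left of the origin
  bc <- floor((c - origin[2]) / size)
  length(unique((br + 1) * 1e6 + bc))
}

#' Multi-origin box-counting fractal dimension
#'
#' For each grid origin, the number of occupied boxes is counted at every
#' box size, and `D` is estimated as -1 times the slope of the ordinary
#' least-squares regression of log(count) on log(size); sizes with zero
#' count are dropped. The first origin is always `(0, 0)`; the remaining
#' `n_origins - 1` are drawn uniformly from offsets below the smallest box
#' size using `seed`, and the final estimate is the mean of the per-origin
#' `D` values, which suppresses grid-placement effects.
#'
#' @param pattern Logical matrix with at least 2 foreground pixels.
#' @param sizes Strictly increasing box sides (px); `NULL` = powers of two
#'   from 2 to a quarter of the smaller image dimension.
#' @param n_origins Number of grid origins (>= 1).
#' @param seed Seed for the random origins.
#' @return Object of class `fractal_result`: `mean_D`, `per_origin_D`,
#'   `origins`, `sizes`, `per_origin_counts` (sizes x origins matrix) and
#'   `regression_points` (data.frame: origin, log_size, log_count).
#' @export
fractal_dimension <- function(pattern, sizes = NULL, n_origins = 10L, seed = 1L) {
  assert_binary_pattern(pattern)
  if (sum(pattern) < 2)
    stop("fractal dimension needs >= 2 foreground pixels", call. = FALSE)
  if (is.null(sizes)) sizes <- default_box_sizes(pattern)
  sizes <- as.integer(sizes)
  if (length(sizes) < 2 || any(diff(sizes) <= 0))
    stop("sizes must be >= 2 strictly increasing values", call. = FALSE)
  if (n_origins < 1) stop("n_origins must be >= 1", call. = FALSE)

  org <- make_origins(sizes, n_origins, seed)
  counts <- matrix(NA_real_, length(sizes), n_origins,
                   dimnames = list(sizes, NULL))
  per_D <- numeric(n_origins)
  reg <- vector("list", n_origins)
  for (o in seq_len(n_origins)) {
    counts[, o] <- vapply(sizes, function(s) {
      box_counts(pattern, s, org[o, ] %% s)
    }, numeric(1))
    use <- counts[, o] > 0
    if (sum(use) < 2)
      stop("regression degenerate: fewer than 2 box sizes with nonzero counts",
           call. = FALSE)
    x <- log(sizes[use]); y <- log(counts[use, o])
    per_D[o] <- -coef(lm(y ~ x))[[2]]
    reg[[o]] <- data.frame(origin = o, log_size = x, log_count = y)
  }
  structure(
    list(mean_D = mean(per_D), per_origin_D = per_D, origins = org,
         sizes = sizes, per_origin_counts = counts,
         regression_points = do.call(rbind, reg)),
    class = "fractal_result"
  )
}

#' @export
print.fractal_result <- function(x, ...) {
  cat(sprintf("Box-counting dimension: D = %.4f (mean of %d origins, sizes %s)\n",
              x$mean_D, length(x$per_origin_D),
              paste(x$sizes, collapse = ", ")))
  invisible(x)
}

#' Lacunarity as the mean coefficient of variation of box masses
#'
#' For every (box size, grid origin) combination, the foreground-pixel count
#' ("mass") of every grid box lying fully inside the image -- including
#' empty boxes -- is collected, and the population coefficient of variation
#' sigma/mu of those masses is computed (`cv_squared` returns `(sigma/mu)^2`
#' instead, the convention of some box-counting tools). The returned value
#' is the average over all sizes and origins. Low lacunarity means the
#' pattern fills space uniformly at all scales.
#'
#' Origins are generated exactly as in [fractal_dimension()], so the same
#' `sizes`, `n_origins` and `seed` analyse both parameters on identical
#' grids.
#'
#' @inheritParams fractal_dimension
#' @param mode `"cv"` or `"cv_squared"`.
#' @return Numeric scalar.
#' @export
lacunarity <- function(pattern, sizes = NULL, n_origins = 10L, seed = 1L,
                       mode = c("cv", "cv_squared")) {
  assert_binary_pattern(pattern)
  mode <- match.arg(mode)
  if (sum(pattern) < 1)
    stop("empty pattern: lacunarity undefined", call. = FALSE)
  if (is.null(sizes)) sizes <- default_box_sizes(pattern)
  sizes <- as.integer(sizes)
  org <- make_origins(sizes, n_origins, seed)
  nr <- nrow(pattern); nc <- ncol(pattern)
  idx <- which(pattern) - 1L
  pr <- idx %% nr
  pc <- idx %/% nr

  cvs <- numeric(0)
  for (o in seq_len(nrow(org))) {
    for (s in sizes) {
      orr <- org[o, 1] %% s; occ <- org[o, 2] %% s
      nbr <- (nr - orr) %/% s           # boxes fully inside, row direction
      nbc <- (nc - occ) %/% s
      if (nbr < 1 || nbc < 1) next
      br <- (pr - orr) %/% s
      bc <- (pc - occ) %/% s
      inside <- pr >= orr & pc >= occ & br < nbr & bc < nbc
      masses <- tabulate(br[inside] * nbc + bc[inside] + 1L, nbins = nbr * nbc)
      mu <- mean(masses)
      if (mu == 0) next                 # all foreground in clipped boxes
      sigma <- sqrt(mean((masses - mu)^2))   # population SD
      cvs <- c(cvs, if (mode == "cv") sigma / mu else (sigma / mu)^2)
    }
  }
  if (!length(cvs))
    stop("no fully interior boxes contained foreground at any size",
         call. = FALSE)
  mean(cvs)
}
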