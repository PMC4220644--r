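#' Morisita's index of dispersion over a quadrat grid
#'
#' Divides the binary pattern into `grid_rows x grid_cols` equal-area
#' sub-images (quadrats), counts the foreground pixels `X_i` in each, and
#' computes
#' \deqn{I_d = n \frac{\sum_i X_i^2 - N}{N (N - 1)}}
#' with `n` the number of quadrats and `N` the total foreground count.
#' `I_d` is about 1 for complete spatial randomness, rises toward `n` as the
#' pattern aggregates into fewer quadrats, and falls to `(N - n)/(N - 1)`
#' for a perfectly even split. (Despite the historical name "index of
#' dispersal", larger values mean more aggregation, not more dispersion.)
#'
#' The image is cropped at the bottom/right edges to dimensions divisible by
#' the grid before counting, so all quadrats have equal area as the formula
#' assumes.
#'
#' @param pattern Logical matrix with at least 2 foreground pixels after
#'   cropping.
#' @param grid_rows,grid_cols Quadrat grid; `NULL` selects 12 quadrats
#'   (3 x 4 for landscape images, 4 x 3 for portrait).
#' @return Object of class `morisita_result`: `index_value`, `n_subimages`,
#'   `total_pixels`, `per_cell_counts` (row-major quadrat order),
#'   `grid_rows`, `grid_cols`.
#' @export
morisita_index <- function(pattern, grid_rows = NULL, grid_cols = NULL) {
  assert_binary_pattern(pattern)
  h <- nrow(pattern); w <- ncol(pattern)
  if (is.null(grid_rows)) grid_rows <- if (w >= h) 3L else 4L
  if (is.null(grid_cols)) grid_cols <- if (w >= h) 4L else 3L
  n <- grid_rows * grid_cols
  if (n < 2) stop("grid must have at least 2 quadrats", call. = FALSE)
  if (grid_rows > h || grid_cols > w)
    stop("grid larger than image", call. = FALSE)

  ch <- h %/% grid_rows
  cw <- w %/% grid_cols
  crop <- pattern[seq_len(grid_rows * ch), seq_len(grid_cols * cw), drop = FALSE]
  N <- sum(crop)
  if (N < 2)
    stop("insufficient foreground: Morisita's index needs N >= 2 pixels",
         call. = FALSE)
  cell_r <- (row(crop) - 1L) %/% ch          # 0-based quadrat coordinates
  cell_c <- (col(crop) - 1L) %/% cw
  cell_id <- cell_r * grid_cols + cell_c + 1L  # row-major order
  counts <- as.integer(tabulate(cell_id[crop], nbins = n))
  id <- n * (sum(as.numeric(counts)^2) - N) / (N * (N - 1))
  structure(
    list(index_value = id, n_subimages = n, total_pixels = N,
         per_cell_counts = counts, grid_rows = grid_rows,
         grid_cols = grid_cols),
    class = "morisita_result"
  )
}

#' @export
print.morisita_result <- function(x, ...) {
  cat(sprintf("Morisita's index: %.4f  (%d x %d quadrats, N = %d pixels)\n",
              x$index_value, x$grid_rows, x$grid_cols, x$total_pixels))
  invisible(x)
}
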