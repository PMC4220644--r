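glcm_offset <- function(distance, angle) {
  # row index grows downwards; angles follow the usual GLCM convention
  switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance),
    stop("angle must be one of 0, 45, 90, 135", call. = FALSE)
  )
}

#' Gray-level co-occurrence matrix
#'
#' Joint frequency `P(i, j)` of gray levels `i` (reference pixel) and `j`
#' (pixel at the offset implied by `distance` and `angle`), normalized to
#' sum 1. Angle 0 means horizontally rightwards; rows grow downwards, so
#' angle 90 pairs a pixel with the one `distance` rows above it. With
#' `symmetric = TRUE` each pair is also counted reversed.
#'
#' @param gray Integer matrix with values in `[0, levels - 1]`.
#' @param distance Offset length in pixels.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param levels Number of gray levels (matrix dimension).
#' @param symmetric Count each pair in both orders.
#' @param mask Optional logical matrix; when given, only pairs with both
#'   pixels inside the mask are counted.
#' @return Object of class `glcm`: `P` (levels x levels matrix), `levels`,
#'   `distance`, `angle`, `symmetric`.
#' @export
compute_glcm <- function(gray, distance = 1L, angle = 0L, levels = 256L,
                         symmetric = FALSE, mask = NULL) {
  assert_gray_image(gray, levels)
  if (distance < 1) stop("distance must be >= 1", call. = FALSE)
  d <- glcm_offset(as.integer(distance), angle)
  nr <- nrow(gray); nc <- ncol(gray)
  r0 <- seq_len(nr); c0 <- seq_len(nc)
  rs <- r0[r0 + d[1] >= 1 & r0 + d[1] <= nr]
  cs <- c0[c0 + d[2] >= 1 & c0 + d[2] <= nc]
  if (!length(rs) || !length(cs))
    stop("degenerate image: no pixel pairs at the requested offset",
         call. = FALSE)
  i <- gray[rs, cs, drop = FALSE]
  j <- gray[rs + d[1], cs + d[2], drop = FALSE]
  if (!is.null(mask)) {
    assert_binary_pattern(mask, "mask")
    ok <- mask[rs, cs, drop = FALSE] & mask[rs + d[1], cs + d[2], drop = FALSE]
    i <- i[ok]; j <- j[ok]
    if (!length(i))
      stop("degenerate mask: no pixel pairs at the requested offset",
           call. = FALSE)
  }
  counts <- tabulate(as.vector(i) * levels + as.vector(j) + 1L,
                     nbins = levels * levels)
  P <- matrix(counts, levels, levels, byrow = TRUE)  # row = i, col = j
  if (symmetric) P <- P + t(P)
  structure(
    list(P = P / sum(P), levels = levels, distance = as.integer(distance),
         angle = as.integer(angle), symmetric = isTRUE(symmetric)),
    class = "glcm"
  )
}

#' Haralick texture features of a co-occurrence matrix
#'
#' The four features most used in clinical texture work:
#' \itemize{
#'   \item entropy `-sum P log P` (0 log 0 := 0); natural log by default.
#'   \item angular second moment (ASM) `sum P^2`; high for homogeneous
#'     textures.
#'   \item variance `sum (i - mu)^2 P(i, j)` with `mu` the reference-pixel
#'     (row-marginal) mean gray level.
#'   \item correlation `(sum i j P(i, j) - mu_x mu_y) / (sigma_x sigma_y)`
#'     with means/SDs of the row and column marginal distributions; defined
#'     as 0 when either marginal SD is 0.
#' }
#'
#' @param glcm A [compute_glcm()] result (or any normalized matrix wrapped
#'   the same way).
#' @param log_base Base for the entropy logarithm; `NULL` = natural log.
#' @return Object of class `texture_features`: `entropy`, `asm`, `variance`,
#'   `correlation`.
#' @export
texture_features <- function(glcm, log_base = NULL) {
  P <- glcm$P
  if (!is.matrix(P) || any(P < 0) || abs(sum(P) - 1) > 1e-9)
    stop("glcm$P must be a normalized co-occurrence matrix", call. = FALSE)
  g <- seq_len(nrow(P)) - 1                       # gray values
  pos <- P > 0
  entropy <- -sum(P[pos] * log(P[pos]))
  if (!is.null(log_base)) entropy <- entropy / log(log_base)
  asm <- sum(P^2)
  px <- rowSums(P); py <- colSums(P)              # marginals (i then j)
  mux <- sum(g * px); muy <- sum(g * py)
  sdx <- sqrt(sum((g - mux)^2 * px))
  sdy <- sqrt(sum((g - muy)^2 * py))
  variance <- sum((g - mux)^2 * px)               # == sum_ij (i - mu)^2 P(i,j)
  correlation <- if (sdx * sdy > 0) {
    (sum(outer(g, g) * P) - mux * muy) / (sdx * sdy)
  } else 0
  structure(
    list(entropy = entropy, asm = asm, variance = variance,
         correlation = correlation),
    class = "texture_features"
  )
}

#' @export
print.texture_features <- function(x, ...) {
  cat(sprintf("GLCM features: entropy %.4f  ASM %.4g  variance %.4g  correlation %.4g\n",
              x$entropy, x$asm, x$variance, x$correlation))
  invisible(x)
}
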