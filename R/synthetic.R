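#' Filled rectangle fixture
#'
#' All-foreground binary pattern; a filled plane region has box-counting
#' dimension 2 and a 1-pixel line dimension 1, which makes these patterns
#' exact fixtures for the fractal estimator.
#'
#' @param width,height Size in pixels (>= 1).
#' @return Logical matrix `height x width`, all `TRUE`.
#' @export
make_filled_rect <- function(width, height) {
  if (width < 1 || height < 1) stop("width and height must be >= 1", call. = FALSE)
  matrix(TRUE, nrow = height, ncol = width)
}

#' Sierpinski carpet fixture
#'
#' Square pattern of side `3^order` built by recursively removing the central
#' ninth; foreground count is exactly `8^order` and the self-similarity
#' dimension is `log(8)/log(3) ~ 1.8928`.
#'
#' @param order Recursion depth, 1 to 7.
#' @return Logical matrix of side `3^order`.
#' @export
make_sierpinski_carpet <- function(order) {
  if (length(order) != 1 || order != floor(order) || order < 1 || order > 7)
    stop("order must be an integer in [1, 7]", call. = FALSE)
  m <- matrix(TRUE, 1, 1)
  for (k in seq_len(order)) {
    side <- nrow(m)
    out <- matrix(FALSE, 3 * side, 3 * side)
    for (br in 0:2) for (bc in 0:2) {
      if (br == 1 && bc == 1) next
      out[br * side + seq_len(side), bc * side + seq_len(side)] <- m
    }
    m <- out
  }
  m
}

#' Point-pattern fixtures with known dispersion behaviour
#'
#' Places exactly `n_points` foreground pixels. `uniform` draws pixel
#' positions independently (complete spatial randomness up to the pixel
#' grid; expected Morisita index ~ 1), `clustered` draws them around
#' `n_clusters` Gaussian centres (index > 1), and `single_cell` confines all
#' points to one quadrat of the default Morisita grid (index = number of
#' quadrats, the maximally clumped extreme).
#'
#' @param n_points Number of foreground pixels.
#' @param layout `"uniform"`, `"clustered"` or `"single_cell"`.
#' @param n_clusters Number of cluster centres (clustered layout).
#' @param cluster_sd Cluster standard deviation in pixels.
#' @param width,height Image size in pixels.
#' @param seed Integer seed; same seed and arguments give identical output.
#' @param grid_rows,grid_cols Quadrat grid used by the `single_cell` layout
#'   (defaults match [morisita_index()]'s default 12-quadrat grid).
#' @return Logical matrix with exactly `n_points` `TRUE` pixels.
#' @export
make_point_pattern <- function(n_points, layout = c("uniform", "clustered", "single_cell"),
                               n_clusters = 3L, cluster_sd = 5, width = 120L,
                               height = 90L, seed = 1L,
                               grid_rows = NULL, grid_cols = NULL) {
  layout <- match.arg(layout)
  if (n_points < 1) stop("n_points must be >= 1", call. = FALSE)
  if (layout == "clustered" && n_clusters < 1)
    stop("clustered layout requires n_clusters >= 1", call. = FALSE)
  if (is.null(grid_rows)) grid_rows <- if (width >= height) 3L else 4L
  if (is.null(grid_cols)) grid_cols <- if (width >= height) 4L else 3L

  withr::with_seed(seed, {
    pat <- matrix(FALSE, height, width)
    if (layout == "single_cell") {
      ch <- height %/% grid_rows
      cw <- width %/% grid_cols
      if (n_points > ch * cw)
        stop("n_points exceeds the capacity of one quadrat (",
             ch * cw, " px)", call. = FALSE)
      cr <- sample.int(grid_rows, 1) - 1L
      cc <- sample.int(grid_cols, 1) - 1L
      cell_idx <- sample.int(ch * cw, n_points)
      r <- cr * ch + (cell_idx - 1L) %% ch + 1L
      c <- cc * cw + (cell_idx - 1L) %/% ch + 1L
      pat[cbind(r, c)] <- TRUE
    } else {
      if (n_points > width * height)
        stop("n_points exceeds image capacity", call. = FALSE)
      if (layout == "clustered") {
        centres <- cbind(runif(n_clusters, 1, height), runif(n_clusters, 1, width))
      }
      placed <- 0L
      while (placed < n_points) {
        if (layout == "uniform") {
          r <- sample.int(height, 1)
          c <- sample.int(width, 1)
        } else {
          k <- sample.int(n_clusters, 1)
          r <- round(rnorm(1, centres[k, 1], cluster_sd))
          c <- round(rnorm(1, centres[k, 2], cluster_sd))
          if (r < 1 || r > height || c < 1 || c > width) next
        }
        if (pat[r, c]) next          # collision: redraw
        pat[r, c] <- TRUE
        placed <- placed + 1L
      }
    }
    pat
  })
}

#' Specification of a synthetic lobular tissue image
#'
#' Parameters of the generative model behind [make_tissue_image()]: a field
#' of parenchyma lobules (Voronoi cells) separated by thick interlobular
#' connective septa, with thin intralobular connective branches growing
#' inward from the septa. Septum thickness controls the connective-tissue
#' area fraction almost independently of `branch_density`, which controls
#' branching complexity -- the pair of knobs needed to build cohorts with
#' matched connective amount but different spatial complexity.
#'
#' @param width,height Image size in pixels (>= 64).
#' @param n_lobules Number of Voronoi lobules (>= 2).
#' @param septum_thickness Septum width in pixels (>= 1; fractional values
#'   allowed, the septum is the band where the two nearest-site distances
#'   differ by at most this amount).
#' @param branch_density Expected number of branch initiations per lobule
#'   (Poisson mean, >= 0).
#' @param branch_length_mean Mean branch length in pixels.
#' @param branch_width Branch stroke width in pixels (>= 1).
#' @param stain_noise_sd Additive Gaussian intensity noise (8-bit units).
#' @param seed Integer seed; same spec and seed give bit-identical images.
#' @return Object of class `tissue_spec` (a validated named list).
#' @export
tissue_spec <- function(width = 192L, height = 192L, n_lobules = 7L,
                        septum_thickness = 6, branch_density = 4,
                        branch_length_mean = 15, branch_width = 1L,
                        stain_noise_sd = 8, seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               n_lobules = as.integer(n_lobules),
               septum_thickness = as.numeric(septum_thickness),
               branch_density = as.numeric(branch_density),
               branch_length_mean = as.numeric(branch_length_mean),
               branch_width = as.integer(branch_width),
               stain_noise_sd = as.numeric(stain_noise_sd),
               seed = as.integer(seed))
  validate_tissue_spec(spec)
  structure(spec, class = "tissue_spec")
}

validate_tissue_spec <- function(spec) {
  with(spec, {
    if (width < 64 || height < 64) stop("width and height must be >= 64", call. = FALSE)
    if (n_lobules < 2) stop("n_lobules must be >= 2", call. = FALSE)
    if (septum_thickness < 1) stop("septum_thickness must be >= 1", call. = FALSE)
    if (branch_density < 0) stop("branch_density must be >= 0", call. = FALSE)
    if (branch_length_mean < 1) stop("branch_length_mean must be >= 1", call. = FALSE)
    if (branch_width < 1) stop("branch_width must be >= 1", call. = FALSE)
    if (stain_noise_sd < 0) stop("stain_noise_sd must be >= 0", call. = FALSE)
  })
  invisible(spec)
}

# Voronoi-septa + biased-random-walk-branch construction of the ground-truth
# connective mask. Runs inside an established RNG state (callers seed it).
build_tissue_mask <- function(spec) {
  h <- spec$height; w <- spec$width; n <- spec$n_lobules

  # lobule sites: dart throwing with a minimum separation so lobule sizes
  # stay comparable; falls back to unconstrained placement if space is tight
  min_d2 <- 0.2 * (w * h / n)
  sites <- matrix(NA_real_, n, 2)
  placed <- 0L; tries <- 0L
  while (placed < n && tries < 3000L) {
    p <- c(runif(1, 1, h), runif(1, 1, w))
    tries <- tries + 1L
    if (placed > 0L) {
      d2 <- (sites[seq_len(placed), 1] - p[1])^2 + (sites[seq_len(placed), 2] - p[2])^2
      if (min(d2) < min_d2) next
    }
    placed <- placed + 1L
    sites[placed, ] <- p
  }
  while (placed < n) {
    placed <- placed + 1L
    sites[placed, ] <- c(runif(1, 1, h), runif(1, 1, w))
  }

  rr <- rep(seq_len(h), times = w)
  cc <- rep(seq_len(w), each = h)
  d1 <- rep(Inf, h * w); lab <- integer(h * w)
  for (k in seq_len(n)) {
    dk <- sqrt((rr - sites[k, 1])^2 + (cc - sites[k, 2])^2)
    upd <- dk < d1
    d1[upd] <- dk[upd]; lab[upd] <- k
  }
  d2 <- rep(Inf, h * w)
  for (k in seq_len(n)) {
    dk <- sqrt((rr - sites[k, 1])^2 + (cc - sites[k, 2])^2)
    sel <- lab != k & dk < d2
    d2[sel] <- dk[sel]
  }
  septa <- matrix(d2 - d1 <= spec$septum_thickness, h, w)

  if (spec$branch_density <= 0) return(septa)

  labm <- matrix(lab, h, w)
  # lobule pixels with a 4-neighbour inside a septum: branch anchor points
  pad <- function(m, dr, dc) {
    out <- matrix(FALSE, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  adj <- !septa & (pad(septa, 1, 0) | pad(septa, -1, 0) |
                   pad(septa, 0, 1) | pad(septa, 0, -1))

  branch <- matrix(FALSE, h, w)
  bw <- spec$branch_width
  off <- seq_len(bw) - 1L - (bw - 1L) %/% 2L   # stroke offsets
  dirs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  for (k in seq_len(n)) {
    nb <- rpois(1, spec$branch_density)
    if (nb == 0) next
    cand <- which(adj & labm == k)
    if (!length(cand)) next
    for (b in seq_len(nb)) {
      idx <- cand[sample.int(length(cand), 1)]
      r <- (idx - 1L) %% h + 1L
      c <- (idx - 1L) %/% h + 1L
      len <- max(3, round(rnorm(1, spec$branch_length_mean,
                                0.3 * spec$branch_length_mean)))
      for (s in seq_len(len)) {
        rs <- pmin(pmax(r + off, 1L), h)
        cs <- pmin(pmax(c + off, 1L), w)
        branch[rs, cs] <- TRUE
        if (runif(1) < 0.6) {       # inward bias toward the lobule site
          dr <- sign(sites[k, 1] - r); dc <- sign(sites[k, 2] - c)
          if (dr == 0 && dc == 0) break
        } else {
          d8 <- dirs[sample.int(8, 1), ]
          dr <- d8[1]; dc <- d8[2]
        }
        r <- r + dr; c <- c + dc
        if (r < 1 || r > h || c < 1 || c > w || septa[r, c]) break
      }
    }
  }
  septa | branch
}

#' Ground-truth connective mask of a synthetic tissue image
#'
#' The exact binary mask that [make_tissue_image()] renders for the same
#' spec and seed, without the rendering step (used heavily by
#' [calibrate_area_fraction()]).
#'
#' @param spec A [tissue_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return Logical matrix `height x width`.
#' @export
make_truth_mask <- function(spec, seed = spec$seed) {
  validate_tissue_spec(spec)
  withr::with_seed(as.integer(seed), build_tissue_mask(spec))
}

#' Render a synthetic histology-like tissue image
#'
#' Renders the Voronoi-septa + branch connective mask as an 8-bit RGB image
#' in which connective tissue is dark in the red channel (a blue trichrome
#' stain absorbs red light) and parenchyma is bright, plus additive Gaussian
#' stain noise. Deterministic in `(spec, spec$seed)`.
#'
#' @param spec A [tissue_spec()].
#' @return List with elements `image` (integer array `[h, w, 3]`, 0--255)
#'   and `truth` (list: `mask`, `area_fraction`, `spec`).
#' @export
make_tissue_image <- function(spec) {
  validate_tissue_spec(spec)
  conn <- c(60, 90, 150)    # dark red channel, bluish cast
  par_ <- c(200, 150, 160)  # bright pinkish parenchyma
  res <- withr::with_seed(spec$seed, {
    mask <- build_tissue_mask(spec)
    img <- array(0L, dim = c(spec$height, spec$width, 3))
    for (ch in 1:3) {
      v <- ifelse(mask, conn[ch], par_[ch])
      if (spec$stain_noise_sd > 0)
        v <- v + rnorm(length(v), 0, spec$stain_noise_sd)
      img[, , ch] <- as.integer(pmin(pmax(round(v), 0), 255))
    }
    list(image = img, mask = mask)
  })
  list(image = res$image,
       truth = list(mask = res$mask,
                    area_fraction = mean(res$mask),
                    spec = spec))
}

#' Calibrate a tissue spec to a target connective-tissue area fraction
#'
#' Adjusts `septum_thickness` by bisection (and, if the upper thickness
#' bound is still insufficient, widens `branch_width`) until the truth-mask
#' area fraction, averaged over `n_seeds` seeds, lies within `tolerance` of
#' `target_fraction`. Area fraction is monotone non-decreasing in both
#' knobs, so bisection converges.
#'
#' @param spec Starting [tissue_spec()].
#' @param target_fraction Target area fraction, in (0, 1).
#' @param tolerance Acceptable deviation of the seed-averaged fraction.
#' @param n_seeds Seeds averaged per evaluation (>= 10 recommended; the
#'   residual mean error scales as the per-image SD over `sqrt(n_seeds)`).
#' @param max_iter Bisection iteration cap.
#' @return Calibrated `tissue_spec`.
#' @export
calibrate_area_fraction <- function(spec, target_fraction, tolerance = 0.02,
                                    n_seeds = 10L, max_iter = 40L) {
  validate_tissue_spec(spec)
  fail <- function(msg, ...) {
    stop(errorCondition(paste0("area-fraction calibration failed: ", msg),
                        class = "morphotex_calibration_failure",
                        ...))
  }
  if (target_fraction <= 0 || target_fraction >= 1)
    fail(sprintf("target %.3f is outside the attainable range (0, 1)",
                 target_fraction))

  measure <- function(sp) {
    mean(vapply(seq_len(n_seeds) - 1L,
                function(i) mean(make_truth_mask(sp, sp$seed + i)),
                numeric(1)))
  }
  with_thickness <- function(sp, t) { sp$septum_thickness <- t; sp }

  t_lo <- 1
  t_hi <- min(spec$width, spec$height) / 3
  f_lo <- measure(with_thickness(spec, t_lo))
  if (f_lo > target_fraction + tolerance)
    fail(sprintf("septa alone give fraction %.3f at minimal thickness, above target %.3f",
                 f_lo, target_fraction),
         achievable_min = f_lo)
  f_hi <- measure(with_thickness(spec, t_hi))
  while (f_hi < target_fraction - tolerance && spec$branch_width < 8L) {
    spec$branch_width <- spec$branch_width + 1L
    f_hi <- measure(with_thickness(spec, t_hi))
  }
  if (f_hi < target_fraction - tolerance)
    fail(sprintf("fraction %.3f at maximal thickness remains below target %.3f",
                 f_hi, target_fraction),
         achievable_max = f_hi)

  f_mid <- NA_real_
  for (i in seq_len(max_iter)) {
    t_mid <- (t_lo + t_hi) / 2
    f_mid <- measure(with_thickness(spec, t_mid))
    if (abs(f_mid - target_fraction) <= tolerance / 2 || (t_hi - t_lo) < 1e-3)
      break
    if (f_mid < target_fraction) t_lo <- t_mid else t_hi <- t_mid
  }
  out <- with_thickness(spec, t_mid)
  f_final <- f_mid
  if (abs(f_final - target_fraction) > tolerance)
    fail(sprintf("bisection stalled at fraction %.3f for target %.3f",
                 f_final, target_fraction),
         achieved = f_final)
  out
}

#' Generate matched synthetic cohorts for a group-comparison study
#'
#' One image per subject, with per-image seeds derived deterministically
#' from `seed`. With `dir = NULL` the images stay in memory (a list column
#' in the manifest); otherwise RGB TIFFs, truth-mask PNGs, a truth CSV and a
#' manifest CSV are written to `dir`.
#'
#' @param specs Named list of [tissue_spec()] objects, one per group.
#' @param n_per_group Subjects (= images) per group.
#' @param seed Master seed for the per-image seed sequence.
#' @param dir Optional output directory.
#' @return List with `manifest` (data.frame: image, image_id, subject_id,
#'   group) and `truth` (data.frame with per-image true area fractions).
#' @export
simulate_cohorts <- function(specs, n_per_group = 20L, seed = 1L, dir = NULL) {
  if (is.null(names(specs)) || any(names(specs) == ""))
    stop("`specs` must be a named list (names are group labels)", call. = FALSE)
  rows <- list(); truth <- list(); images <- list()
  i <- 0L
  for (gi in seq_along(specs)) {
    g <- names(specs)[gi]
    for (s in seq_len(n_per_group)) {
      i <- i + 1L
      sp <- specs[[gi]]
      sp$seed <- as.integer(seed + gi * 100000L + s)
      gen <- make_tissue_image(sp)
      id <- sprintf("%s_%02d", g, s)
      images[[i]] <- gen$image
      rows[[i]] <- data.frame(image_id = id, subject_id = id, group = g,
                              stringsAsFactors = FALSE)
      truth[[i]] <- data.frame(image_id = id, seed = sp$seed,
                               area_fraction = gen$truth$area_fraction,
                               branch_density = sp$branch_density,
                               septum_thickness = sp$septum_thickness,
                               stringsAsFactors = FALSE)
      if (!is.null(dir)) {
        write_image_tiff(gen$image, file.path(dir, paste0(id, ".tif")))
        write_mask_png(gen$truth$mask, file.path(dir, paste0(id, "_mask.png")))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  if (!is.null(dir)) {
    manifest$image <- file.path(dir, paste0(manifest$image_id, ".tif"))
    write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
    write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  } else {
    manifest$image <- I(images)
  }
  list(manifest = manifest, truth = truth)
}
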