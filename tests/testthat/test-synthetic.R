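test_that("filled rectangles and lines have the expected geometry", {
  expect_equal(sum(make_filled_rect(8, 8)), 64)
  expect_equal(dim(make_filled_rect(3, 5)), c(5L, 3L))
  expect_true(all(make_filled_rect(4, 4)))
  expect_error(make_filled_rect(0, 4), "must be >= 1")
})

test_that("Sierpinski carpet has exact side and pixel counts at all orders", {
  for (k in 1:7) {
    sc <- make_sierpinski_carpet(k)
    expect_equal(dim(sc), c(3L^k, 3L^k))
    expect_equal(sum(sc), 8^k)
  }
  expect_false(make_sierpinski_carpet(1)[2, 2])  # centre removed
  expect_error(make_sierpinski_carpet(0), "order")
  expect_error(make_sierpinski_carpet(8), "order")
})

test_that("point patterns place exactly n_points and honour the layout", {
  for (layout in c("uniform", "clustered", "single_cell")) {
    p <- make_point_pattern(120, layout, seed = 7)
    expect_equal(sum(p), 120)
  }
  # single_cell: all mass in one quadrat of the default grid
  p <- make_point_pattern(120, "single_cell", seed = 3)
  counts <- morisita_index(p)$per_cell_counts
  expect_equal(sum(counts > 0), 1)
  expect_error(make_point_pattern(10000, "single_cell"), "capacity")
  # determinism
  expect_identical(make_point_pattern(200, "clustered", seed = 5),
                   make_point_pattern(200, "clustered", seed = 5))
})

test_that("clustered point patterns are more aggregated than uniform ones", {
  wins <- 0L
  for (s in 1:40) {
    iu <- morisita_index(make_point_pattern(300, "uniform", seed = s))$index_value
    ic <- morisita_index(make_point_pattern(300, "clustered", n_clusters = 3,
                                            cluster_sd = 5, seed = s))$index_value
    wins <- wins + (ic > iu)
  }
  expect_gte(wins / 40, 0.95)
})

test_that("tissue spec validates its invariants", {
  expect_s3_class(tissue_spec(), "tissue_spec")
  expect_error(tissue_spec(width = 32), ">= 64")
  expect_error(tissue_spec(n_lobules = 1), "n_lobules")
  expect_error(tissue_spec(septum_thickness = 0.5), "septum_thickness")
  expect_error(tissue_spec(branch_density = -1), "branch_density")
})

test_that("tissue images are deterministic and truth records are exact", {
  sp <- tissue_spec(seed = 21)
  a <- make_tissue_image(sp)
  b <- make_tissue_image(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$mask, b$truth$mask)
  expect_equal(a$truth$area_fraction, mean(a$truth$mask))
  expect_identical(a$truth$mask, make_truth_mask(sp))
})

test_that("zero branch density gives the septa-only network", {
  sp0 <- tissue_spec(branch_density = 0, seed = 13)
  sp8 <- tissue_spec(branch_density = 8, seed = 13)
  m0 <- make_truth_mask(sp0)
  m8 <- make_truth_mask(sp8)
  # same seed => identical septa; branches only add pixels inside lobules
  expect_true(all(m8[m0]))
  expect_gt(sum(m8), sum(m0))
})

test_that("area fraction grows with septum thickness and branch density", {
  frac <- function(st, bd) {
    mean(vapply(1:5, function(s)
      mean(make_truth_mask(tissue_spec(septum_thickness = st,
                                       branch_density = bd, seed = s))),
      1))
  }
  expect_lt(frac(3, 2), frac(8, 2))
  expect_lt(frac(8, 2), frac(16, 2))
  expect_lt(frac(4, 0), frac(4, 6))
})

test_that("area-fraction calibration hits its target and fails cleanly", {
  sp <- tissue_spec(seed = 31)
  cal <- calibrate_area_fraction(sp, 0.30, tolerance = 0.02, n_seeds = 10)
  got <- mean(vapply(0:9, function(i)
    mean(make_truth_mask(cal, cal$seed + i)), 1))
  expect_lt(abs(got - 0.30), 0.02)
  # degenerate targets
  expect_error(calibrate_area_fraction(sp, 0), class = "morphotex_calibration_failure")
  expect_error(calibrate_area_fraction(sp, 0.01, n_seeds = 3),
               class = "morphotex_calibration_failure")
  # fixed point: recalibrating to the current fraction changes little
  cur <- mean(vapply(0:9, function(i)
    mean(make_truth_mask(cal, cal$seed + i)), 1))
  cal2 <- calibrate_area_fraction(cal, cur, tolerance = 0.02, n_seeds = 10)
  got2 <- mean(vapply(0:9, function(i)
    mean(make_truth_mask(cal2, cal2$seed + i)), 1))
  expect_lt(abs(got2 - cur), 0.02)
})

test_that("simulate_cohorts builds a usable manifest in memory and on disk", {
  specs <- list(a = tissue_spec(seed = 1), b = tissue_spec(branch_density = 8, seed = 2))
  sim <- simulate_cohorts(specs, n_per_group = 2, seed = 5)
  expect_equal(nrow(sim$manifest), 4)
  expect_equal(sort(unique(sim$manifest$group)), c("a", "b"))
  expect_true(is.list(sim$manifest$image))
  expect_equal(dim(sim$manifest$image[[1]])[3], 3)
  d <- withr::local_tempdir()
  sim2 <- simulate_cohorts(specs, n_per_group = 1, seed = 5, dir = d)
  expect_true(all(file.exists(sim2$manifest$image)))
  expect_true(file.exists(file.path(d, "truth.csv")))
  img <- read_image_rgb(sim2$manifest$image[1])
  expect_equal(dim(img), c(192L, 192L, 3L))
})
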