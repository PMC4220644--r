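rgb_from <- function(r, g, b) {
  # build an RGB array from equal-sized integer matrices
  array(c(r, g, b), dim = c(nrow(r), ncol(r), 3))
}

test_that("red-channel extraction returns the first channel unchanged", {
  r <- matrix(c(10L, 70L, 40L, 0L), 2, 2)
  img <- rgb_from(r, r + 10L, r + 20L)
  expect_identical(extract_red_channel(img), r)
  px <- array(c(255L, 0L, 0L), dim = c(1, 1, 3))
  expect_equal(as.vector(extract_red_channel(px)), 255L)
  expect_error(extract_red_channel(array(0L, c(2, 2, 2))), "width x 3")
  expect_error(extract_red_channel(array(300L, c(2, 2, 3))), "8-bit")
})

test_that("Otsu splits a bimodal image perfectly and rejects constants", {
  gray <- matrix(c(rep(10L, 50), rep(200L, 50)), 10, 10)
  cfg <- segmentation_config()
  fg <- threshold_image(gray, cfg)
  expect_identical(fg, gray == 10L)
  expect_error(otsu_threshold(matrix(7L, 4, 4)), "degenerate")
  # manual mode has no degeneracy
  cfg2 <- segmentation_config("manual", manual_threshold = 128,
                              polarity = "bright_foreground")
  expect_true(all(threshold_image(matrix(200L, 4, 4), cfg2)))
})

test_that("Otsu equals exhaustive between-class-variance search", {
  withr::with_seed(11, {
    for (i in 1:25) {
      gray <- random_gray(16, 16, levels = 256L)
      expect_equal(otsu_threshold(gray), naive_otsu(gray))
    }
  })
})

test_that("geometric filter removes components outside the area range", {
  cfg <- segmentation_config(min_area = 5)
  p <- matrix(FALSE, 8, 8); p[2, 2:4] <- TRUE      # 3-px component
  expect_false(any(geometric_filter(p, cfg)))
  q <- matrix(FALSE, 20, 20)
  q[1:2, 1:2] <- TRUE                               # area 4
  q[6:15, 6:15] <- TRUE                             # area 100
  cfg2 <- segmentation_config(min_area = 10)
  out <- geometric_filter(q, cfg2)
  expect_equal(sum(out), 100)
  expect_true(all(out[6:15, 6:15]))
})

test_that("geometric filter matches the naive flood-fill oracle", {
  withr::with_seed(23, {
    for (i in 1:15) {
      p <- random_pattern(24, 24, 0.35)
      cfg <- segmentation_config(min_area = sample(1:6, 1),
                                 max_area = sample(c(30, 60, Inf), 1),
                                 min_circularity = sample(c(0, 0.1), 1),
                                 connectivity = sample(c(4L, 8L), 1))
      expect_identical(geometric_filter(p, cfg), naive_geometric_filter(p, cfg))
    }
  })
})

test_that("component labeling agrees with EBImage at 4-connectivity", {
  skip_if_not_installed("EBImage")
  withr::with_seed(31, {
    for (i in 1:10) {
      p <- random_pattern(30, 30, 0.4)
      mine <- morphotex:::.cc_label(p, 4L)
      ref <- EBImage::bwlabel(matrix(as.numeric(p), 30))
      expect_equal(max(mine), max(ref))
      # same partition up to label order
      expect_equal(length(unique(paste(mine[p], ref[p]))), max(ref))
    }
  })
})

test_that("geometric filter is idempotent and never adds pixels", {
  withr::with_seed(5, {
    p <- random_pattern(30, 30, 0.3)
    cfg <- segmentation_config(min_area = 4)
    f1 <- geometric_filter(p, cfg)
    expect_true(all(p[f1]))
    expect_identical(geometric_filter(f1, cfg), f1)
  })
})

test_that("area fraction is foreground count over total count", {
  p <- matrix(FALSE, 10, 10); p[1:4, 1:10] <- TRUE
  expect_equal(area_fraction(p), 0.40)
  expect_equal(area_fraction(matrix(FALSE, 5, 5)), 0)
  expect_error(area_fraction(matrix(logical(0), 0, 0)), "zero-size")
})

test_that("skeletonization thins, preserves topology and is idempotent", {
  line <- matrix(TRUE, 1, 30)
  expect_identical(skeletonize(line), line)
  expect_identical(skeletonize(matrix(FALSE, 5, 5)), matrix(FALSE, 5, 5))
  disk <- outer(1:20, 1:20, function(r, c) (r - 10.5)^2 + (c - 10.5)^2 <= 81)
  sk <- skeletonize(disk)
  expect_lte(sum(sk), 5)
  expect_true(all(disk[sk]))                        # subset of input
  withr::with_seed(17, {
    for (i in 1:15) {
      p <- random_pattern(30, 30, 0.45)
      sk <- skeletonize(p)
      expect_lte(sum(sk), sum(p))
      expect_identical(skeletonize(sk), sk)
      expect_equal(max(morphotex:::.cc_label(sk, 8L)),
                   max(morphotex:::.cc_label(p, 8L)))
    }
  })
})

test_that("segmentation recovers the synthetic truth mask", {
  sp <- tissue_spec(branch_density = 4, stain_noise_sd = 10, seed = 41)
  gen <- make_tissue_image(sp)
  cfg <- default_config()$segmentation
  mask <- geometric_filter(threshold_image(extract_red_channel(gen$image), cfg), cfg)
  jac <- sum(mask & gen$truth$mask) / sum(mask | gen$truth$mask)
  expect_gte(jac, 0.9)
})
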