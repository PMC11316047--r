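test_that("maximum projection is the per-pixel max over z", {
  arr <- array(1, c(4, 5, 3))
  arr[2, 3, 2] <- 9
  mp <- max_project(arr)
  expect_equal(dim(mp), c(4L, 5L))
  expect_equal(mp[2, 3], 9)
  expect_equal(sum(mp == 1), 19L)
  # z extent 1 and constant volumes are identities
  expect_equal(max_project(array(7, c(3, 3, 1))), matrix(7, 3, 3))
  expect_equal(max_project(matrix(2, 3, 3)), matrix(2, 3, 3))
})

test_that("rolling-ball subtraction removes offsets and never increases intensity", {
  px <- c(x = 0.1, y = 0.1)
  const <- matrix(55, 40, 40)
  expect_true(all(subtract_background(const, 0.5, pixel_size = px) == 0))

  spot <- get_channel(render_spot(c(2, 2), sigma = 0.08, amplitude = 200,
                                  plane_shape = c(40, 40), pixel_size = 0.1), "spot")
  plane <- spot + 70
  sub <- subtract_background(plane, 0.5, pixel_size = px)
  expect_equal(max(abs(sub - spot)), 0, tolerance = 1)
  expect_true(all(sub <= plane))
  expect_error(subtract_background(const, 0.05, pixel_size = px), "one pixel")
})

test_that("puncta detection applies the strict area filter", {
  px <- 0.1   # pixel area 0.01 um^2: a punctum must cover >= 2 pixels
  plane <- matrix(0, 80, 80)
  centers <- expand.grid(y = c(15, 40, 65), x = c(15, 40, 65))[1:7, ]
  for (i in seq_len(7)) {   # 7 plus-shaped puncta of 5 pixels (area 0.05 um^2)
    plane[cbind(centers$y[i] + c(0, 0, 0, -1, 1),
                centers$x[i] + c(-1, 0, 1, 0, 0))] <- 150
  }
  singles <- cbind(y = c(5, 5, 75), x = c(5, 75, 75))
  plane[singles] <- 150     # 3 single-pixel spots: area 0.01, filtered out
  pts <- detect_puncta(plane, threshold = 100, min_area = 0.01, pixel_size = px)
  expect_equal(nrow(pts), 7L)
  expect_equal(sort(pts$n_pixels), rep(5L, 7))
  expect_equal(nrow(detect_puncta(matrix(0, 20, 20), threshold = 10,
                                  min_area = 0.01, pixel_size = px)), 0L)
})

test_that("counts are invariant to a constant offset ahead of background subtraction", {
  sc <- generate_scene(scene_preset("lc3", "ko", seed = 17))
  mip <- max_project(sc$volume, "lc3")
  px <- c(x = 0.1, y = 0.1)
  n0 <- nrow(detect_puncta(subtract_background(mip, 0.5, pixel_size = px),
                           threshold = 100, pixel_size = px))
  n1 <- nrow(detect_puncta(subtract_background(mip + 500, 0.5, pixel_size = px),
                           threshold = 100, pixel_size = px))
  expect_equal(n0, n1)
})

test_that("the 2:1-over-background line-profile criterion classifies reporter puncta", {
  px <- 0.02
  base <- matrix(100, 101, 101)
  spot <- get_channel(render_spot(c(1.01, 1.01), sigma = 0.08, amplitude = 200,
                                  plane_shape = c(101, 101), pixel_size = px), "spot")
  mch <- base + spot          # mCherry peak 300, background 100
  gfp <- base                 # GFP flat
  r <- classify_mcherry_only(c(1.01, 1.01), gfp, mch, pixel_size = px)
  expect_equal(r$rho_mcherry, 2.0, tolerance = 0.02)
  expect_lt(r$rho_gfp, 0.5)
  expect_identical(r$reason, "ok")
  # at the published threshold the boundary case is >=: test just inside/outside
  expect_true(classify_mcherry_only(c(1.01, 1.01), gfp, mch, px,
                                    rho_min = 1.95)$mcherry_only)
  expect_false(classify_mcherry_only(c(1.01, 1.01), gfp, mch, px,
                                     rho_min = 2.05)$mcherry_only)

  # GFP-positive punctum is rejected even with a strong mCherry signal
  gfp2 <- base + spot         # GFP peak 300 too
  r2 <- classify_mcherry_only(c(1.01, 1.01), gfp2, mch, pixel_size = px)
  expect_true(r2$gfp_positive)
  expect_false(r2$mcherry_only)

  # weak mCherry (peak 150, background 100): rho = 0.5, rejected
  mch3 <- base + 0.25 * spot
  r3 <- classify_mcherry_only(c(1.01, 1.01), gfp, mch3, pixel_size = px)
  expect_equal(r3$rho_mcherry, 0.5, tolerance = 0.02)
  expect_false(r3$mcherry_only)

  # non-positive background excludes the punctum with a reason
  r4 <- classify_mcherry_only(c(1.01, 1.01), gfp - 100, mch - 100, pixel_size = px)
  expect_identical(r4$reason, "non-positive background")
  expect_true(is.na(r4$mcherry_only))
})

test_that("linescan FWHM matches the Gaussian closed form and scales with sigma", {
  px <- 0.02
  for (sigma in c(0.0637, 2 * 0.0637)) {
    sp <- render_spot(c(1.01, 1.01), sigma = sigma, amplitude = 500,
                      plane_shape = c(101, 101), pixel_size = px)
    ls <- linescan_fwhm(get_channel(sp, "spot"), p0 = c(0.11, 1.01),
                        p1 = c(1.91, 1.01), pixel_size = px)
    expect_true(ls$defined)
    expect_equal(ls$fwhm, 2 * sqrt(2 * log(2)) * sigma, tolerance = 0.05)
  }
  # doubling sigma doubles the width (tighter than the absolute tolerance)
  f1 <- linescan_fwhm(get_channel(render_spot(c(1.01, 1.01), 0.0637, 500,
                                              c(101, 101), px), "spot"),
                      c(0.11, 1.01), c(1.91, 1.01), pixel_size = px)$fwhm
  f2 <- linescan_fwhm(get_channel(render_spot(c(1.01, 1.01), 0.1274, 500,
                                              c(101, 101), px), "spot"),
                      c(0.11, 1.01), c(1.91, 1.01), pixel_size = px)$fwhm
  expect_equal(f2 / f1, 2, tolerance = 0.02)

  # flat and monotone profiles have no defined width
  flat <- linescan_fwhm(matrix(5, 50, 50), c(0.2, 2), c(4.5, 2), pixel_size = 0.1)
  expect_false(flat$defined)
  expect_true(is.na(flat$fwhm))
  ramp <- linescan_fwhm(matrix(rep(1:50, each = 50), 50, 50, byrow = FALSE) * 0 +
                          outer(rep(1, 50), 1:50), c(0.2, 2), c(4.5, 2),
                        pixel_size = 0.1)
  expect_false(ramp$defined)
})

test_that("cargo-selective matching is greedy, exclusive and radius-gated", {
  a <- data.frame(centroid_x = 1.00, centroid_y = 1.00)
  b <- data.frame(centroid_x = 1.05, centroid_y = 1.00)
  r <- classify_cargo(a, b, match_radius = 0.15)
  expect_equal(r$dual, 1L); expect_equal(r$a_only, 0L); expect_equal(r$b_only, 0L)

  b2 <- data.frame(centroid_x = 1.30, centroid_y = 1.00)
  r2 <- classify_cargo(a, b2, match_radius = 0.15)
  expect_equal(r2$dual, 0L); expect_equal(r2$a_only, 1L); expect_equal(r2$b_only, 1L)

  a3 <- data.frame(centroid_x = runif(100, 0, 10), centroid_y = runif(100, 0, 10))
  r3 <- classify_cargo(a3, a3[0, ], match_radius = 0.15)
  expect_equal(r3$a_only, 100L); expect_equal(r3$dual, 0L)

  # each spot used at most once: two A spots near one B spot give 1 dual + 1 A-only
  a4 <- data.frame(centroid_x = c(1.00, 1.08), centroid_y = c(1, 1))
  b4 <- data.frame(centroid_x = 1.04, centroid_y = 1)
  r4 <- classify_cargo(a4, b4, match_radius = 0.15)
  expect_equal(r4$dual, 1L); expect_equal(r4$a_only, 1L)
  expect_true(r4$matched_a[1])               # closer pair wins

  # co-placed dual-label ground truth: recall >= 0.95 noiseless
  set.seed(6)
  n <- 200
  ax <- runif(n, 1, 9); ay <- runif(n, 1, 9)
  jit <- function(v) v + runif(n, -0.03, 0.03)
  rec <- classify_cargo(data.frame(centroid_x = ax, centroid_y = ay),
                        data.frame(centroid_x = jit(ax), centroid_y = jit(ay)),
                        match_radius = 0.15)
  expect_gte(rec$dual / n, 0.95)
})

test_that("puncta density on a mask is physical and resolution independent", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:10, 1:20] <- TRUE                  # 200 px * 0.01 um^2 = 2 um^2
  spots <- data.frame(centroid_x = c(0.5, 1.0, 1.5, 0.7),
                      centroid_y = c(0.5, 0.5, 0.9, 0.3))
  r <- puncta_density_on_mask(spots, mask, pixel_size = 0.1)
  expect_equal(r$density_per_um2, 2.0)

  off <- data.frame(centroid_x = c(0.5, 1.5), centroid_y = c(1.5, 1.9))
  expect_equal(puncta_density_on_mask(off, mask, 0.1)$density_per_um2, 0)

  r0 <- puncta_density_on_mask(spots, mask & FALSE, 0.1)
  expect_true(is.na(r0$density_per_um2))
  expect_identical(r0$reason, "empty mask")

  # halving the pixel size with the same physical mask leaves density unchanged
  mask2 <- matrix(FALSE, 40, 40)
  mask2[1:20, 1:40] <- TRUE
  r2 <- puncta_density_on_mask(spots, mask2, pixel_size = 0.05)
  expect_equal(r2$density_per_um2, r$density_per_um2, tolerance = 1e-9)
})

test_that("ROI mean intensity and Parkin-positive area behave geometrically", {
  plane <- matrix(4, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:5, ] <- TRUE
  expect_equal(region_mean_intensity(plane, mask), 4)
  half <- plane; half[1:5, ] <- 0; half[6:10, ] <- 8
  m2 <- matrix(TRUE, 10, 10)
  expect_equal(region_mean_intensity(half, m2), 4)
  outside <- plane; outside[!mask] <- 1e6
  expect_equal(region_mean_intensity(outside, mask), 4)
  expect_error(region_mean_intensity(plane, mask & FALSE), "empty")

  # disk of radius 1 um above threshold: area ~ pi um^2
  px <- 0.05
  xs <- (seq_len(80) - 0.5) * px
  disk <- outer((xs - 2)^2, (xs - 2)^2, `+`) <= 1
  plane2 <- 10 + 90 * disk
  expect_equal(parkin_positive_area(plane2, threshold = 50, pixel_size = px),
               pi, tolerance = 0.02)
  expect_equal(parkin_positive_area(plane2, threshold = 200, pixel_size = px), 0)
  # area is monotone non-increasing in the threshold
  areas <- vapply(c(5, 20, 60, 101), function(t)
    parkin_positive_area(plane2, t, pixel_size = px), numeric(1))
  expect_true(all(diff(areas) <= 0))
})
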