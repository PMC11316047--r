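test_that("segmentation basics: empty volumes, two tubes, threshold monotonicity", {
  vs <- c(x = 0.1, y = 0.1, z = 0.3)
  zeros <- array(0, c(20, 20, 4))
  expect_warning(lv <- segment_3d(zeros, threshold = 10, voxel_size = vs),
                 "no objects")
  expect_equal(max(lv$labels), 0L)

  # two disjoint synthetic tubes
  cfg <- scene_config(grid_shape = c(y = 64, x = 64, z = 8), n_mito = 2,
                      tube_length_meanlog = log(1.5), tube_length_sdlog = 1e-9,
                      min_separation = 3, cyto_level = 0, shot_noise = FALSE,
                      read_noise_sigma = 0, tube_amplitude = 4, seed = 21)
  sc <- generate_scene(cfg)
  lv2 <- segment_3d(sc$volume, threshold = 150, channel = "tom20")
  expect_equal(max(lv2$labels), 2L)

  # monotonicity: higher threshold gives a subset mask
  arr <- get_channel(generate_scene(scene_preset("morpho", "ko", seed = 2))$volume,
                     "tom20")
  m1 <- segment_3d(arr, threshold = 130, clean_min_voxels = 1, voxel_size = vs)
  m2 <- segment_3d(arr, threshold = 180, clean_min_voxels = 1, voxel_size = vs)
  expect_true(all(m1$labels[m2$labels > 0] > 0))
})

test_that("principal-axis lengths match analytic second moments", {
  vs <- c(x = 0.1, y = 0.1, z = 0.1)
  # solid ellipsoid with semi-axes (5, 1, 1) um: full axes (10, 2, 2)
  vox <- rasterize_ellipsoid(c(5, 1, 1), c(5.5, 1.5, 1.5),
                             grid = c(30, 110, 30), voxel_size = vs)
  ax <- axis_lengths(vox, vs)
  expect_equal(ax, c(10, 2, 2), tolerance = 0.02)
  expect_equal(as.numeric(elongation(ax[1], ax[2], ax[3])), 5, tolerance = 0.02)

  # sphere of radius r: all axes 2r, elongation 1
  vox2 <- rasterize_ellipsoid(c(1, 1, 1), c(1.5, 1.5, 1.5),
                              grid = c(30, 30, 30), voxel_size = vs)
  ax2 <- axis_lengths(vox2, vs)
  expect_equal(ax2, c(2, 2, 2), tolerance = 0.02)
  expect_equal(as.numeric(elongation(ax2[1], ax2[2], ax2[3])), 1, tolerance = 0.01)
})

test_that("axis lengths are invariant to rotation and isotropic rescaling", {
  set.seed(4)
  pts <- cbind(y = rnorm(400, sd = 3), x = rnorm(400, sd = 1), z = rnorm(400, sd = 0.5))
  ax <- axis_lengths(pts, c(x = 1, y = 1, z = 1))
  q <- qr.Q(qr(matrix(rnorm(9), 3)))           # random orthogonal matrix
  rot <- pts %*% q
  colnames(rot) <- c("y", "x", "z")
  expect_equal(axis_lengths(rot, c(x = 1, y = 1, z = 1)), ax, tolerance = 1e-9)

  # isotropic rescaling scales axes, leaves elongation unchanged
  ax_s <- axis_lengths(pts, c(x = 2, y = 2, z = 2))
  # note: the 0.5-voxel centre shift is affine, so only ratios are compared
  expect_equal(ax_s[1] / mean(ax_s[2:3]), ax[1] / mean(ax[2:3]), tolerance = 1e-6)
})

test_that("elongation formula, degeneracy and input validation", {
  expect_equal(as.numeric(elongation(10, 2, 2)), 5)
  expect_equal(as.numeric(elongation(10, 4, 2)), 10 / 3)
  expect_equal(as.numeric(elongation(3, 3, 3)), 1)
  deg <- elongation(5, 0, 0)
  expect_equal(as.numeric(deg), 1)
  expect_true(attr(deg, "degenerate"))
  expect_error(elongation(-1, -2, -3), "non-negative")
  expect_error(elongation(0, 0, 0), "sorted|zero")
  # single voxel is defined to have elongation 1
  ax1 <- axis_lengths(matrix(c(3, 3, 3), 1, dimnames = list(NULL, c("y", "x", "z"))),
                      c(x = 0.1, y = 0.1, z = 0.3))
  expect_equal(as.numeric(elongation(ax1[1], ax1[2], ax1[3])), 1)
})

test_that("size classes use the published boundaries and partition all objects", {
  expect_equal(as.character(classify_size(0.02)), "mdv_sized")
  expect_equal(as.character(classify_size(1.5)), "network")
  expect_equal(as.character(classify_size(0.5)), "intermediate")
  sc <- generate_scene(scene_preset("morpho", "ko", seed = 8))
  obj <- assay_morpho(sc$volume)$objects
  counts <- table(obj$size_class)
  expect_equal(sum(counts), nrow(obj))
  cell <- summarize_cell(obj)
  expect_equal(cell$n_network + cell$n_intermediate + cell$n_mdv_sized,
               cell$n_objects)
})

test_that("per-cell summaries: median elongation, totals, empty-cell record", {
  obj <- data.frame(label = 1:3, n_voxels = c(10, 20, 30),
                    volume_um3 = c(0.1, 0.2, 0.3),
                    a1 = c(1, 2, 9), a2 = c(1, 1, 1), a3 = c(1, 1, 1),
                    elongation = c(1, 2, 9),
                    centroid_x = 1:3, centroid_y = 1:3, centroid_z = 1:3,
                    size_class = classify_size(c(0.1, 0.2, 0.3)))
  s <- summarize_cell(obj, cell_id = "c1")
  expect_equal(s$median_elongation, 2)
  expect_equal(s$total_volume_um3, 0.6)
  expect_equal(summarize_cell(obj[1, , drop = FALSE])$median_elongation, 1)

  empty <- summarize_cell(obj[0, ], cell_id = 7)
  expect_equal(empty$n_objects, 0L)
  expect_equal(empty$total_volume_um3, 0)
  expect_true(is.na(empty$median_elongation))
})

test_that("segmentation recovers ground truth on noiseless scenes and overlaps well at preset SNR", {
  # noiseless, well separated: exact object count
  cfg <- scene_config(grid_shape = c(y = 96, x = 96, z = 10), n_mito = 5,
                      tube_amplitude = 4, tube_length_meanlog = log(1),
                      tube_length_sdlog = 0.1, min_separation = 2.5,
                      cyto_level = 0, shot_noise = FALSE, read_noise_sigma = 0,
                      seed = 31)
  sc <- generate_scene(cfg)
  lv <- segment_3d(sc$volume, threshold = 150, channel = "tom20")
  expect_equal(max(lv$labels), 5L)

  # per-object IoU at the default morpho preset SNR
  # resolvable tubes: ~1.5 um long and 0.5 um across, so every tube spans at
  # least one z plane of the 0.3-um stack; thinner/shorter objects suffer
  # partial-volume loss and are covered by the size-class analyses instead
  scn <- generate_scene(scene_preset("morpho", "control", seed = 13,
                                     n_mito = 6, min_separation = 2.2,
                                     tube_length_meanlog = log(1.5),
                                     tube_length_sdlog = 0.05,
                                     tube_radius = 0.25,
                                     mdv_rate = 0))
  # per-image manual-style threshold at the tubes' half-maximum plateau
  # (background ~100 counts, blurred tube plateau ~240)
  lvn <- segment_3d(scn$volume, threshold = 170, channel = "tom20")
  expect_equal(max(lvn$labels), 6L)           # exact count at preset SNR too
  d <- dim(lvn$labels)
  ious <- vapply(seq_along(scn$truth$tube_voxels), function(i) {
    vox <- scn$truth$tube_voxels[[i]]
    lin <- (vox[, "z"] - 1) * d[1] * d[2] + (vox[, "x"] - 1) * d[1] + vox[, "y"]
    labs <- lvn$labels[lin]
    l <- as.integer(names(sort(table(labs[labs > 0]), decreasing = TRUE)))[1]
    if (length(l) == 0L || is.na(l)) return(0)
    inter <- sum(labs == l)
    union <- nrow(vox) + sum(lvn$labels == l) - inter
    inter / union
  }, numeric(1))
  expect_true(all(ious >= 0.7))

  # measured total volume tracks ground truth (PSF + rasterisation tolerance)
  meas <- sum(measure_objects(lvn)$volume_um3)
  truth <- sum(scn$truth$objects$volume_um3[scn$truth$objects$type == "tube"])
  expect_equal(meas, truth, tolerance = 0.15)
})

test_that("knockout-style elongation shift is recovered with the right sign", {
  # paired seeds: the split random streams give both conditions the same
  # tube geometry draws, so the comparison isolates the condition effect
  diffs <- vapply(1:20, function(s) {
    ctrl <- assay_morpho(generate_scene(scene_preset("morpho", "control",
                                                     seed = s))$volume)
    ko <- assay_morpho(generate_scene(scene_preset("morpho", "ko",
                                                   seed = s))$volume)
    ko$cell$median_elongation - ctrl$cell$median_elongation
  }, numeric(1))
  expect_gte(mean(diffs > 0), 0.95)
})
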