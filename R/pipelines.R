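# Per-assay pipelines. Detection thresholds are fixed counts applied
# identically to every condition (the acquisition-matched analysis used for
# all published comparisons); defaults are calibrated to the synthetic preset
# amplitudes and are plain arguments for real data.

#' LC3 puncta count for one cell
#'
#' Full autophagosome pipeline: maximum intensity projection, rolling-ball
#' background subtraction, intensity threshold, size filter (> `min_area`
#' um^2), count of surviving puncta.
#'
#' @param volume an [image_volume()] with the LC3 channel.
#' @param channel channel name (default `"lc3"`).
#' @param threshold counts after background subtraction, or `"auto"`.
#' @param min_area um^2, strict lower bound on punctum area.
#' @param background_radius rolling-ball radius, um.
#' @return List: `count`, `puncta` (data frame from [detect_puncta()]).
#' @export
assay_lc3 <- function(volume, channel = "lc3", threshold = 100,
                      min_area = 0.01, background_radius = 0.5) {
  mip <- max_project(volume, channel)
  px <- volume$voxel_size[c("x", "y")]
  sub <- subtract_background(mip, radius = background_radius, pixel_size = px)
  pts <- detect_puncta(sub, threshold = threshold, min_area = min_area,
                       pixel_size = px)
  list(count = nrow(pts), puncta = pts)
}

#' Parkin-positive area for one cell
#'
#' Maximum intensity projection of the Parkin channel, thresholded within the
#' cell mask; returns the positive area in um^2.
#'
#' @param volume an [image_volume()] with a `"parkin"` channel.
#' @param cell_mask logical `[y, x]` mask (e.g. ground-truth cell region).
#' @param threshold counts (raw image), identical across conditions.
#' @param channel channel name.
#' @return Positive area, um^2.
#' @export
assay_parkin <- function(volume, cell_mask = NULL, threshold = 250,
                         channel = "parkin") {
  mip <- max_project(volume, channel)
  parkin_positive_area(mip, threshold = threshold, cell_mask = cell_mask,
                       pixel_size = volume$voxel_size[c("x", "y")])
}

#' mCherry-only mitolysosome count for one cell
#'
#' Dual-channel mitophagy-reporter pipeline: puncta are detected on the
#' background-subtracted mCherry projection, then each candidate is accepted
#' only if its raw mCherry line profile is at least `rho_min`:1 over
#' background while GFP fluorescence is absent
#' ([classify_mcherry_only()]).
#'
#' @param volume an [image_volume()] with `"gfp"` and `"mcherry"` channels.
#' @param detect_threshold counts after background subtraction.
#' @param rho_min,gfp_absent_ratio classifier thresholds.
#' @param min_area um^2 size filter.
#' @param background_radius rolling-ball radius, um.
#' @return List: `count` (mCherry-only puncta), `candidates` (detected spots),
#'   `classification` (per-candidate list results).
#' @export
assay_cox8 <- function(volume, detect_threshold = 60, rho_min = 2.0,
                       gfp_absent_ratio = 0.5, min_area = 0.01,
                       background_radius = 0.5) {
  px <- volume$voxel_size[c("x", "y")]
  mch <- max_project(volume, "mcherry")
  gfp <- max_project(volume, "gfp")
  sub <- subtract_background(mch, radius = background_radius, pixel_size = px)
  cand <- detect_puncta(sub, threshold = detect_threshold, min_area = min_area,
                        pixel_size = px)
  if (nrow(cand) == 0L) {
    return(list(count = 0L, candidates = cand, classification = list()))
  }
  cls <- lapply(seq_len(nrow(cand)), function(i) {
    classify_mcherry_only(c(cand$centroid_x[i], cand$centroid_y[i]),
                          gfp_plane = gfp, mcherry_plane = mch,
                          pixel_size = px, rho_min = rho_min,
                          gfp_absent_ratio = gfp_absent_ratio)
  })
  n <- sum(vapply(cls, function(x) isTRUE(x$mcherry_only), logical(1)))
  list(count = n, candidates = cand, classification = cls)
}

#' 3D morphometry for one cell
#'
#' Segment the mitochondrial channel in 3D, measure every object and collapse
#' to the per-cell summary (median elongation, total volume, size-class
#' counts).
#'
#' @param volume an [image_volume()] with the mitochondrial channel.
#' @param channel channel name (default `"tom20"`).
#' @param threshold counts or `"auto"`.
#' @param clean_min_voxels clean-filter size, voxels.
#' @param v_mdv,v_network size-class bounds, um^3.
#' @param cell_id identifier for the summary row.
#' @return List: `objects` (per-object data frame), `cell` (one-row summary),
#'   `label_volume`.
#' @export
assay_morpho <- function(volume, channel = "tom20", threshold = 150,
                         clean_min_voxels = 5, v_mdv = 0.03, v_network = 1.0,
                         cell_id = 1L) {
  lv <- segment_3d(volume, threshold = threshold,
                   clean_min_voxels = clean_min_voxels, channel = channel)
  obj <- measure_objects(lv, v_mdv = v_mdv, v_network = v_network)
  list(objects = obj, cell = summarize_cell(obj, cell_id), label_volume = lv)
}

#' Live-cell dynamics for one time-lapse
#'
#' The modified vesselness tracking pipeline: optional histogram-matching
#' bleach correction, per-frame Frangi enhancement, semantic threshold,
#' connected-component instance segmentation, object measurement, and
#' assignment-based tracking with motility metrics.
#'
#' @param timelapse an [image_timelapse()].
#' @param channel channel to analyse.
#' @param scales Frangi scales, pixels.
#' @param tau semantic threshold on normalised vesselness.
#' @param max_speed tracking gate, um/s.
#' @param bleach_correction apply [bleach_correct()] first.
#' @param min_voxels drop instances smaller than this (speckle guard).
#' @return List: `tracks` (TrackSet), `summary` (per-track metrics),
#'   `frame_objects`, `masks` (per-frame logical masks).
#' @export
assay_track <- function(timelapse, channel = "tom20", scales = c(1, 1.5, 2),
                        tau = 1e-5, max_speed = 1.0, bleach_correction = TRUE,
                        min_voxels = 20L) {
  stopifnot(inherits(timelapse, "ImageTimelapse"))
  tl <- if (bleach_correction) bleach_correct(timelapse, channel) else timelapse
  vs <- tl$frames[[1L]]$voxel_size
  frame_objects <- vector("list", length(tl$frames))
  masks <- vector("list", length(tl$frames))
  for (f in seq_along(tl$frames)) {
    arr <- get_channel(tl$frames[[f]], channel)
    ves <- frangi_enhance(arr, scales = scales)
    mask <- semantic_mask(ves, tau = tau)
    labels <- clean_labels(label_components(mask), min_voxels)
    frame_objects[[f]] <- measure_objects(labels, voxel_size = vs)
    masks[[f]] <- mask
  }
  tracks <- track_objects(frame_objects, tl$frame_interval, max_speed = max_speed)
  list(tracks = tracks,
       summary = summarize_tracks(tracks, tl$frame_interval),
       frame_objects = frame_objects, masks = masks)
}

#' Fold-change recovery over a cohort of synthetic cells
#'
#' Generates `n_cells` control and `n_cells` knockout-like scenes from a
#' preset (seeds `base_seed + 1 .. base_seed + 2*n_cells`), runs the matching
#' assay pipeline on every cell and returns the per-condition statistics and
#' their ratio. This is the package's end-to-end validation harness.
#'
#' @param preset `"lc3"`, `"parkin"` or `"cox8_48h"`.
#' @param n_cells cells per condition.
#' @param base_seed integer; cell i of condition c uses seed
#'   `base_seed + (c - 1) * n_cells + i`.
#' @param stat `"median"` or `"mean"` per-condition summary.
#' @return List: `control`, `ko` (per-cell values), `stat_control`, `stat_ko`,
#'   `ratio`.
#' @export
recover_fold_change <- function(preset = c("lc3", "parkin", "cox8_48h"),
                                n_cells = 30L, base_seed = 0L,
                                stat = c("median", "mean")) {
  preset <- match.arg(preset)
  stat <- match.arg(stat)
  f <- switch(preset,
    lc3 = function(cfg, sc) assay_lc3(sc$volume)$count,
    parkin = function(cfg, sc) assay_parkin(sc$volume, cell_mask = sc$truth$cell_mask),
    cox8_48h = function(cfg, sc) assay_cox8(sc$volume)$count
  )
  run <- function(condition, offset) {
    vapply(seq_len(n_cells), function(i) {
      cfg <- scene_preset(preset, condition, seed = base_seed + offset + i)
      f(cfg, generate_scene(cfg))
    }, numeric(1))
  }
  ctrl <- run("control", 0L)
  ko <- run("ko", n_cells)
  s <- if (stat == "median") median else mean
  list(control = ctrl, ko = ko, stat_control = s(ctrl), stat_ko = s(ko),
       ratio = s(ko) / s(ctrl))
}
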