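# helpers ---------------------------------------------------------------------

# normalise input to (plane matrix [y,x], pixel_size c(x, y))
as_plane <- function(x, channel = NULL, pixel_size = NULL) {
  if (inherits(x, "ImageVolume")) {
    arr <- get_channel(x, channel)
    if (length(dim(arr)) == 3L) {
      if (dim(arr)[3L] != 1L) stop("expected a 2D plane; run max_project() first")
      arr <- arr[, , 1L]
    }
    list(plane = arr, pixel_size = x$voxel_size[c("x", "y")])
  } else {
    if (is.null(pixel_size)) stop("pixel_size is required for bare matrices")
    pixel_size <- unlist(pixel_size)
    if (length(pixel_size) == 1L) pixel_size <- c(x = pixel_size, y = pixel_size)
    list(plane = x, pixel_size = pixel_size[c("x", "y")])
  }
}

#' Maximum intensity projection
#'
#' Per-pixel maximum over the z axis of a single-channel stack. A 2D input
#' (or z extent 1) is returned unchanged.
#'
#' @param volume an [image_volume()] or numeric array `[y, x, z]`.
#' @param channel channel name for multi-channel volumes.
#' @return Numeric matrix `[y, x]`.
#' @export
max_project <- function(volume, channel = NULL) {
  arr <- if (inherits(volume, "ImageVolume")) get_channel(volume, channel) else volume
  d <- dim(arr)
  if (length(d) == 2L) return(arr)
  if (length(d) != 3L) stop("max_project expects a 2D or 3D array")
  if (d[3L] == 1L) return(arr[, , 1L])
  apply(arr, c(1L, 2L), max)
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grayscale morphological opening of
#' the plane with a disc of the given radius and removes it; structures
#' narrower than the disc (puncta) survive, additive offsets and slowly
#' varying background are removed. Output is clipped at zero, so the result
#' is everywhere less than or equal to the input.
#'
#' @param plane numeric matrix `[y, x]` or 2D [image_volume()].
#' @param radius ball radius, um; must be larger than the puncta of interest
#'   and map to at least one pixel.
#' @param channel,pixel_size see [detect_puncta()].
#' @return Background-subtracted matrix.
#' @export
subtract_background <- function(plane, radius = 0.5, channel = NULL,
                                pixel_size = NULL) {
  p <- as_plane(plane, channel, pixel_size)
  r_px <- radius / min(p$pixel_size)
  if (r_px < 1) stop("background radius (", radius, " um) is smaller than one pixel")
  size <- 2L * floor(r_px) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  bg <- gray_morph(gray_morph(p$plane, brush, "erode"), brush, "dilate")
  pmax(p$plane - bg, 0)
}

# flat grayscale erosion/dilation (min/max filter over the brush support,
# replicate padding at the borders)
gray_morph <- function(plane, brush, op = c("erode", "dilate")) {
  op <- match.arg(op)
  offs <- which(brush > 0, arr.ind = TRUE)
  ctr <- (dim(brush) + 1L) / 2
  ny <- nrow(plane); nx <- ncol(plane)
  out <- NULL
  f <- if (op == "erode") pmin else pmax
  for (k in seq_len(nrow(offs))) {
    iy <- pmin(pmax(seq_len(ny) + (offs[k, 1L] - ctr[1L]), 1L), ny)
    ix <- pmin(pmax(seq_len(nx) + (offs[k, 2L] - ctr[2L]), 1L), nx)
    shifted <- plane[iy, ix, drop = FALSE]
    out <- if (is.null(out)) shifted else f(out, shifted)
  }
  out
}

#' Detect diffraction-limited puncta on a 2D plane
#'
#' Connected components (8-connectivity) of suprathreshold pixels whose area
#' strictly exceeds `min_area` (default 0.01 um^2). Each punctum records its
#' intensity-weighted centroid, area, peak pixel value and a local background
#' estimated as the median of an annulus around the component (inner radius =
#' equivalent radius + 1 px, width 3 px, excluding foreground pixels).
#'
#' @param plane background-subtracted matrix `[y, x]` or 2D [image_volume()].
#' @param threshold counts, or `"auto"` for Otsu.
#' @param min_area minimum punctum area, um^2 (strict).
#' @param channel channel name for `ImageVolume` input.
#' @param pixel_size um per pixel (`c(x=, y=)` or scalar) for bare matrices.
#' @return Data frame with one row per punctum: `label`, `centroid_x`,
#'   `centroid_y` (um), `n_pixels`, `area_um2`, `peak`, `background`.
#' @export
detect_puncta <- function(plane, threshold = "auto", min_area = 0.01,
                          channel = NULL, pixel_size = NULL) {
  p <- as_plane(plane, channel, pixel_size)
  thr <- if (identical(threshold, "auto")) auto_threshold(p$plane) else threshold
  mask <- p$plane >= thr
  labels <- label_components(mask)
  px_area <- prod(p$pixel_size)
  n_obj <- max(labels)
  empty <- data.frame(label = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), n_pixels = integer(0),
                      area_um2 = numeric(0), peak = numeric(0),
                      background = numeric(0))
  if (n_obj == 0L) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  coord <- arrayInd(idx, dim(labels))
  vals <- p$plane[idx]
  ny <- nrow(p$plane); nx <- ncol(p$plane)
  rows <- lapply(seq_len(n_obj), function(l) {
    sel <- lab == l
    n_px <- sum(sel)
    # strict ">" with a relative epsilon so an area exactly at the bound
    # (e.g. one 0.1 um pixel vs 0.01 um^2) is excluded despite rounding
    if (n_px * px_area <= min_area * (1 + 1e-9)) return(NULL)
    yy <- coord[sel, 1L]; xx <- coord[sel, 2L]; vv <- vals[sel]
    w <- vv / sum(vv)
    cy <- sum(w * yy); cx <- sum(w * xx)
    r_eq <- sqrt(n_px / pi)
    ry <- round(cy); rx <- round(cx)
    r_out <- ceiling(r_eq + 4)
    wy <- max(1L, ry - r_out):min(ny, ry + r_out)
    wx <- max(1L, rx - r_out):min(nx, rx + r_out)
    dmat <- sqrt(outer((wy - cy)^2, (wx - cx)^2, `+`))
    ann <- dmat > (r_eq + 1) & dmat <= (r_eq + 4) & labels[wy, wx] == 0L
    bg <- if (any(ann)) median(p$plane[wy, wx][ann]) else NA_real_
    data.frame(label = l,
               centroid_x = (cx - 0.5) * p$pixel_size[["x"]],
               centroid_y = (cy - 0.5) * p$pixel_size[["y"]],
               n_pixels = n_px, area_um2 = n_px * px_area,
               peak = max(vv), background = bg)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out$label <- seq_len(nrow(out))
  out
}

#' Sample an intensity line profile
#'
#' Bilinear interpolation along the segment from `p0` to `p1` (um), sampled
#' at the pixel pitch.
#'
#' @param plane matrix `[y, x]` or 2D [image_volume()].
#' @param p0,p1 endpoints `c(x, y)` in um.
#' @param channel,pixel_size see [detect_puncta()].
#' @return Data frame with `position` (um from `p0`) and `intensity`.
#' @export
linescan_profile <- function(plane, p0, p1, channel = NULL, pixel_size = NULL) {
  p <- as_plane(plane, channel, pixel_size)
  if (isTRUE(all.equal(p0, p1))) stop("p0 and p1 must differ")
  len <- sqrt(sum((p1 - p0)^2))
  pitch <- min(p$pixel_size)
  n <- max(2L, ceiling(len / pitch) + 1L)
  t <- seq(0, 1, length.out = n)
  xs <- p0[1L] + t * (p1[1L] - p0[1L])
  ys <- p0[2L] + t * (p1[2L] - p0[2L])
  ny <- nrow(p$plane); nx <- ncol(p$plane)
  # continuous pixel coordinates (voxel-centre convention)
  fx <- xs / p$pixel_size[["x"]] + 0.5
  fy <- ys / p$pixel_size[["y"]] + 0.5
  if (any(fx < 1 | fx > nx | fy < 1 | fy > ny)) {
    stop("line extends outside the plane")
  }
  x0 <- pmin(floor(fx), nx - 1L); y0 <- pmin(floor(fy), ny - 1L)
  dx <- fx - x0; dy <- fy - y0
  v <- (1 - dx) * (1 - dy) * p$plane[cbind(y0, x0)] +
    dx * (1 - dy) * p$plane[cbind(y0, x0 + 1L)] +
    (1 - dx) * dy * p$plane[cbind(y0 + 1L, x0)] +
    dx * dy * p$plane[cbind(y0 + 1L, x0 + 1L)]
  data.frame(position = t * len, intensity = v)
}

#' Full width at half maximum of a linescan
#'
#' Samples the profile between `p0` and `p1`, subtracts the profile minimum,
#' locates the global peak, and measures the distance between the two
#' half-maximum crossings bracketing it (linear interpolation between
#' samples). For a Gaussian profile of standard deviation `sigma` the result
#' is `2 * sqrt(2 * log(2)) * sigma`.
#'
#' @inheritParams linescan_profile
#' @return A list of class `LinescanResult`: `profile` (data frame),
#'   `peak_position` (um), `fwhm` (um, `NA` when undefined) and `defined`
#'   (FALSE when no half-maximum crossing exists on one side, e.g. a flat or
#'   monotone profile).
#' @export
linescan_fwhm <- function(plane, p0, p1, channel = NULL, pixel_size = NULL) {
  prof <- linescan_profile(plane, p0, p1, channel, pixel_size)
  y <- prof$intensity - min(prof$intensity)
  x <- prof$position
  i_pk <- which.max(y)
  half <- y[i_pk] / 2
  res <- list(profile = prof, peak_position = x[i_pk], fwhm = NA_real_,
              defined = FALSE)
  class(res) <- "LinescanResult"
  if (y[i_pk] <= 0) return(res)
  cross <- function(i, j) {
    # linear interpolation of the half-max crossing between samples i, j
    x[i] + (half - y[i]) * (x[j] - x[i]) / (y[j] - y[i])
  }
  left <- NA_real_
  for (i in rev(seq_len(i_pk - 1L))) {
    if (y[i] <= half) { left <- cross(i, i + 1L); break }
  }
  right <- NA_real_
  if (i_pk < length(y)) {
    for (i in (i_pk + 1L):length(y)) {
      if (y[i] <= half) { right <- cross(i, i - 1L); break }
    }
  }
  if (is.na(left) || is.na(right)) return(res)
  res$fwhm <- abs(right - left)
  res$defined <- TRUE
  res
}

#' @export
print.LinescanResult <- function(x, ...) {
  if (x$defined) {
    cat("Linescan: peak at", signif(x$peak_position, 4), "um, FWHM",
        signif(x$fwhm, 4), "um\n")
  } else {
    cat("Linescan: FWHM undefined (no half-maximum crossing)\n")
  }
  invisible(x)
}

#' Classify a punctum as mCherry-only (acid-quenched mitophagy reporter)
#'
#' Implements the published manual criterion for mitochondria delivered to
#' lysosomes: an mCherry fluorescence at least `rho_min`-to-1 over background
#' together with a lack of GFP fluorescence. A 1-um line is drawn through the
#' punctum centroid, oriented toward the brightest neighbouring pixel of the
#' mCherry channel; on each channel the background is the mean of the two
#' line-end intensities and the ratio is
#' `rho = (peak - background) / background`.
#'
#' @param centroid punctum centroid `c(x, y)`, um.
#' @param gfp_plane,mcherry_plane aligned matrices `[y, x]`.
#' @param pixel_size um per pixel.
#' @param rho_min minimum mCherry ratio (default 2: background-subtracted peak
#'   at least twice background).
#' @param gfp_absent_ratio maximum GFP ratio still counted as "absent".
#' @param line_length linescan length, um.
#' @return List: `mcherry_only`, `gfp_positive`, `rho_mcherry`, `rho_gfp`,
#'   and `reason` (`"ok"`, or why the punctum was excluded, e.g. non-positive
#'   background).
#' @export
classify_mcherry_only <- function(centroid, gfp_plane, mcherry_plane,
                                  pixel_size, rho_min = 2.0,
                                  gfp_absent_ratio = 0.5, line_length = 1.0) {
  pm <- as_plane(mcherry_plane, pixel_size = pixel_size)
  pg <- as_plane(gfp_plane, pixel_size = pixel_size)
  if (!identical(dim(pm$plane), dim(pg$plane))) {
    stop("GFP and mCherry planes must be aligned (same dimensions)")
  }
  ny <- nrow(pm$plane); nx <- ncol(pm$plane)
  cx <- round(centroid[1L] / pm$pixel_size[["x"]] + 0.5)
  cy <- round(centroid[2L] / pm$pixel_size[["y"]] + 0.5)
  cx <- min(max(cx, 2L), nx - 1L); cy <- min(max(cy, 2L), ny - 1L)
  nb <- expand.grid(dy = -1:1, dx = -1:1)
  nb <- nb[!(nb$dx == 0 & nb$dy == 0), ]
  vals <- pm$plane[cbind(cy + nb$dy, cx + nb$dx)]
  k <- which.max(vals)
  dir <- c(nb$dx[k], nb$dy[k])
  dir <- dir / sqrt(sum(dir^2))
  half <- line_length / 2
  clamp <- function(p) c(min(max(p[1L], 0.6 * pm$pixel_size[["x"]]),
                             (nx - 0.6) * pm$pixel_size[["x"]]),
                         min(max(p[2L], 0.6 * pm$pixel_size[["y"]]),
                             (ny - 0.6) * pm$pixel_size[["y"]]))
  p0 <- clamp(centroid - dir * half)
  p1 <- clamp(centroid + dir * half)
  rho_of <- function(plane_obj) {
    prof <- linescan_profile(plane_obj$plane, p0, p1,
                             pixel_size = plane_obj$pixel_size)
    n <- nrow(prof)
    bg <- mean(prof$intensity[c(1L, n)])
    # fluorescence at the punctum: peak within the central third of the line
    # (line ends measure background; a wider window would pick up
    # neighbouring structures instead of the punctum itself)
    mid <- prof$intensity[prof$position > (1 / 3) * prof$position[n] &
                            prof$position < (2 / 3) * prof$position[n]]
    peak <- if (length(mid)) max(mid) else max(prof$intensity)
    list(bg = bg, rho = (peak - bg) / bg)
  }
  rm_ <- rho_of(pm)
  rg_ <- rho_of(pg)
  if (!is.finite(rm_$bg) || rm_$bg <= 0 || !is.finite(rg_$bg) || rg_$bg <= 0) {
    return(list(mcherry_only = NA, gfp_positive = NA,
                rho_mcherry = NA_real_, rho_gfp = NA_real_,
                reason = "non-positive background"))
  }
  list(mcherry_only = rm_$rho >= rho_min && rg_$rho < gfp_absent_ratio,
       gfp_positive = rg_$rho >= gfp_absent_ratio,
       rho_mcherry = rm_$rho, rho_gfp = rg_$rho, reason = "ok")
}

#' Cargo-selective classification of MDV spots
#'
#' Greedy nearest-pair matching of spots detected in two cargo channels:
#' candidate pairs within `match_radius` are matched in order of increasing
#' distance (ties broken by lower spot index), each spot at most once.
#' Matched pairs are dual-labelled; unmatched spots are single-cargo MDV
#' calls.
#'
#' @param spots_a,spots_b data frames with `centroid_x`, `centroid_y` (um),
#'   e.g. from [detect_puncta()].
#' @param match_radius maximum centroid distance for a dual call, um.
#' @return List: counts `a_only`, `b_only`, `dual`, plus logical vectors
#'   `matched_a`, `matched_b`.
#' @export
classify_cargo <- function(spots_a, spots_b, match_radius = 0.15) {
  na <- nrow(spots_a); nb <- nrow(spots_b)
  matched_a <- rep(FALSE, na); matched_b <- rep(FALSE, nb)
  if (na > 0L && nb > 0L) {
    dx <- outer(spots_a$centroid_x, spots_b$centroid_x, `-`)
    dy <- outer(spots_a$centroid_y, spots_b$centroid_y, `-`)
    d <- sqrt(dx^2 + dy^2)
    cand <- which(d <= match_radius, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], cand[, 1L], cand[, 2L])
      for (k in ord) {
        i <- cand[k, 1L]; j <- cand[k, 2L]
        if (!matched_a[i] && !matched_b[j]) {
          matched_a[i] <- TRUE; matched_b[j] <- TRUE
        }
      }
    }
  }
  list(a_only = sum(!matched_a), b_only = sum(!matched_b),
       dual = sum(matched_a), matched_a = matched_a, matched_b = matched_b)
}

#' Puncta density on a mitochondrial mask
#'
#' Counts spot centroids falling on foreground pixels of the mask and divides
#' by the mask area (spots per um^2), the readout used for Drp1/Mfn2
#' localisation to mitochondria.
#'
#' @param spots data frame with `centroid_x`, `centroid_y` (um).
#' @param mito_mask logical matrix `[y, x]`.
#' @param pixel_size um per pixel.
#' @return List: `count`, `mask_area_um2`, `density_per_um2` (`NA` with a
#'   reason when the mask is empty).
#' @export
puncta_density_on_mask <- function(spots, mito_mask, pixel_size) {
  pixel_size <- unlist(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- c(x = pixel_size, y = pixel_size)
  area <- sum(mito_mask) * prod(pixel_size[c("x", "y")])
  if (area <= 0) {
    return(list(count = NA_integer_, mask_area_um2 = 0,
                density_per_um2 = NA_real_, reason = "empty mask"))
  }
  on_mask <- 0L
  if (nrow(spots)) {
    ix <- pmin(pmax(round(spots$centroid_x / pixel_size[["x"]] + 0.5), 1L),
               ncol(mito_mask))
    iy <- pmin(pmax(round(spots$centroid_y / pixel_size[["y"]] + 0.5), 1L),
               nrow(mito_mask))
    on_mask <- sum(mito_mask[cbind(iy, ix)])
  }
  list(count = on_mask, mask_area_um2 = area,
       density_per_um2 = on_mask / area, reason = "ok")
}

#' Mean intensity within a region of interest
#'
#' Per-cell mean fluorescence, the readout used for TMRE membrane-potential
#' and MitoSOX superoxide measurements.
#'
#' @param plane matrix `[y, x]` or 2D [image_volume()].
#' @param cell_mask logical matrix, same shape; must be non-empty.
#' @param channel channel name for `ImageVolume` input.
#' @return Mean of the pixel intensities inside the mask.
#' @export
region_mean_intensity <- function(plane, cell_mask, channel = NULL) {
  arr <- if (inherits(plane, "ImageVolume")) get_channel(plane, channel) else plane
  if (length(dim(arr)) == 3L && dim(arr)[3L] == 1L) arr <- arr[, , 1L]
  if (!identical(dim(arr), dim(cell_mask))) stop("mask and plane dimensions differ")
  if (!any(cell_mask)) stop("cell mask is empty")
  mean(arr[cell_mask])
}

#' Thresholded Parkin-positive area per cell
#'
#' Area (um^2) of suprathreshold pixels within the cell mask, the readout for
#' Parkin accumulation at mitochondria.
#'
#' @param plane matrix `[y, x]` or 2D [image_volume()].
#' @param threshold counts, or `"auto"` for Otsu within the cell mask.
#' @param cell_mask logical matrix (defaults to the whole plane).
#' @param channel,pixel_size see [detect_puncta()].
#' @return Positive area in um^2.
#' @export
parkin_positive_area <- function(plane, threshold, cell_mask = NULL,
                                 channel = NULL, pixel_size = NULL) {
  p <- as_plane(plane, channel, pixel_size)
  if (is.null(cell_mask)) cell_mask <- matrix(TRUE, nrow(p$plane), ncol(p$plane))
  thr <- if (identical(threshold, "auto")) auto_threshold(p$plane[cell_mask]) else threshold
  sum(p$plane >= thr & cell_mask) * prod(p$pixel_size)
}
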