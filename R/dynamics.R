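#' Histogram-matching photobleaching correction
#'
#' Monotonically maps the intensity histogram of every frame onto the
#' histogram of the first frame (rank mapping: the k-th smallest pixel of
#' frame t is replaced by the k-th smallest pixel of frame 1). A pure
#' multiplicative or additive intensity decay is removed exactly; corrected
#' frames share the reference frame's mean.
#'
#' @param frames an [image_timelapse()], or a list of numeric arrays.
#' @param channel channel to correct when frames are multi-channel
#'   (`ImageTimelapse` input); other channels pass through unchanged.
#' @return Same type as the input, with matched histograms.
#' @export
bleach_correct <- function(frames, channel = NULL) {
  if (inherits(frames, "ImageTimelapse")) {
    chs <- names(frames$frames[[1L]]$channels)
    ch <- if (is.null(channel)) {
      if (length(chs) != 1L) stop("multi-channel time-lapse: specify 'channel'")
      chs
    } else channel
    arrs <- lapply(frames$frames, get_channel, channel = ch)
    fixed <- match_histograms(arrs)
    out <- frames
    for (i in seq_along(out$frames)) out$frames[[i]]$channels[[ch]] <- fixed[[i]]
    return(out)
  }
  if (!is.list(frames) || length(frames) < 2L) {
    stop("bleach_correct needs at least 2 frames")
  }
  match_histograms(frames)
}

match_histograms <- function(arrs) {
  ref_sorted <- sort(as.numeric(arrs[[1L]]))
  out <- vector("list", length(arrs))
  out[[1L]] <- arrs[[1L]]
  for (t in 2L:length(arrs)) {
    a <- arrs[[t]]
    o <- order(a)
    b <- a
    b[o] <- ref_sorted
    dim(b) <- dim(a)
    out[[t]] <- b
  }
  out
}

# second-derivative (Hessian) fields of a Gaussian-smoothed image, central
# differences in voxel units, scale-normalised by sigma^2
hessian_fields <- function(arr, sigma) {
  d <- dim(arr)
  is3d <- length(d) == 3L && d[3L] > 1L
  sm <- gaussian_blur(if (length(d) == 2L) array(arr, c(d, 1L)) else arr,
                      c(y = sigma, x = sigma, z = if (is3d) sigma else 0),
                      pad = "replicate")
  shift <- function(a, axis, by) {
    dd <- dim(a)
    idx <- pmin(pmax(seq_len(dd[axis]) + by, 1L), dd[axis])
    switch(axis, a[idx, , , drop = FALSE], a[, idx, , drop = FALSE],
           a[, , idx, drop = FALSE])
  }
  d1 <- function(a, axis) (shift(a, axis, 1L) - shift(a, axis, -1L)) / 2
  s2 <- sigma^2
  gy <- d1(sm, 1L); gx <- d1(sm, 2L)
  H <- list(yy = s2 * d1(gy, 1L), xx = s2 * d1(gx, 2L), xy = s2 * d1(gx, 1L))
  if (is3d) {
    gz <- d1(sm, 3L)
    H$zz <- s2 * d1(gz, 3L); H$xz <- s2 * d1(gx, 3L); H$yz <- s2 * d1(gy, 3L)
  }
  H
}

# eigenvalues of symmetric 3x3 matrices, vectorised (trigonometric method);
# returns list(e1, e2, e3) unsorted
sym3_eigenvalues <- function(xx, yy, zz, xy, xz, yz) {
  q <- (xx + yy + zz) / 3
  a <- xx - q; b <- yy - q; c <- zz - q
  p2 <- (a^2 + b^2 + c^2 + 2 * (xy^2 + xz^2 + yz^2)) / 6
  p <- sqrt(pmax(p2, 0))
  # det of (H - q I) / p
  detB <- (a * (b * c - yz^2) - xy * (xy * c - yz * xz) + xz * (xy * yz - b * xz))
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  list(e1, e2, e3)
}

#' Multiscale Frangi vesselness with a Frobenius-norm gate
#'
#' Hessian-eigenvalue ridge enhancement for bright tubular structures,
#' evaluated at each Gaussian scale and combined by the pixelwise maximum,
#' then normalised to `[0, 1]`. Before the vesselness response is computed at
#' each scale, voxels whose Hessian Frobenius norm falls below the square
#' root of the maximum Frobenius norm are assigned zero response (an
#' efficiency gate; disable with `gate = FALSE`). The gate presumes
#' count-scaled images (norms above 1); on the voxels that pass it, gated and
#' ungated responses are identical.
#'
#' @param frame single-channel matrix `[y, x]` or array `[y, x, z]` (or a 2D
#'   [image_volume()]).
#' @param scales Gaussian standard deviations in pixels (non-empty).
#' @param beta blobness sensitivity (2D and 3D).
#' @param alpha plate/line sensitivity (3D only).
#' @param gamma structureness scale; `NULL` uses half the maximum Frobenius
#'   norm at each scale.
#' @param gate apply the Frobenius-norm gate (default TRUE).
#' @param channel channel name for `ImageVolume` input.
#' @return Vesselness array in `[0, 1]`, same shape as the input.
#' @export
frangi_enhance <- function(frame, scales = c(1, 1.5, 2), beta = 0.5,
                           alpha = 0.5, gamma = NULL, gate = TRUE,
                           channel = NULL) {
  if (inherits(frame, "ImageVolume")) frame <- get_channel(frame, channel)
  if (length(scales) == 0L) stop("'scales' must contain at least one scale")
  d0 <- dim(frame)
  is3d <- length(d0) == 3L && d0[3L] > 1L
  best <- array(0, dim = d0)
  for (s in scales) {
    H <- hessian_fields(frame, s)
    if (!is3d) {
      frob <- sqrt(H$xx^2 + H$yy^2 + 2 * H$xy^2)
      tr <- H$xx + H$yy
      disc <- sqrt(pmax((H$xx - H$yy)^2 + 4 * H$xy^2, 0))
      ea <- (tr + disc) / 2; eb <- (tr - disc) / 2
      big <- ifelse(abs(ea) >= abs(eb), ea, eb)   # |lambda2| >= |lambda1|
      small <- ifelse(abs(ea) >= abs(eb), eb, ea)
      c2 <- if (is.null(gamma)) pmax(max(frob) / 2, .Machine$double.eps) else gamma
      rb2 <- (small / big)^2
      rb2[!is.finite(rb2)] <- 0
      v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-frob^2 / (2 * c2^2)))
      v[big >= 0] <- 0                            # bright ridges only
    } else {
      frob <- sqrt(H$xx^2 + H$yy^2 + H$zz^2 + 2 * (H$xy^2 + H$xz^2 + H$yz^2))
      ev <- sym3_eigenvalues(H$xx, H$yy, H$zz, H$xy, H$xz, H$yz)
      abs_ev <- lapply(ev, abs)
      # sort by |lambda|: l1 smallest ... l3 largest, per voxel
      n <- length(ev[[1L]])
      m <- cbind(as.numeric(ev[[1L]]), as.numeric(ev[[2L]]), as.numeric(ev[[3L]]))
      o <- t(apply(abs(m), 1L, order))
      l1 <- m[cbind(seq_len(n), o[, 1L])]
      l2 <- m[cbind(seq_len(n), o[, 2L])]
      l3 <- m[cbind(seq_len(n), o[, 3L])]
      ra2 <- (l2 / l3)^2; ra2[!is.finite(ra2)] <- 0
      rb2 <- l1^2 / pmax(abs(l2 * l3), .Machine$double.eps)
      c2 <- if (is.null(gamma)) pmax(max(frob) / 2, .Machine$double.eps) else gamma
      v <- (1 - exp(-ra2 / (2 * alpha^2))) * exp(-rb2 / (2 * beta^2)) *
        (1 - exp(-as.numeric(frob)^2 / (2 * c2^2)))
      v[l2 >= 0 | l3 >= 0] <- 0
      v <- array(v, dim = d0)
    }
    if (gate) {
      gate_thr <- sqrt(max(frob))
      v[frob < gate_thr] <- 0
    }
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  best
}

#' Semantic mitochondrial mask from a vesselness map
#'
#' Every voxel of the normalised Frangi response above the threshold
#' (default 1e-5) is kept as a mitochondrial voxel.
#'
#' @param vesselness array in `[0, 1]` from [frangi_enhance()].
#' @param tau semantic threshold.
#' @return Logical mask of the same shape.
#' @export
semantic_mask <- function(vesselness, tau = 1e-5) {
  if (min(vesselness) < 0 || max(vesselness) > 1 + 1e-12) {
    stop("vesselness must be normalised to [0, 1]")
  }
  vesselness > tau
}

#' Instance segmentation of a binary mask
#'
#' Connected components (8-connectivity in 2D, 26 in 3D) of the semantic
#' mask, one label per mitochondrion.
#'
#' @param mask logical matrix or array.
#' @param voxel_size physical voxel sizes (stored in the result).
#' @return A `LabelVolume`.
#' @export
instance_segment <- function(mask, voxel_size = c(x = 1, y = 1, z = 1)) {
  labels <- label_components(mask)
  structure(list(labels = labels, voxel_size = unlist(voxel_size),
                 threshold = NA_real_, clean_min_voxels = 1L),
            class = "LabelVolume")
}
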