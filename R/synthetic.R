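#' Synthetic microscopy scene configuration
#'
#' Describes one synthetic cell: a convex cell region containing tubular
#' mitochondria (persistent random walks dilated to capsules), optional
#' diffraction-limited puncta, MDV-sized single-cargo spots and
#' Parkin-style patches, imaged with a Gaussian point-spread function,
#' photon (Poisson) noise, Gaussian read noise and a camera baseline.
#'
#' Amplitudes are expressed in units of `photon_scale`: a structure of
#' amplitude `a` contributes an expected `a * photon_scale` counts per voxel
#' before noise. Tubes and patches are rasterised densities convolved with
#' the PSF; puncta are point emitters and are therefore rendered directly as
#' PSF-shaped Gaussians.
#'
#' @param grid_shape named integer vector `c(y=, x=, z=)`, voxels (`z = 1`
#'   gives a 2D scene).
#' @param voxel_size named numeric `c(x=, y=, z=)`, um per voxel; z may exceed
#'   the lateral sizes (anisotropic stacks).
#' @param n_mito number of mitochondrial tubes.
#' @param tube_radius tube radius, um.
#' @param tube_length_meanlog,tube_length_sdlog lognormal tube length
#'   parameters (um).
#' @param persistence direction persistence of the generating random walk and
#'   of time-lapse motion, in `[0, 1]` (1 = straight).
#' @param tube_amplitude emitter density inside tubes.
#' @param cyto_level diffuse cytoplasmic emitter density inside the cell mask
#'   (gives puncta a positive local background).
#' @param puncta_rate expected puncta per cell for each puncta channel.
#' @param puncta_channels channel names receiving puncta at `puncta_rate`.
#' @param puncta_amplitude peak amplitude of puncta.
#' @param mdv_rate expected MDV-sized spots per cell.
#' @param mdv_cargo_probs probabilities that an MDV carries only the first
#'   cargo, only the second, or both; named `c(A=, B=, dual=)`, summing to 1.
#' @param mdv_channels the two cargo channel names.
#' @param mdv_amplitude peak amplitude of MDV spots.
#' @param parkin_area_fraction fraction of the cell area covered by bright
#'   Parkin patches (0 disables the channel).
#' @param parkin_patch_radius nominal patch radius, um.
#' @param parkin_amplitude emitter density inside patches.
#' @param tube_channels channel names in which tubes are rendered.
#' @param z_wiggle standard deviation of the walk's per-step axial drift, as a
#'   fraction of the lateral step (0 keeps tubes in one focal plane).
#' @param psf_sigma named numeric `c(lateral=, axial=)`, Gaussian PSF standard
#'   deviations in um.
#' @param photon_scale expected counts per unit emitter density; 0 disables
#'   signal entirely.
#' @param read_noise_sigma Gaussian read noise standard deviation, counts.
#' @param baseline camera offset added after photon sampling, counts.
#' @param shot_noise logical; set `FALSE` for a noiseless (expected-value)
#'   render. Read noise is still controlled by `read_noise_sigma`.
#' @param min_separation minimum distance between tube start points, um
#'   (0 disables the spacing constraint).
#' @param seed integer seed; identical `(config, seed)` pairs reproduce
#'   identical scenes bit for bit.
#'
#' @return A list of class `SceneConfig`.
#' @seealso [scene_preset()], [generate_scene()], [generate_timelapse()]
#' @export
scene_config <- function(grid_shape = c(y = 128, x = 128, z = 1),
                         voxel_size = c(x = 0.1, y = 0.1, z = 0.3),
                         n_mito = 0,
                         tube_radius = 0.15,
                         tube_length_meanlog = log(1.5),
                         tube_length_sdlog = 0.3,
                         persistence = 0.9,
                         tube_amplitude = 1.5,
                         cyto_level = 0.1,
                         puncta_rate = 0,
                         puncta_channels = character(0),
                         puncta_amplitude = 6,
                         mdv_rate = 0,
                         mdv_cargo_probs = c(A = 0.45, B = 0.45, dual = 0.1),
                         mdv_channels = c("tom20", "pdh"),
                         mdv_amplitude = 6,
                         parkin_area_fraction = 0,
                         parkin_patch_radius = 0.25,
                         parkin_amplitude = 6,
                         tube_channels = "tom20",
                         z_wiggle = 0.2,
                         psf_sigma = c(lateral = 0.08, axial = 0.25),
                         photon_scale = 50,
                         read_noise_sigma = 2,
                         baseline = 100,
                         shot_noise = TRUE,
                         min_separation = 0,
                         seed = 1L) {
  cfg <- as.list(environment())
  cfg$grid_shape <- round(unlist(grid_shape)[c("y", "x", "z")])
  cfg$voxel_size <- unlist(voxel_size)[c("x", "y", "z")]
  cfg$psf_sigma <- unlist(psf_sigma)[c("lateral", "axial")]
  validate_scene_config(cfg)
  structure(cfg, class = "SceneConfig")
}

validate_scene_config <- function(cfg) {
  if (any(is.na(cfg$grid_shape)) || any(cfg$grid_shape < 1)) {
    stop("grid_shape must contain positive y, x, z voxel counts")
  }
  if (any(is.na(cfg$voxel_size)) || any(cfg$voxel_size <= 0)) {
    stop("voxel sizes must be positive")
  }
  for (f in c("n_mito", "puncta_rate", "mdv_rate", "parkin_area_fraction",
              "cyto_level", "photon_scale", "read_noise_sigma", "baseline",
              "min_separation", "z_wiggle")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || !is.finite(cfg[[f]]) ||
        cfg[[f]] < 0) stop("'", f, "' must be a single non-negative number")
  }
  if (cfg$persistence < 0 || cfg$persistence > 1) stop("persistence must lie in [0, 1]")
  if (cfg$tube_radius <= 0) stop("tube_radius must be positive")
  if (any(cfg$psf_sigma <= 0)) stop("psf_sigma must be positive")
  if (abs(sum(cfg$mdv_cargo_probs) - 1) > 1e-8 || any(cfg$mdv_cargo_probs < 0)) {
    stop("mdv_cargo_probs must be non-negative and sum to 1")
  }
  if (length(cfg$mdv_channels) != 2L) stop("mdv_channels must name two channels")
  if (cfg$puncta_rate > 0 && length(cfg$puncta_channels) == 0L) {
    stop("puncta_rate > 0 requires at least one puncta channel name")
  }
  if (cfg$n_mito > 0) {
    extent <- (cfg$grid_shape[c("x", "y")]) * cfg$voxel_size[c("x", "y")]
    need <- exp(cfg$tube_length_meanlog) + 2 * cfg$tube_radius + 1
    if (min(extent) < need) {
      stop("grid too small to contain one tube at the requested length: ",
           "field extent ", signif(min(extent), 3), " um < required ",
           signif(need, 3), " um")
    }
  }
  invisible(cfg)
}

# Deterministic substreams: object classes draw from independent seeds so
# that, e.g., changing puncta_rate never perturbs tube geometry. The (seed,
# stream) pair is scrambled with a multiplicative hash and the generator is
# warmed up, so that scenes with consecutive seeds draw decorrelated values.
with_stream <- function(seed, stream_id, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  h <- (abs(as.numeric(seed)) * 2654435761 + as.numeric(stream_id) * 40503) %%
    2147483647
  set.seed(as.integer(h))
  invisible(runif(25L))                     # warm-up draws
  expr
}

STREAM_CELL <- 1L; STREAM_TUBES <- 2L; STREAM_PUNCTA <- 3L
STREAM_MDV <- 4L; STREAM_PARKIN <- 5L; STREAM_NOISE <- 6L; STREAM_MOTION <- 7L

# --- geometry helpers --------------------------------------------------------

# Elliptical (convex) cell region. Returns the parametric ellipse and a
# logical [y, x] mask.
make_cell_mask <- function(cfg) {
  ny <- cfg$grid_shape[["y"]]; nx <- cfg$grid_shape[["x"]]
  Lx <- nx * cfg$voxel_size[["x"]]; Ly <- ny * cfg$voxel_size[["y"]]
  jitter <- with_stream(cfg$seed, STREAM_CELL, runif(2, 0.92, 1.0))
  semi <- c(x = 0.42 * Lx * jitter[1], y = 0.40 * Ly * jitter[2])
  center <- c(x = Lx / 2, y = Ly / 2)
  xs <- voxel_centers(nx, cfg$voxel_size[["x"]])
  ys <- voxel_centers(ny, cfg$voxel_size[["y"]])
  mask <- outer(((ys - center["y"]) / semi["y"])^2,
                ((xs - center["x"]) / semi["x"])^2, `+`) <= 1
  list(center = center, semi = semi, mask = mask)
}

inside_cell <- function(cell, x, y, margin = 0) {
  sx <- pmax(cell$semi["x"] - margin, 1e-6)
  sy <- pmax(cell$semi["y"] - margin, 1e-6)
  ((x - cell$center["x"]) / sx)^2 + ((y - cell$center["y"]) / sy)^2 <= 1
}

# n points uniform in the cell ellipse eroded by `margin` (um)
sample_in_cell <- function(cell, n, margin = 0) {
  out <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("x", "y")))
  k <- 0L
  while (k < n) {
    m <- 2L * (n - k) + 8L
    x <- runif(m, cell$center["x"] - cell$semi["x"], cell$center["x"] + cell$semi["x"])
    y <- runif(m, cell$center["y"] - cell$semi["y"], cell$center["y"] + cell$semi["y"])
    ok <- which(inside_cell(cell, x, y, margin))
    if (length(ok)) {
      take <- ok[seq_len(min(length(ok), n - k))]
      out[k + seq_along(take), ] <- cbind(x[take], y[take])
      k <- k + length(take)
    }
  }
  out
}

rand_unit2 <- function() { a <- runif(1, 0, 2 * pi); c(cos(a), sin(a)) }

# Persistent random-walk polyline inside the cell (coordinates in um).
# Returns a matrix with columns x, y, z.
walk_polyline <- function(cfg, cell, start, length_um, z0) {
  step <- min(cfg$voxel_size[c("x", "y")])
  n_step <- max(1L, round(length_um / step))
  p <- cfg$persistence
  dir2 <- rand_unit2()
  zspan <- cfg$grid_shape[["z"]] * cfg$voxel_size[["z"]]
  dz_scale <- if (cfg$grid_shape[["z"]] > 1) cfg$z_wiggle else 0
  pts <- matrix(NA_real_, n_step + 1L, 3L, dimnames = list(NULL, c("x", "y", "z")))
  pts[1L, ] <- c(start[["x"]], start[["y"]], z0)
  z <- z0
  for (i in seq_len(n_step)) {
    dir2 <- p * dir2 + (1 - p) * rand_unit2()
    dir2 <- dir2 / sqrt(sum(dir2^2))
    prop <- pts[i, 1:2] + dir2 * step
    if (!inside_cell(cell, prop[1], prop[2], margin = cfg$tube_radius + 0.1)) {
      # reflect: point the walk back toward the cell centre
      to_c <- c(cell$center["x"], cell$center["y"]) - pts[i, 1:2]
      dir2 <- to_c / sqrt(sum(to_c^2))
      prop <- pts[i, 1:2] + dir2 * step
    }
    if (dz_scale > 0) {
      z <- z + rnorm(1, 0, dz_scale * step)
      zmin <- min(3 * cfg$psf_sigma[["axial"]], zspan / 2 - 1e-3)
      z <- min(max(z, zmin), zspan - zmin)
    }
    pts[i + 1L, ] <- c(prop, z)
  }
  pts
}

# Voxel indices (1-based, [y, x, z]) whose centres lie within `radius` um of
# the polyline (capsule union). Distances are physical, so anisotropic z is
# handled naturally.
rasterize_tube <- function(polyline, grid_shape, voxel_size, radius) {
  ny <- grid_shape[["y"]]; nx <- grid_shape[["x"]]; nz <- grid_shape[["z"]]
  vx <- voxel_size[["x"]]; vy <- voxel_size[["y"]]; vz <- voxel_size[["z"]]
  hits <- new.env(hash = TRUE, size = 1024L)
  n <- nrow(polyline)
  segs <- if (n >= 2L) seq_len(n - 1L) else integer(0)
  add_box <- function(p0, p1) {
    lo <- pmin(p0, p1) - radius; hi <- pmax(p0, p1) + radius
    ix <- max(1L, ceiling(lo[1] / vx + 0.5)):min(nx, floor(hi[1] / vx + 0.5))
    iy <- max(1L, ceiling(lo[2] / vy + 0.5)):min(ny, floor(hi[2] / vy + 0.5))
    iz <- max(1L, ceiling(lo[3] / vz + 0.5)):min(nz, floor(hi[3] / vz + 0.5))
    if (!length(ix) || !length(iy) || !length(iz)) return(invisible())
    g <- expand.grid(y = iy, x = ix, z = iz, KEEP.OUT.ATTRS = FALSE)
    cx <- (g$x - 0.5) * vx; cy <- (g$y - 0.5) * vy; cz <- (g$z - 0.5) * vz
    d <- p1 - p0
    dd <- sum(d^2)
    if (dd < 1e-12) {
      t <- 0
      px <- p0[1]; py <- p0[2]; pz <- p0[3]
      d2 <- (cx - px)^2 + (cy - py)^2 + (cz - pz)^2
    } else {
      t <- pmin(1, pmax(0, ((cx - p0[1]) * d[1] + (cy - p0[2]) * d[2] +
                              (cz - p0[3]) * d[3]) / dd))
      d2 <- (cx - (p0[1] + t * d[1]))^2 + (cy - (p0[2] + t * d[2]))^2 +
        (cz - (p0[3] + t * d[3]))^2
    }
    sel <- which(d2 <= radius^2)
    for (j in sel) {
      key <- sprintf("%d_%d_%d", g$y[j], g$x[j], g$z[j])
      if (is.null(hits[[key]])) hits[[key]] <- c(g$y[j], g$x[j], g$z[j])
    }
    invisible()
  }
  if (length(segs)) {
    for (s in segs) add_box(polyline[s, ], polyline[s + 1L, ])
  } else {
    add_box(polyline[1L, ], polyline[1L, ])
  }
  keys <- ls(hits)
  if (!length(keys)) {
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("y", "x", "z"))))
  }
  out <- t(vapply(keys, function(k) hits[[k]], integer(3) + 0))
  colnames(out) <- c("y", "x", "z")
  out
}

# separable Gaussian blur; sigma in voxels per axis (y,x,z). Zero padding
# conserves total mass (scene rendering); replicate padding avoids border
# cliffs (derivative filters).
gaussian_blur <- function(arr, sigma_vox, pad = c("zero", "replicate")) {
  pad <- match.arg(pad)
  d <- dim(arr)
  if (length(d) == 2L) d <- c(d, 1L)
  out <- array(arr, dim = d)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (is.na(s) || s <= 0 || d[axis] == 1L) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    acc <- array(0, dim = d)
    for (j in seq(-r, r)) {
      w <- k[j + r + 1L]
      src_idx <- seq_len(d[axis]) - j
      if (pad == "zero") {
        valid <- src_idx >= 1L & src_idx <= d[axis]
        idx_dst <- which(valid)
        idx_src <- src_idx[valid]
      } else {
        idx_dst <- seq_len(d[axis])
        idx_src <- pmin(pmax(src_idx, 1L), d[axis])
      }
      if (axis == 1L) acc[idx_dst, , ] <- acc[idx_dst, , ] + w * out[idx_src, , ]
      if (axis == 2L) acc[, idx_dst, ] <- acc[, idx_dst, ] + w * out[, idx_src, ]
      if (axis == 3L) acc[, , idx_dst] <- acc[, , idx_dst] + w * out[, , idx_src]
    }
    out <- acc
  }
  if (length(dim(arr)) == 2L) dim(out) <- dim(arr)
  out
}

# add anisotropic Gaussian emitters (point sources as seen through the PSF)
# into `arr` [y, x, z]; centers in um, columns x, y, z
add_gaussians <- function(arr, centers, amplitudes, sigma_um, voxel_size) {
  d <- dim(arr)
  vx <- voxel_size[["x"]]; vy <- voxel_size[["y"]]; vz <- voxel_size[["z"]]
  sx <- sigma_um[["lateral"]]; sy <- sigma_um[["lateral"]]; sz <- sigma_um[["axial"]]
  for (i in seq_len(nrow(centers))) {
    cx <- centers[i, "x"]; cy <- centers[i, "y"]
    cz <- if ("z" %in% colnames(centers)) centers[i, "z"] else (d[3] / 2) * vz
    ix <- max(1L, floor((cx - 4 * sx) / vx)):min(d[2], ceiling((cx + 4 * sx) / vx))
    iy <- max(1L, floor((cy - 4 * sy) / vy)):min(d[1], ceiling((cy + 4 * sy) / vy))
    iz <- if (d[3] == 1L) 1L else {
      max(1L, floor((cz - 4 * sz) / vz)):min(d[3], ceiling((cz + 4 * sz) / vz))
    }
    gx <- exp(-(((ix - 0.5) * vx - cx)^2) / (2 * sx^2))
    gy <- exp(-(((iy - 0.5) * vy - cy)^2) / (2 * sy^2))
    gz <- if (d[3] == 1L) 1 else exp(-(((iz - 0.5) * vz - cz)^2) / (2 * sz^2))
    blob <- array(amplitudes[i] * outer(outer(gy, gx), gz),
                  dim = c(length(iy), length(ix), length(iz)))
    arr[iy, ix, iz] <- arr[iy, ix, iz, drop = FALSE] + blob
  }
  arr
}

# camera model: photon noise, baseline, read noise (drawn from STREAM_NOISE
# by the caller)
apply_camera <- function(signal_counts, cfg) {
  d <- dim(signal_counts)
  out <- if (cfg$shot_noise && cfg$photon_scale > 0) {
    array(rpois(length(signal_counts), lambda = pmax(signal_counts, 0)), dim = d)
  } else {
    signal_counts
  }
  out <- out + cfg$baseline
  if (cfg$read_noise_sigma > 0) {
    out <- out + array(rnorm(length(out), 0, cfg$read_noise_sigma), dim = d)
  }
  pmax(out, 0)
}

# --- scene assembly ----------------------------------------------------------

# Build the noiseless per-channel expected signal (counts, before baseline)
# plus ground truth. Used by both generate_scene and generate_timelapse.
build_scene_signal <- function(cfg, polylines = NULL) {
  ny <- cfg$grid_shape[["y"]]; nx <- cfg$grid_shape[["x"]]; nz <- cfg$grid_shape[["z"]]
  vx <- cfg$voxel_size[["x"]]; vy <- cfg$voxel_size[["y"]]; vz <- cfg$voxel_size[["z"]]
  voxvol <- vx * vy * vz
  cell <- make_cell_mask(cfg)
  sigma_vox <- c(y = cfg$psf_sigma[["lateral"]] / vy,
                 x = cfg$psf_sigma[["lateral"]] / vx,
                 z = if (nz > 1) cfg$psf_sigma[["axial"]] / vz else 0)

  channels <- character(0)
  if (cfg$n_mito > 0) channels <- union(channels, cfg$tube_channels)
  if (cfg$puncta_rate > 0) channels <- union(channels, cfg$puncta_channels)
  if (cfg$mdv_rate > 0) channels <- union(channels, cfg$mdv_channels)
  if (cfg$parkin_area_fraction > 0) channels <- union(channels, "parkin")
  if (length(channels) == 0L) channels <- "ch1"

  density <- setNames(lapply(channels, function(ch) array(0, c(ny, nx, nz))), channels)
  spots <- setNames(lapply(channels, function(ch) {
    list(centers = matrix(0, 0, 3, dimnames = list(NULL, c("x", "y", "z"))),
         amplitudes = numeric(0))
  }), channels)

  objects <- list()
  total_integral <- 0
  zc <- (nz / 2) * vz

  # diffuse cytoplasm in every channel
  if (cfg$cyto_level > 0) {
    cyto <- array(0, c(ny, nx, nz))
    for (k in seq_len(nz)) cyto[, , k] <- cfg$cyto_level * cell$mask
    for (ch in channels) density[[ch]] <- density[[ch]] + cyto
    total_integral <- total_integral +
      length(channels) * cfg$cyto_level * sum(cell$mask) * nz * cfg$photon_scale
  }

  # tubes
  tube_voxels <- list()
  if (cfg$n_mito > 0) {
    if (is.null(polylines)) {
      polylines <- with_stream(cfg$seed, STREAM_TUBES, {
        lens <- rlnorm(cfg$n_mito, cfg$tube_length_meanlog, cfg$tube_length_sdlog)
        starts <- sample_starts(cfg, cell)
        z0 <- if (nz > 1) {
          runif(cfg$n_mito, zc - 0.25 * nz * vz, zc + 0.25 * nz * vz)
        } else rep(zc, cfg$n_mito)
        lapply(seq_len(cfg$n_mito), function(i) {
          walk_polyline(cfg, cell, starts[i, ], lens[i], z0[i])
        })
      })
    }
    for (i in seq_along(polylines)) {
      vox <- rasterize_tube(polylines[[i]], cfg$grid_shape, cfg$voxel_size,
                            cfg$tube_radius)
      tube_voxels[[i]] <- vox
      if (nrow(vox) == 0L) next
      idx <- cbind(vox[, "y"], vox[, "x"], vox[, "z"])
      for (ch in intersect(cfg$tube_channels, channels)) {
        density[[ch]][idx] <- density[[ch]][idx] + cfg$tube_amplitude
      }
      ax <- axis_lengths(vox[, c("y", "x", "z"), drop = FALSE], cfg$voxel_size)
      ctr <- c(mean((vox[, "x"] - 0.5) * vx), mean((vox[, "y"] - 0.5) * vy),
               mean((vox[, "z"] - 0.5) * vz))
      objects[[length(objects) + 1L]] <- data.frame(
        id = length(objects) + 1L, type = "tube",
        channel = paste(intersect(cfg$tube_channels, channels), collapse = ";"),
        x = ctr[1], y = ctr[2], z = ctr[3],
        volume_um3 = nrow(vox) * voxvol,
        a1 = ax[1], a2 = ax[2], a3 = ax[3],
        elongation = elongation(ax[1], ax[2], ax[3]),
        amplitude = cfg$tube_amplitude, cargo = NA_character_,
        integral = nrow(vox) * cfg$tube_amplitude * cfg$photon_scale *
          length(intersect(cfg$tube_channels, channels))
      )
      total_integral <- total_integral + objects[[length(objects)]]$integral
    }
  }

  # spot integral helper (counts) for a PSF-shaped Gaussian of peak `a`
  spot_integral <- function(a) {
    lat <- cfg$psf_sigma[["lateral"]]
    g <- a * cfg$photon_scale * (2 * pi * lat^2) / (vx * vy)
    if (nz > 1) g <- g * sqrt(2 * pi) * cfg$psf_sigma[["axial"]] / vz
    g
  }

  # diffraction-limited puncta (e.g. LC3, mCherry-only mitolysosomes)
  if (cfg$puncta_rate > 0) {
    with_stream(cfg$seed, STREAM_PUNCTA, {
      n <- rpois(1, cfg$puncta_rate)
      if (n > 0) {
        pos <- sample_in_cell(cell, n, margin = 0.5)
        amp <- cfg$puncta_amplitude * exp(rnorm(n, 0, 0.15))
        zpos <- if (nz > 1) runif(n, zc - 0.15, zc + 0.15) else rep(zc, n)
        for (ch in cfg$puncta_channels) {
          spots[[ch]]$centers <- rbind(spots[[ch]]$centers,
                                       cbind(x = pos[, "x"], y = pos[, "y"], z = zpos))
          spots[[ch]]$amplitudes <- c(spots[[ch]]$amplitudes, amp)
        }
        for (i in seq_len(n)) {
          objects[[length(objects) + 1L]] <- data.frame(
            id = length(objects) + 1L, type = "punctum",
            channel = paste(cfg$puncta_channels, collapse = ";"),
            x = pos[i, "x"], y = pos[i, "y"], z = zpos[i],
            volume_um3 = NA_real_, a1 = NA_real_, a2 = NA_real_, a3 = NA_real_,
            elongation = NA_real_, amplitude = amp[i], cargo = NA_character_,
            integral = spot_integral(amp[i]) * length(cfg$puncta_channels)
          )
          total_integral <- total_integral + objects[[length(objects)]]$integral
        }
      }
    })
  }

  # MDV-sized single-cargo spots
  if (cfg$mdv_rate > 0) {
    with_stream(cfg$seed, STREAM_MDV, {
      n <- rpois(1, cfg$mdv_rate)
      if (n > 0) {
        pos <- sample_in_cell(cell, n, margin = 0.5)
        zpos <- if (nz > 1) runif(n, zc - 0.15, zc + 0.15) else rep(zc, n)
        cargo <- sample(names(cfg$mdv_cargo_probs), n, replace = TRUE,
                        prob = cfg$mdv_cargo_probs)
        for (i in seq_len(n)) {
          chs <- switch(cargo[i],
                        A = cfg$mdv_channels[1L],
                        B = cfg$mdv_channels[2L],
                        dual = cfg$mdv_channels)
          for (ch in chs) {
            spots[[ch]]$centers <- rbind(spots[[ch]]$centers,
                                         cbind(x = pos[i, "x"], y = pos[i, "y"], z = zpos[i]))
            spots[[ch]]$amplitudes <- c(spots[[ch]]$amplitudes, cfg$mdv_amplitude)
          }
          objects[[length(objects) + 1L]] <- data.frame(
            id = length(objects) + 1L, type = "mdv",
            channel = paste(chs, collapse = ";"),
            x = pos[i, "x"], y = pos[i, "y"], z = zpos[i],
            volume_um3 = NA_real_, a1 = NA_real_, a2 = NA_real_, a3 = NA_real_,
            elongation = NA_real_, amplitude = cfg$mdv_amplitude,
            cargo = cargo[i],
            integral = spot_integral(cfg$mdv_amplitude) * length(chs)
          )
          total_integral <- total_integral + objects[[length(objects)]]$integral
        }
      }
    })
  }

  # Parkin-style patches: a deterministic area budget (fraction of the cell
  # area) split over near-equal disks, so the generated positive area is the
  # configured fraction exactly
  if (cfg$parkin_area_fraction > 0) {
    with_stream(cfg$seed, STREAM_PARKIN, {
      cell_area <- sum(cell$mask) * vx * vy
      budget <- cfg$parkin_area_fraction * cell_area
      nominal <- pi * cfg$parkin_patch_radius^2
      k <- max(1L, ceiling(budget / nominal))
      r <- sqrt(budget / (k * pi))
      pos <- sample_in_cell(cell, k, margin = r + 0.5)
      xs <- voxel_centers(nx, vx); ys <- voxel_centers(ny, vy)
      for (i in seq_len(k)) {
        disk <- outer((ys - pos[i, "y"])^2, (xs - pos[i, "x"])^2, `+`) <= r^2
        nvox <- sum(disk)
        for (kk in seq_len(nz)) {
          density[["parkin"]][, , kk] <- density[["parkin"]][, , kk] +
            cfg$parkin_amplitude * disk
        }
        objects[[length(objects) + 1L]] <- data.frame(
          id = length(objects) + 1L, type = "patch", channel = "parkin",
          x = pos[i, "x"], y = pos[i, "y"], z = zc,
          volume_um3 = nvox * voxvol, a1 = NA_real_, a2 = NA_real_, a3 = NA_real_,
          elongation = NA_real_, amplitude = cfg$parkin_amplitude,
          cargo = NA_character_,
          integral = nvox * nz * cfg$parkin_amplitude * cfg$photon_scale
        )
        total_integral <- total_integral + objects[[length(objects)]]$integral
      }
    })
  }

  # optics: densities see the PSF; puncta are already PSF-shaped
  signal <- setNames(vector("list", length(channels)), channels)
  for (ch in channels) {
    s <- gaussian_blur(density[[ch]], sigma_vox)
    if (nrow(spots[[ch]]$centers)) {
      s <- add_gaussians(s, spots[[ch]]$centers, spots[[ch]]$amplitudes,
                         cfg$psf_sigma, cfg$voxel_size)
    }
    signal[[ch]] <- s * cfg$photon_scale
  }

  truth <- list(
    objects = if (length(objects)) do.call(rbind, objects) else data.frame(),
    cell_mask = cell$mask,
    cell = cell[c("center", "semi")],
    total_integral = total_integral,
    tube_voxels = tube_voxels,
    polylines = polylines
  )
  list(signal = signal, truth = truth, channels = channels)
}

# tube start points; optional minimum pairwise separation via rejection
# sampling with restarts (a bad early placement must not wedge the sampler)
sample_starts <- function(cfg, cell) {
  n <- cfg$n_mito
  if (cfg$min_separation <= 0) return(sample_in_cell(cell, n, margin = cfg$tube_radius + 0.3))
  for (restart in 1:50) {
    pts <- matrix(NA_real_, 0, 2, dimnames = list(NULL, c("x", "y")))
    tries <- 0L
    while (nrow(pts) < n && tries < 400L) {
      cand <- sample_in_cell(cell, 1L, margin = cfg$tube_radius + 0.3)
      ok <- nrow(pts) == 0L ||
        min(sqrt((pts[, 1] - cand[1, 1])^2 + (pts[, 2] - cand[1, 2])^2)) >=
          cfg$min_separation
      if (ok) pts <- rbind(pts, cand)
      tries <- tries + 1L
    }
    if (nrow(pts) == n) return(pts)
  }
  stop("could not place ", n, " tubes at min_separation = ",
       cfg$min_separation, " um in this field")
}

#' Generate one synthetic multi-channel scene with ground truth
#'
#' Renders mitochondrial tubes (persistent random walks dilated to capsules of
#' `tube_radius`; a voxel is foreground when its centre lies within the radius
#' of the polyline), diffraction-limited puncta, single-cargo MDV-sized spots
#' and Parkin-style patches, then applies the Gaussian PSF, scales to expected
#' photon counts, Poisson-samples, and adds the camera baseline and Gaussian
#' read noise. Ground truth describes every object before blur and noise.
#'
#' @param config a [scene_config()] (or [scene_preset()]).
#' @return A list with elements `volume` (an [image_volume()]) and `truth`
#'   (ground-truth list: `objects` data frame with true volume, principal axis
#'   lengths, elongation, amplitude, cargo and analytic intensity integral per
#'   object; `cell_mask`; `total_integral`; per-tube voxel coordinates).
#' @examples
#' sc <- generate_scene(scene_config(n_mito = 2, seed = 7))
#' sc$truth$objects[, c("type", "volume_um3", "elongation")]
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "SceneConfig"))
  built <- build_scene_signal(config)
  img <- with_stream(config$seed, STREAM_NOISE, {
    lapply(built$signal, apply_camera, cfg = config)
  })
  nz <- config$grid_shape[["z"]]
  channels <- lapply(img, function(a) if (nz == 1L) a[, , 1L] else a)
  vs <- if (nz == 1L) config$voxel_size[c("x", "y")] else config$voxel_size
  list(volume = image_volume(channels, voxel_size = vs),
       truth = built$truth,
       config = config)
}

#' Generate a synthetic time-lapse with ground-truth tracks
#'
#' Each mitochondrion from the base scene translates rigidly between frames:
#' its speed is drawn once per object from `speed_dist` and its direction
#' evolves with the configured persistence; displacement per frame is
#' `speed * frame_interval`. Motion reflects off the cell boundary. An
#' optional multiplicative intensity decay per frame models photobleaching.
#'
#' @param config a [scene_config()] with `n_mito > 0`.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval seconds between frames (> 0).
#' @param speed_dist function `n -> n speeds` in um/s; the default lognormal
#'   (median 0.08 um/s, log-sd 0.3) matches reported mitochondrial speeds in
#'   cultured cells.
#' @param bleach multiplicative intensity decay per frame (1 = none).
#' @return A list with `timelapse` (an [image_timelapse()]) and `truth`
#'   (including `tracks`: one row per object per frame with true centroid and
#'   per-frame displacement components in um).
#' @export
generate_timelapse <- function(config, n_frames, frame_interval,
                               speed_dist = function(n) rlnorm(n, log(0.08), 0.3),
                               bleach = 1.0) {
  stopifnot(inherits(config, "SceneConfig"))
  if (config$n_mito < 1) stop("time-lapse generation requires n_mito >= 1")
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) stop("n_frames must be >= 2")
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive")
  }

  base <- build_scene_signal(config)   # frame 1 (also fixes tube geometry)
  polylines <- base$truth$polylines
  cell <- list(center = base$truth$cell$center, semi = base$truth$cell$semi)
  n_obj <- length(polylines)

  motion <- with_stream(config$seed, STREAM_MOTION, {
    speeds <- speed_dist(n_obj)
    dirs <- t(vapply(seq_len(n_obj), function(i) rand_unit2(), numeric(2)))
    steps <- vector("list", n_frames - 1L)
    poly_t <- polylines
    disp <- array(0, c(n_obj, 2, n_frames - 1L))
    p <- config$persistence
    for (f in seq_len(n_frames - 1L)) {
      for (i in seq_len(n_obj)) {
        dirs[i, ] <- dirs[i, ] * p + (1 - p) * rand_unit2()
        dirs[i, ] <- dirs[i, ] / sqrt(sum(dirs[i, ]^2))
        d <- dirs[i, ] * speeds[i] * frame_interval
        ctr <- colMeans(poly_t[[i]][, 1:2, drop = FALSE])
        if (!inside_cell(cell, ctr[1] + d[1], ctr[2] + d[2],
                         margin = config$tube_radius + 0.5)) {
          dirs[i, ] <- -dirs[i, ]
          d <- -d
        }
        poly_t[[i]][, 1] <- poly_t[[i]][, 1] + d[1]
        poly_t[[i]][, 2] <- poly_t[[i]][, 2] + d[2]
        disp[i, , f] <- d
      }
      steps[[f]] <- lapply(poly_t, identity)
    }
    list(speeds = speeds, steps = steps, disp = disp)
  })

  frame_signals <- vector("list", n_frames)
  frame_truth <- vector("list", n_frames)
  frame_signals[[1L]] <- base$signal
  frame_truth[[1L]] <- base$truth
  for (f in 2L:n_frames) {
    b <- build_scene_signal(config, polylines = motion$steps[[f - 1L]])
    frame_signals[[f]] <- lapply(b$signal, function(s) s * bleach^(f - 1L))
    frame_truth[[f]] <- b$truth
  }

  frames <- with_stream(config$seed, STREAM_NOISE, {
    lapply(frame_signals, function(sig) {
      img <- lapply(sig, apply_camera, cfg = config)
      nz <- config$grid_shape[["z"]]
      chs <- lapply(img, function(a) if (nz == 1L) a[, , 1L] else a)
      vs <- if (nz == 1L) config$voxel_size[c("x", "y")] else config$voxel_size
      image_volume(chs, voxel_size = vs, frame_interval = frame_interval)
    })
  })

  tracks <- do.call(rbind, lapply(seq_len(n_frames), function(f) {
    obj <- frame_truth[[f]]$objects
    obj <- obj[obj$type == "tube", , drop = FALSE]
    data.frame(frame = f, id = seq_len(nrow(obj)),
               x = obj$x, y = obj$y, z = obj$z,
               dx = if (f == 1L) 0 else motion$disp[, 1, f - 1L],
               dy = if (f == 1L) 0 else motion$disp[, 2, f - 1L],
               speed_true = motion$speeds)
  }))

  list(timelapse = image_timelapse(frames, frame_interval),
       truth = list(tracks = tracks, frames = frame_truth,
                    speeds = motion$speeds, cell_mask = base$truth$cell_mask),
       config = config)
}

#' Render a noiseless 2D Gaussian spot
#'
#' Utility for calibration fixtures such as FWHM linescans: a single isotropic
#' Gaussian of peak `amplitude` on an otherwise empty plane.
#'
#' @param center `c(x, y)` in um.
#' @param sigma Gaussian standard deviation, um (> 0).
#' @param amplitude peak value, counts.
#' @param plane_shape `c(y, x)` pixels.
#' @param pixel_size um per pixel.
#' @return An [image_volume()] with a single channel `"spot"`.
#' @examples
#' sp <- render_spot(c(1, 1), sigma = 0.0637, amplitude = 100,
#'                   plane_shape = c(101, 101), pixel_size = 0.02)
#' max(get_channel(sp, "spot"))
#' @export
render_spot <- function(center, sigma, amplitude, plane_shape, pixel_size) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be positive")
  ny <- plane_shape[1L]; nx <- plane_shape[2L]
  if (center[1L] < 0 || center[1L] > nx * pixel_size ||
      center[2L] < 0 || center[2L] > ny * pixel_size) {
    stop("spot center lies outside the requested grid")
  }
  xs <- voxel_centers(nx, pixel_size); ys <- voxel_centers(ny, pixel_size)
  plane <- amplitude * outer(exp(-(ys - center[2L])^2 / (2 * sigma^2)),
                             exp(-(xs - center[1L])^2 / (2 * sigma^2)))
  image_volume(list(spot = plane), voxel_size = c(x = pixel_size, y = pixel_size))
}
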