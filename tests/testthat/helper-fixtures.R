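# Analytic voxel rasterisers used as independent oracles -----------------------

# voxel indices (columns y, x, z) whose centres lie inside an axis-aligned
# solid ellipsoid; semi-axes and centre in um
rasterize_ellipsoid <- function(semi, center, grid, voxel_size) {
  g <- as.matrix(expand.grid(y = seq_len(grid[1]), x = seq_len(grid[2]),
                             z = seq_len(grid[3])))
  px <- (g[, "x"] - 0.5) * voxel_size[["x"]]
  py <- (g[, "y"] - 0.5) * voxel_size[["y"]]
  pz <- (g[, "z"] - 0.5) * voxel_size[["z"]]
  keep <- ((px - center[1]) / semi[1])^2 + ((py - center[2]) / semi[2])^2 +
    ((pz - center[3]) / semi[3])^2 <= 1
  g[keep, , drop = FALSE]
}

# voxel indices inside a capsule (segment p0-p1 dilated by radius), all in um
rasterize_capsule <- function(p0, p1, radius, grid, voxel_size) {
  g <- as.matrix(expand.grid(y = seq_len(grid[1]), x = seq_len(grid[2]),
                             z = seq_len(grid[3])))
  px <- (g[, "x"] - 0.5) * voxel_size[["x"]]
  py <- (g[, "y"] - 0.5) * voxel_size[["y"]]
  pz <- (g[, "z"] - 0.5) * voxel_size[["z"]]
  d <- p1 - p0
  dd <- sum(d^2)
  t <- if (dd == 0) rep(0, length(px)) else
    pmin(1, pmax(0, ((px - p0[1]) * d[1] + (py - p0[2]) * d[2] +
                       (pz - p0[3]) * d[3]) / dd))
  d2 <- (px - (p0[1] + t * d[1]))^2 + (py - (p0[2] + t * d[2]))^2 +
    (pz - (p0[3] + t * d[3]))^2
  g[d2 <= radius^2, , drop = FALSE]
}

# thin one-pixel Y-shaped skeleton mask (three straight arms, one junction)
make_y_mask <- function(n = 64) {
  m <- matrix(FALSE, n, n)
  cy <- n %/% 2
  m[cy, 10:(n %/% 2)] <- TRUE
  for (i in 1:15) {
    m[cy - i, n %/% 2 + i] <- TRUE
    m[cy + i, n %/% 2 + i] <- TRUE
  }
  m
}

# ground-truth link statistics for a tracked synthetic time-lapse:
# fraction of true frame-to-frame identity links recovered, plus
# per-object (true speed, recovered speed) pairs for long tracks
link_stats <- function(tl, res, frame_interval = 2, match_radius = 0.5) {
  gt <- tl$truth$tracks
  n_frames <- max(gt$frame)
  maps <- lapply(seq_len(n_frames), function(f) {
    fo <- res$frame_objects[[f]]
    g <- gt[gt$frame == f, ]
    if (nrow(fo) == 0L) return(integer(0))
    vapply(seq_len(nrow(fo)), function(i) {
      d <- sqrt((g$x - fo$centroid_x[i])^2 + (g$y - fo$centroid_y[i])^2)
      if (min(d) < match_radius) g$id[which.min(d)] else NA_integer_
    }, integer(1))
  })
  correct <- 0
  total <- (n_frames - 1L) * length(unique(gt$id))
  pair <- NULL
  for (tr in res$tracks) {
    if (nrow(tr) < 2L) next
    ids <- vapply(seq_len(nrow(tr)), function(k) maps[[tr$frame[k]]][tr$label[k]],
                  integer(1))
    for (k in seq_len(nrow(tr) - 1L)) {
      if (!is.na(ids[k]) && !is.na(ids[k + 1L]) && ids[k] == ids[k + 1L]) {
        correct <- correct + 1
      }
    }
    if (nrow(tr) >= n_frames / 2 && any(!is.na(ids))) {
      gid <- as.integer(names(sort(table(ids), decreasing = TRUE))[1L])
      pair <- rbind(pair, data.frame(
        gid = gid, recovered = track_metrics(tr, frame_interval)$mean_speed_um_s))
    }
  }
  list(recall = correct / total, pair = pair)
}

# brute-force minimum-cost assignment over all permutations (small n)
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(ncol(cost)))) {
    cc <- sum(cost[cbind(seq_len(n), p[seq_len(n)])])
    if (cc < best_cost) { best_cost <- cc; best <- p[seq_len(n)] }
  }
  list(assignment = best, cost = best_cost)
}
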