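# Hungarian algorithm (Jonker-style augmenting paths with potentials) for a
# dense rectangular cost matrix with nrow <= ncol. Returns, for each row, the
# assigned column. O(n^2 m).
hungarian_assign <- function(a) {
  n <- nrow(a); m <- ncol(a)
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  J0 <- m + 1L                     # virtual column
  u <- numeric(n)
  v <- numeric(m + 1L)
  p <- integer(m + 1L)             # p[j]: row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[J0] <- i
    j0 <- J0
    minv <- rep(INF, m)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- INF; j1 <- 0L
      red <- a[i0, ] - u[i0] - v[seq_len(m)]
      upd <- !used[seq_len(m)] & red < minv
      minv[upd] <- red[upd]
      way[seq_len(m)][upd] <- j0
      free <- which(!used[seq_len(m)])
      if (length(free)) {
        jbest <- free[which.min(minv[free])]
        delta <- minv[jbest]; j1 <- jbest
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else if (j <= m) {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == J0) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) ans[p[j]] <- j
  ans
}

# pairwise linking cost between objects of consecutive frames:
# distance term (normalised by the speed gate) + relative volume difference +
# relative major-axis difference; pairs beyond the gate are forbidden
link_cost_matrix <- function(prev, nxt, gate_um) {
  d <- sqrt(outer(prev$centroid_x, nxt$centroid_x, `-`)^2 +
              outer(prev$centroid_y, nxt$centroid_y, `-`)^2 +
              outer(prev$centroid_z, nxt$centroid_z, `-`)^2)
  vol <- abs(outer(prev$volume_um3, nxt$volume_um3, `-`)) /
    outer(prev$volume_um3, nxt$volume_um3, `+`)
  ax <- abs(outer(prev$a1, nxt$a1, `-`)) / outer(prev$a1, nxt$a1, `+`)
  cost <- d / gate_um + vol + ax
  cost[d > gate_um] <- NA
  list(cost = cost, dist = d)
}

#' Track segmented mitochondria across frames
#'
#' Frame-to-frame global assignment in the style of the Mitometer tracker:
#' the total linking cost is minimised, where the cost of linking objects i
#' and j is the centroid distance normalised by the speed gate plus the
#' relative volume difference plus the relative major-axis difference,
#' `d/(max_speed*dt) + |Vi-Vj|/(Vi+Vj) + |a1i-a1j|/(a1i+a1j)`. Pairs farther
#' apart than `max_speed * dt` are forbidden; unmatched objects terminate or
#' start tracks (no gap closing across missed frames). Equal-cost assignments
#' resolve to the smaller distance, then the lower label.
#'
#' @param frame_objects list of per-frame data frames from
#'   [measure_objects()] (columns `label`, `centroid_x/y/z`, `volume_um3`,
#'   `a1`).
#' @param frame_interval seconds between frames (> 0).
#' @param max_speed gate speed, um/s.
#' @return List of tracks; each track is a data frame with `frame`, `label`,
#'   `centroid_x/y/z`, `volume_um3`. The list carries class `TrackSet`.
#' @export
track_objects <- function(frame_objects, frame_interval, max_speed = 1.0) {
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive")
  }
  n_frames <- length(frame_objects)
  if (n_frames < 2L) stop("tracking requires at least 2 frames of objects")
  gate_um <- max_speed * frame_interval

  as_rows <- function(obj, f) {
    if (nrow(obj) == 0L) return(obj)
    data.frame(frame = f, label = obj$label,
               centroid_x = obj$centroid_x, centroid_y = obj$centroid_y,
               centroid_z = if ("centroid_z" %in% names(obj)) obj$centroid_z else 0,
               volume_um3 = obj$volume_um3, a1 = obj$a1)
  }

  tracks <- list()              # each: data frame of rows
  active <- integer(0)          # track index per active track
  last_rows <- as_rows(frame_objects[[1L]], 1L)
  for (i in seq_len(nrow(last_rows))) {
    tracks[[i]] <- last_rows[i, , drop = FALSE]
    active[i] <- i
  }

  for (f in 2L:n_frames) {
    cur <- as_rows(frame_objects[[f]], f)
    if (length(active) == 0L || nrow(cur) == 0L) {
      active <- integer(0)
      if (nrow(cur) > 0L) {
        for (i in seq_len(nrow(cur))) {
          tracks[[length(tracks) + 1L]] <- cur[i, , drop = FALSE]
          active <- c(active, length(tracks))
        }
      }
      next
    }
    prev <- do.call(rbind, lapply(tracks[active], function(tr) tr[nrow(tr), ]))
    cm <- link_cost_matrix(prev, cur, gate_um)
    BIG <- 1e9
    cost <- cm$cost
    # deterministic tie-break: tiny penalties by distance then label order
    cost <- cost + cm$dist * 1e-9 +
      outer(seq_len(nrow(cost)) * 0, cur$label) * 1e-12
    cost[is.na(cost)] <- BIG
    transposed <- nrow(cost) > ncol(cost)
    assign <- if (transposed) {
      cols <- hungarian_assign(t(cost))   # per new object: track row
      out <- rep(0L, nrow(cost))
      out[cols] <- seq_along(cols)
      out
    } else {
      hungarian_assign(cost)
    }
    new_active <- integer(0)
    linked_cur <- rep(FALSE, nrow(cur))
    for (i in seq_along(active)) {
      j <- assign[i]
      if (j > 0L && cost[i, j] < BIG / 2) {
        tr <- active[i]
        tracks[[tr]] <- rbind(tracks[[tr]], cur[j, , drop = FALSE])
        new_active <- c(new_active, tr)
        linked_cur[j] <- TRUE
      }
    }
    for (j in which(!linked_cur)) {
      tracks[[length(tracks) + 1L]] <- cur[j, , drop = FALSE]
      new_active <- c(new_active, length(tracks))
    }
    active <- new_active
  }
  structure(tracks, class = "TrackSet")
}

#' @export
print.TrackSet <- function(x, ...) {
  lens <- vapply(x, nrow, integer(1))
  cat("TrackSet:", length(x), "tracks; lengths", min(lens), "-", max(lens), "\n")
  invisible(x)
}

#' Motility metrics of one track
#'
#' Total distance is the summed frame-to-frame centroid displacement (path
#' length, not net displacement); mean speed is distance divided by elapsed
#' time `(n_frames - 1) * frame_interval`.
#'
#' @param track data frame with `frame`, `centroid_x/y` (optionally
#'   `centroid_z`), one row per frame, frames strictly increasing.
#' @param frame_interval seconds between consecutive frames.
#' @return List: `n_frames`, `total_distance_um`, `mean_speed_um_s`,
#'   `defined` (FALSE for singleton tracks, whose metrics are `NA`).
#' @export
track_metrics <- function(track, frame_interval) {
  if (!is.numeric(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be positive")
  }
  n <- nrow(track)
  if (n < 2L) {
    return(list(n_frames = n, total_distance_um = NA_real_,
                mean_speed_um_s = NA_real_, defined = FALSE))
  }
  if (any(diff(track$frame) <= 0)) stop("track frames must be strictly increasing")
  z <- if ("centroid_z" %in% names(track)) track$centroid_z else rep(0, n)
  d <- sqrt(diff(track$centroid_x)^2 + diff(track$centroid_y)^2 + diff(z)^2)
  total <- sum(d)
  list(n_frames = n, total_distance_um = total,
       mean_speed_um_s = total / ((n - 1L) * frame_interval), defined = TRUE)
}

#' Summarise all tracks of a TrackSet
#'
#' @param tracks a `TrackSet` from [track_objects()].
#' @param frame_interval seconds between frames.
#' @param min_length drop tracks shorter than this many frames (default 2).
#' @return Data frame: one row per track with `track`, `n_frames`,
#'   `total_distance_um`, `mean_speed_um_s`.
#' @export
summarize_tracks <- function(tracks, frame_interval, min_length = 2L) {
  rows <- lapply(seq_along(tracks), function(i) {
    m <- track_metrics(tracks[[i]], frame_interval)
    if (m$n_frames < min_length) return(NULL)
    data.frame(track = i, n_frames = m$n_frames,
               total_distance_um = m$total_distance_um,
               mean_speed_um_s = m$mean_speed_um_s)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(track = integer(0), n_frames = integer(0),
                      total_distance_um = numeric(0),
                      mean_speed_um_s = numeric(0)))
  }
  do.call(rbind, rows)
}
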