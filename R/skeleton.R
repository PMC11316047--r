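#' Skeletonize a mitochondrial mask and build its branch graph
#'
#' Thins the mask to a one-pixel-wide medial skeleton and decomposes it into a
#' graph: nodes are skeleton pixels of degree 1 (tips) or degree >= 3
#' (junctions) in the 8-neighbourhood, and branches are the ordered pixel
#' paths traced between node pairs (junction-tip, tip-tip or
#' junction-junction). Every degree-2 skeleton pixel belongs to exactly one
#' branch; isolated closed loops (all pixels degree 2) become a single closed
#' branch. Branch length is the sum of physical steps between consecutive
#' pixels.
#'
#' Skeletonization operates in 2D; a 3D mask is reduced by maximum projection
#' first (the fast-volumetric live-cell protocol is analysed on per-frame
#' projections).
#'
#' @param mask logical matrix `[y, x]` (or array `[y, x, z]`, projected).
#' @param pixel_size um per pixel, `c(x=, y=)` or scalar.
#' @return A list of class `SkeletonGraph`: `nodes` (data frame: `y`, `x`
#'   pixel indices, `degree`, `type`), `branches` (list of ordered index
#'   matrices), `branch_table` (data frame: endpoints, pixel count, length in
#'   um, kind), `skeleton` (logical matrix), and counts `n_tips`,
#'   `n_junctions`.
#' @export
skeletonize_and_graph <- function(mask, pixel_size = c(x = 1, y = 1)) {
  pixel_size <- unlist(pixel_size)
  if (length(pixel_size) == 1L) pixel_size <- c(x = pixel_size, y = pixel_size)
  if (length(dim(mask)) == 3L) mask <- apply(mask, c(1L, 2L), any)
  storage.mode(mask) <- "logical"
  empty <- structure(list(
    nodes = data.frame(y = integer(0), x = integer(0), degree = integer(0),
                       type = character(0)),
    branches = list(),
    branch_table = data.frame(from = integer(0), to = integer(0),
                              n_pixels = integer(0), length_um = numeric(0),
                              kind = character(0)),
    skeleton = mask & FALSE, n_tips = 0L, n_junctions = 0L),
    class = "SkeletonGraph")
  if (!any(mask)) return(empty)

  skel <- .thin_mask_cpp(mask)
  ny <- nrow(skel); nx <- ncol(skel)
  idx <- which(skel)
  if (!length(idx)) return(empty)
  coord <- arrayInd(idx, dim(skel))
  pos <- match(seq_len(ny * nx), idx)     # linear index -> skeleton pixel id

  # 8-neighbour adjacency among skeleton pixels
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  offs <- offs[!(offs$dy == 0 & offs$dx == 0), ]
  nb <- vector("list", length(idx))
  for (k in seq_len(nrow(offs))) {
    yy <- coord[, 1L] + offs$dy[k]
    xx <- coord[, 2L] + offs$dx[k]
    ok <- yy >= 1L & yy <= ny & xx >= 1L & xx <= nx
    lin <- (xx - 1L) * ny + yy
    hit <- ok & !is.na(ifelse(ok, pos[ifelse(ok, lin, 1L)], NA))
    for (i in which(hit)) nb[[i]] <- c(nb[[i]], pos[lin[i]])
  }
  degree <- lengths(nb)
  is_node <- degree != 2L
  node_ids <- which(is_node)

  # adjacent junction pixels form one junction node (8-connected skeletons
  # commonly represent a single anatomical junction by 2-3 touching pixels)
  cluster <- integer(length(idx))
  next_cl <- 0L
  for (v in node_ids) {
    if (cluster[v] != 0L) next
    next_cl <- next_cl + 1L
    if (degree[v] >= 3L) {
      q <- v
      while (length(q)) {
        cur <- q[1L]; q <- q[-1L]
        if (cluster[cur] != 0L) next
        cluster[cur] <- next_cl
        q <- c(q, Filter(function(w) degree[w] >= 3L && cluster[w] == 0L, nb[[cur]]))
      }
    } else {
      cluster[v] <- next_cl
    }
  }

  step_len <- function(a, b) {
    sqrt(((coord[a, 2L] - coord[b, 2L]) * pixel_size[["x"]])^2 +
           ((coord[a, 1L] - coord[b, 1L]) * pixel_size[["y"]])^2)
  }
  edge_key <- function(a, b) paste0(min(a, b), "_", max(a, b))
  used <- new.env(hash = TRUE)
  branches <- list()
  btab <- list()

  add_branch <- function(path) {
    a <- path[1L]; b <- path[length(path)]
    len <- 0
    if (length(path) > 1L) {
      for (i in seq_len(length(path) - 1L)) len <- len + step_len(path[i], path[i + 1L])
    }
    kind_of <- function(p) if (degree[p] == 1L) "tip" else if (degree[p] >= 3L) "junction" else "loop"
    branches[[length(branches) + 1L]] <<- cbind(y = coord[path, 1L], x = coord[path, 2L])
    btab[[length(btab) + 1L]] <<- data.frame(
      from = if (cluster[a] > 0L) cluster[a] else NA_integer_,
      to = if (cluster[b] > 0L) cluster[b] else NA_integer_,
      n_pixels = length(path), length_um = len,
      kind = paste(kind_of(a), kind_of(b), sep = "-"))
  }

  for (v in node_ids) {
    for (w in nb[[v]]) {
      if (is_node[w] && cluster[w] == cluster[v]) next     # intra-junction link
      if (!is.null(used[[edge_key(v, w)]])) next
      path <- c(v, w)
      used[[edge_key(v, w)]] <- TRUE
      prev <- v; cur <- w
      while (!is_node[cur]) {
        nxt <- setdiff(nb[[cur]], prev)
        if (length(nxt) == 0L) break                      # dead end (shouldn't occur)
        # prefer the unused continuation (guards rare thinning artefacts)
        nxt <- nxt[is.null(used[[edge_key(cur, nxt[1L])]]) | length(nxt) == 1L][1L]
        if (!is.null(used[[edge_key(cur, nxt)]])) break
        used[[edge_key(cur, nxt)]] <- TRUE
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      add_branch(path)
    }
  }

  # isolated cycles: degree-2 pixels not yet traversed
  in_branch <- rep(FALSE, length(idx))
  for (b in branches) {
    pid <- pos[(b[, "x"] - 1L) * ny + b[, "y"]]
    in_branch[pid] <- TRUE
  }
  for (v in which(!in_branch & degree == 2L)) {
    if (in_branch[v]) next
    path <- v
    prev <- v; cur <- nb[[v]][1L]
    while (cur != v) {
      path <- c(path, cur)
      nxt <- setdiff(nb[[cur]], prev)[1L]
      prev <- cur; cur <- nxt
    }
    path <- c(path, v)                                     # close the loop
    in_branch[unique(path)] <- TRUE
    add_branch(path)
  }

  nodes <- data.frame(
    y = coord[node_ids, 1L], x = coord[node_ids, 2L],
    degree = degree[node_ids],
    cluster = cluster[node_ids],
    type = ifelse(degree[node_ids] == 1L, "tip",
                  ifelse(degree[node_ids] >= 3L, "junction", "isolated")))
  structure(list(
    nodes = nodes,
    branches = branches,
    branch_table = if (length(btab)) do.call(rbind, btab) else
      data.frame(from = integer(0), to = integer(0), n_pixels = integer(0),
                 length_um = numeric(0), kind = character(0)),
    skeleton = skel,
    n_tips = sum(degree[node_ids] == 1L),
    n_junctions = length(unique(cluster[node_ids][degree[node_ids] >= 3L]))),
    class = "SkeletonGraph")
}

#' @export
print.SkeletonGraph <- function(x, ...) {
  cat("SkeletonGraph:", length(x$branches), "branches,", x$n_tips, "tips,",
      x$n_junctions, "junctions\n")
  invisible(x)
}
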