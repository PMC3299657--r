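# Centreline extraction: homotopic thinning of the vessel mask, branch
# removal to split the tree into measurable segments, spur pruning, and a
# coarse per-segment diameter estimate from the distance transform.

# One Guo-Hall subiteration, fully vectorised.  Neighbours are labelled
# clockwise P2..P9 starting north.  `allowed` optionally restricts which
# pixels may be deleted (used for distance-ordered thinning).  Returns
# the updated mask.
guo_hall_pass <- function(mask, iter, allowed = NULL) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  sh <- function(dr, dc) pad[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  p2 <- sh(-1L, 0L); p3 <- sh(-1L, 1L); p4 <- sh(0L, 1L); p5 <- sh(1L, 1L)
  p6 <- sh(1L, 0L); p7 <- sh(1L, -1L); p8 <- sh(0L, -1L); p9 <- sh(-1L, -1L)
  C <- (!p2 & (p3 | p4)) + (!p4 & (p5 | p6)) +
    (!p6 & (p7 | p8)) + (!p8 & (p9 | p2))
  n1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
  n2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
  N <- pmin(n1, n2)
  m <- if (iter == 1L) (p6 | p7 | !p9) & p8 else (p2 | p3 | !p5) & p4
  del <- mask & (C == 1) & (N >= 2) & (N <= 3) & !m
  if (!is.null(allowed)) del <- del & allowed
  mask & !del
}

#' Thin a binary mask to a one-pixel-wide skeleton
#'
#' Homotopic morphological thinning (Guo--Hall two-subiteration deletion
#' conditions, applied in distance-ordered fashion): exterior pixels are
#' removed in increasing order of their Euclidean distance to the
#' background, so the surviving skeleton tracks the ridge of the
#' distance transform — the medial axis — rather than drifting where the
#' boundary is stepped. The skeleton is a subset of the input,
#' 8-connected, 1 px wide, and preserves the topology of the mask
#' (component and hole counts are unchanged).
#'
#' @param mask Logical matrix.
#' @return Logical matrix, the skeleton.
#' @export
thin_mask <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask)) return(mask)
  dt <- EBImage::distmap(mask * 1, metric = "euclidean")
  dt <- matrix(as.numeric(dt), nrow = nrow(mask))
  layers <- sort(unique(round(dt[mask] * 4) / 4))  # quarter-px granularity
  for (k in layers) {
    allowed <- round(dt * 4) / 4 <= k
    repeat {
      before <- mask
      mask <- guo_hall_pass(mask, 1L, allowed)
      mask <- guo_hall_pass(mask, 2L, allowed)
      if (identical(mask, before)) break
    }
  }
  repeat {
    before <- mask
    mask <- guo_hall_pass(mask, 1L)
    mask <- guo_hall_pass(mask, 2L)
    if (identical(mask, before)) break
  }
  mask
}

# Ordered walk through the pixels of a simple path/cycle component.
# `pts` is an n x 2 matrix of (row, col); every pixel has <= 2 on-
# neighbours within the set.  Direct (4-connected) neighbours are
# preferred over diagonal ones to avoid skipping pixels.
trace_chain <- function(pts) {
  n <- nrow(pts)
  if (n == 1L) return(list(order = 1L, closed = FALSE))
  key <- pts[, 1] * 1e6 + pts[, 2]
  idx_of <- function(r, c) match(r * 1e6 + c, key)
  deg <- integer(n)
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    cand_r <- pts[i, 1] + c(-1, 1, 0, 0, -1, -1, 1, 1)
    cand_c <- pts[i, 2] + c(0, 0, -1, 1, -1, 1, -1, 1)
    hit <- idx_of(cand_r, cand_c)
    nbrs[[i]] <- hit[!is.na(hit)]
    deg[i] <- length(nbrs[[i]])
  }
  ends <- which(deg <= 1L)
  lex <- order(pts[, 1], pts[, 2])
  start <- if (length(ends)) ends[which.min(match(ends, lex))] else lex[1L]
  closed <- length(ends) == 0L
  visited <- logical(n)
  ord <- integer(n)
  cur <- start
  for (step in seq_len(n)) {
    ord[step] <- cur
    visited[cur] <- TRUE
    nxt <- nbrs[[cur]][!visited[nbrs[[cur]]]]
    if (length(nxt) == 0L) {
      ord <- ord[seq_len(step)]
      break
    }
    if (length(nxt) > 1L) {
      # prefer a 4-connected continuation, then lexicographic
      direct <- nxt[abs(pts[nxt, 1] - pts[cur, 1]) +
                      abs(pts[nxt, 2] - pts[cur, 2]) == 1L]
      pool <- if (length(direct)) direct else nxt
      nxt <- pool[order(pts[pool, 1], pts[pool, 2])][1L]
    }
    cur <- nxt
  }
  list(order = ord, closed = closed)
}

new_chain <- function(points, is_closed = FALSE, diameter_estimate = NA_real_) {
  structure(
    list(points = points, is_closed = is_closed,
         diameter_estimate = diameter_estimate),
    class = "centreline_chain"
  )
}

#' @export
print.centreline_chain <- function(x, ...) {
  cat(sprintf(
    "Centreline chain: %d point(s)%s, diameter estimate %s px\n",
    nrow(x$points), if (x$is_closed) " (closed loop)" else "",
    if (is.na(x$diameter_estimate)) "not set" else
      format(x$diameter_estimate)
  ))
  invisible(x)
}

#' Split a skeleton into individual vessel-segment chains
#'
#' Counts the 'on' 8-neighbours of every skeleton pixel: branch pixels
#' (3 or more neighbours) are removed, dividing the vascular tree into
#' individual vessel segments, which is required because diameters are
#' not well defined at branches. The remaining runs are traced into
#' ordered chains starting from end pixels (1 neighbour); isolated loops
#' are cut at their lexicographically smallest pixel and flagged
#' `is_closed`.
#'
#' @param skeleton Logical matrix, a 1-px-wide skeleton from [thin_mask()].
#' @return List of `centreline_chain` objects, each with an ordered
#'   `points` matrix of (row, col) coordinates.
#' @export
split_at_branches <- function(skeleton) {
  stopifnot(is.logical(skeleton), is.matrix(skeleton))
  counts <- neighbour_count(skeleton)
  reduced <- skeleton & counts < 3
  lab <- label_components8(reduced)
  k <- max(lab)
  chains <- vector("list", k)
  for (i in seq_len(k)) {
    w <- which(lab == i)
    nr <- nrow(lab)
    pts <- cbind(((w - 1L) %% nr) + 1L, ((w - 1L) %/% nr) + 1L)
    tr <- trace_chain(pts)
    chains[[i]] <- new_chain(pts[tr$order, , drop = FALSE], tr$closed)
  }
  chains
}

#' Remove spurs and short segments from a chain set
#'
#' Thinning creates short side-branches (spurs) that do not correspond to
#' vessels. All chains shorter than `max_length` pixels are deleted.
#' Deleting a spur can leave its branch pixel separating exactly two
#' surviving chains that in truth belong to one vessel; such branch
#' pixels are re-inserted and the two chains merged, so the main vessel
#' is not erroneously subdivided.
#'
#' @param chains List of chains from [split_at_branches()].
#' @param skeleton The skeleton the chains were derived from (used to
#'   recover branch and end pixels).
#' @param max_length Minimum surviving chain length in pixels (default 10).
#' @return List of `centreline_chain` objects.
#' @export
remove_spurs <- function(chains, skeleton, max_length = 10) {
  stopifnot(max_length >= 0)
  counts <- neighbour_count(skeleton)
  branch <- skeleton & counts >= 3
  lens <- vapply(chains, function(ch) nrow(ch$points), integer(1))
  keep <- lens >= max_length
  deleted <- chains[!keep]
  chains <- chains[keep]
  if (length(deleted) == 0L || !any(branch)) return(chains)

  # Thinning can mark a small cluster of mutually adjacent pixels as
  # branch pixels, so reconnection works cluster-wise: when deleting a
  # spur leaves a branch cluster adjacent to exactly two surviving
  # chains, the cluster is bridged by a shortest pixel path and the two
  # chains merged.
  blab <- label_components8(branch)
  nrb <- nrow(branch)
  bidx <- which(branch)
  bpts <- cbind(((bidx - 1L) %% nrb) + 1L, ((bidx - 1L) %/% nrb) + 1L)
  bcl <- blab[bidx]
  adj_to_cluster <- function(p, cl) {
    any(abs(bpts[bcl == cl, 1L] - p[1]) <= 1L &
          abs(bpts[bcl == cl, 2L] - p[2]) <= 1L)
  }
  # clusters adjacent to a deleted chain that had a free end (a spur)
  spur_clusters <- integer(0)
  for (ch in deleted) {
    pts <- ch$points
    term <- pts[unique(c(1L, nrow(pts))), , drop = FALSE]
    adj_cl <- integer(0)
    free_end <- FALSE
    for (t in seq_len(nrow(term))) {
      near <- unique(bcl[abs(bpts[, 1L] - term[t, 1L]) <= 1L &
                           abs(bpts[, 2L] - term[t, 2L]) <= 1L])
      if (length(near) == 0L) free_end <- TRUE else adj_cl <- c(adj_cl, near)
    }
    if (free_end && length(adj_cl)) spur_clusters <- c(spur_clusters, adj_cl)
  }
  for (cl in unique(spur_clusters)) {
    hits <- list()
    for (i in seq_along(chains)) {
      pts <- chains[[i]]$points
      n <- nrow(pts)
      if (adj_to_cluster(pts[1L, ], cl)) hits[[length(hits) + 1L]] <- c(i, 1L)
      if (n > 1L && adj_to_cluster(pts[n, ], cl)) {
        hits[[length(hits) + 1L]] <- c(i, n)
      }
    }
    if (length(hits) != 2L) next
    i1 <- hits[[1L]][1L]; i2 <- hits[[2L]][1L]
    if (i1 == i2) next
    a <- chains[[i1]]$points
    if (hits[[1L]][2L] == 1L) a <- a[rev(seq_len(nrow(a))), , drop = FALSE]
    b2 <- chains[[i2]]$points
    if (hits[[2L]][2L] != 1L) b2 <- b2[rev(seq_len(nrow(b2))), , drop = FALSE]
    bridge <- cluster_bridge(bpts[bcl == cl, , drop = FALSE],
                             a[nrow(a), ], b2[1L, ])
    if (is.null(bridge)) next
    chains[[i1]] <- new_chain(rbind(a, bridge, b2), FALSE)
    chains[[i2]] <- NULL
  }
  chains
}

# Shortest 8-connected path through `cluster` pixels from a pixel
# adjacent to `from` to a pixel adjacent to `to` (BFS, deterministic in
# lexicographic order).  Returns the path as a matrix, or NULL.
cluster_bridge <- function(cluster, from, to) {
  o <- order(cluster[, 1L], cluster[, 2L])
  cluster <- cluster[o, , drop = FALSE]
  n <- nrow(cluster)
  adj8 <- function(p, q) max(abs(p[1L] - q[1L]), abs(p[2L] - q[2L])) == 1L
  start <- which(vapply(seq_len(n),
                        function(i) adj8(cluster[i, ], from), logical(1)))
  goal <- vapply(seq_len(n), function(i) adj8(cluster[i, ], to), logical(1))
  if (length(start) == 0L || !any(goal)) return(NULL)
  prev <- rep(NA_integer_, n)
  seen <- logical(n)
  queue <- start
  seen[start] <- TRUE
  while (length(queue)) {
    cur <- queue[1L]
    queue <- queue[-1L]
    if (goal[cur]) {
      path <- cur
      while (!is.na(prev[path[1L]])) path <- c(prev[path[1L]], path)
      return(cluster[path, , drop = FALSE])
    }
    for (i in seq_len(n)) {
      if (!seen[i] && adj8(cluster[cur, ], cluster[i, ])) {
        seen[i] <- TRUE
        prev[i] <- cur
        queue <- c(queue, i)
      }
    }
  }
  NULL
}

#' Estimate segment diameters from the distance transform
#'
#' The Euclidean distance transform of the vessel mask gives, for every
#' vessel pixel, its distance to the closest non-vessel pixel. Doubling
#' the maximum of the transform along a thinned centreline estimates the
#' diameter of that vessel segment at its widest point.
#'
#' @param mask Logical vessel mask the chains were derived from.
#' @param chains List of chains.
#' @return The chains with `diameter_estimate` set.
#' @export
estimate_diameters <- function(mask, chains) {
  if (length(chains) == 0L) return(chains)
  dt <- EBImage::distmap(mask * 1, metric = "euclidean")
  dt <- matrix(as.numeric(dt), nrow = nrow(mask))
  nr <- nrow(mask)
  lapply(chains, function(ch) {
    idx <- (ch$points[, 2] - 1L) * nr + ch$points[, 1]
    if (any(!mask[idx])) {
      stop("internal error: centreline point outside mask", call. = FALSE)
    }
    ch$diameter_estimate <- 2 * max(dt[idx])
    ch
  })
}

#' Drop chains too short to be measurable
#'
#' A centreline with fewer pixels than its estimated diameter is unlikely
#' to correspond to a measurable vessel and is removed.
#'
#' @param chains List of chains with diameter estimates set.
#' @return Filtered list.
#' @export
remove_short_chains <- function(chains) {
  Filter(function(ch) {
    !is.na(ch$diameter_estimate) && nrow(ch$points) >= ch$diameter_estimate
  }, chains)
}

#' Extract vessel centrelines from a binary mask
#'
#' Composes [thin_mask()], [split_at_branches()], [remove_spurs()],
#' [estimate_diameters()] and [remove_short_chains()]: each resulting
#' chain is the centreline of one vessel segment suitable for spline
#' fitting and calibre measurement.
#'
#' @param mask Logical vessel mask.
#' @param spur_length Minimum chain length in pixels (default 10).
#' @return List of `centreline_chain` objects.
#' @export
extract_centrelines <- function(mask, spur_length = 10) {
  skel <- thin_mask(mask)
  chains <- split_at_branches(skel)
  chains <- remove_spurs(chains, skel, spur_length)
  chains <- estimate_diameters(mask, chains)
  remove_short_chains(chains)
}
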