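#' Topological thinning of a binary mask
#'
#' Reduces an 8-connected foreground component to a 1-pixel-wide skeleton
#' with the Zhang-Suen two-subiteration thinning algorithm, which preserves
#' connectivity. The skeleton is a subset of the mask.
#'
#' @param mask logical matrix containing one 8-connected component.
#' @return logical matrix of skeleton pixels.
#' @export
thin_mask <- function(mask) {
  if (sum(mask) == 0) stop("cannot thin an empty mask")
  m <- mask * 1L
  h <- nrow(m)
  w <- ncol(m)
  pad <- matrix(0L, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- m
  shift <- function(p, dr, dc) {
    p[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- pad[2:(h + 1), 2:(w + 1)]
      # Neighbors clockwise from north: P2..P9.
      p2 <- shift(pad, -1, 0)
      p3 <- shift(pad, -1, 1)
      p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1)
      p6 <- shift(pad, 1, 0)
      p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1)
      p9 <- shift(pad, -1, -1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (sub == 1) {
        cond <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p == 1 & b >= 2 & b <= 6 & a == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) {
        changed <- TRUE
        p[cond] <- 0L
        pad[2:(h + 1), 2:(w + 1)] <- p
      }
    }
    if (!changed) break
  }
  pad[2:(h + 1), 2:(w + 1)] == 1L
}

# Build the minimal-connectivity weighted pixel graph of a skeleton:
# orthogonal neighbors get weight-1 edges and diagonal neighbors weight
# sqrt(2), but a diagonal edge is included only when neither of the two
# shared orthogonal neighbors is a skeleton pixel — otherwise every corner
# would close a spurious triangle and no curved skeleton would be a tree.
skeleton_graph <- function(skel) {
  h <- nrow(skel)
  w <- ncol(skel)
  idx <- which(skel)
  pos <- integer(h * w)
  pos[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  at <- function(r, c) {
    ok <- r >= 1L & r <= h & c >= 1L & c <= w
    out <- integer(length(r))
    out[ok] <- pos[(c[ok] - 1L) * h + r[ok]]
    out
  }
  edges <- NULL
  weights <- NULL
  for (o in list(c(1L, 0L), c(0L, 1L))) {
    nbr <- at(rr + o[1], cc + o[2])
    hit <- nbr > 0L
    edges <- rbind(edges, cbind(seq_along(idx)[hit], nbr[hit]))
    weights <- c(weights, rep(1, sum(hit)))
  }
  for (o in list(c(1L, 1L), c(-1L, 1L))) {
    nbr <- at(rr + o[1], cc + o[2])
    # shared orthogonal neighbors of the diagonal pair
    orth1 <- at(rr + o[1], cc)
    orth2 <- at(rr, cc + o[2])
    hit <- nbr > 0L & orth1 == 0L & orth2 == 0L
    edges <- rbind(edges, cbind(seq_along(idx)[hit], nbr[hit]))
    weights <- c(weights, rep(sqrt(2), sum(hit)))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges), weight = weights)
  }
  list(graph = g, coords = cbind(row = rr, col = cc))
}

#' Prune a skeleton to its longest endpoint-to-endpoint path
#'
#' Thinning a noisy or non-worm object can leave side branches; the worm's
#' body is taken to be the maximum-weight path between two skeleton
#' endpoints (degree-1 pixels), with orthogonal steps weighing 1 and
#' diagonal steps `sqrt(2)` — equivalent to removing the shortest branches.
#' The fraction of total skeleton length retained is reported as
#' `prune_ratio`, used downstream as a filter on spurious objects.
#'
#' Skeletons containing a cycle (self-touching worms) are rejected with an
#' error of class `nm_skeleton_cycle`; such objects cannot be measured
#' correctly and are auto-failed by the pipeline.
#'
#' @param skel logical skeleton matrix (one connected component), e.g. from
#'   [thin_mask()].
#' @return a `skeleton_path` list: `points` ((row, col) matrix ordered tip
#'   to tip, starting at the endpoint smallest in (row, col) order),
#'   `length_px` (chain-code arclength) and `prune_ratio`.
#' @export
prune_to_path <- function(skel) {
  sg <- skeleton_graph(skel)
  g <- sg$graph
  coords <- sg$coords
  n <- igraph::vcount(g)
  if (n == 0) stop("empty skeleton")
  comp <- igraph::components(g)
  if (comp$no > 1) stop("skeleton pixels are not a single connected component")
  if (igraph::ecount(g) >= n) {
    stop(structure(
      class = c("nm_skeleton_cycle", "error", "condition"),
      list(
        message = "skeleton contains a cycle (self-touching object); rejected",
        call = sys.call(-1)
      )
    ))
  }
  if (n == 1) {
    return(structure(
      list(points = coords, length_px = 0, prune_ratio = 1),
      class = "skeleton_path"
    ))
  }
  deg <- igraph::degree(g)
  eps <- which(deg == 1)
  if (length(eps) == 0) {
    stop(structure(
      class = c("nm_skeleton_cycle", "error", "condition"),
      list(message = "skeleton has no endpoints; rejected", call = sys.call(-1))
    ))
  }
  dmat <- igraph::distances(g, v = eps, to = eps)
  best <- max(dmat)
  tol <- 1e-9
  cand <- which(dmat >= best - tol, arr.ind = TRUE)
  cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
  # Deterministic tie-break: smallest (row, col) of the start endpoint,
  # then of the other end.
  key <- function(v) coords[v, 1] * (max(coords[, 2]) + 1) + coords[v, 2]
  a <- eps[cand[, 1]]
  b <- eps[cand[, 2]]
  swap <- key(b) < key(a)
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  ord <- order(key(a), key(b))
  from <- a[ord[1]]
  to <- b[ord[1]]
  vpath <- igraph::shortest_paths(g, from = from, to = to,
    output = "vpath"
  )$vpath[[1]]
  pts <- coords[as.integer(vpath), , drop = FALSE]
  total <- sum(igraph::E(g)$weight)
  structure(
    list(
      points = pts,
      length_px = path_length(pts),
      prune_ratio = if (total > 0) best / total else 1
    ),
    class = "skeleton_path"
  )
}

#' Pruned/original skeleton length ratio filter
#'
#' @param path a `skeleton_path` from [prune_to_path()].
#' @param prune_ratio_min minimum acceptable ratio in \[0, 1\].
#' @return TRUE (pass) or FALSE (fail).
#' @export
ratio_filter <- function(path, prune_ratio_min) {
  stopifnot(prune_ratio_min >= 0, prune_ratio_min <= 1)
  path$prune_ratio >= prune_ratio_min
}

#' Smooth a medial path by centered moving average
#'
#' A pixel-resolution skeleton is a staircase: its chain-code length
#' overestimates the true curve length by an angle-dependent factor of up
#' to ~8%, and longest-path pruning retains every zigzag. Averaging each
#' point with its neighbors (window shrinking symmetrically toward the
#' tips, endpoints kept exact) turns the staircase into a subpixel
#' polyline whose length is close to the underlying curve's, making length
#' nearly invariant under rotation of the object.
#'
#' @param path a `skeleton_path` or (row, col) matrix of ordered points.
#' @param window full moving-average window in points (odd; default 7).
#' @return same type as the input, with smoothed `points` (and, for a
#'   `skeleton_path`, updated `length_px`).
#' @export
smooth_path <- function(path, window = 7) {
  pts <- if (inherits(path, "skeleton_path")) path$points else path
  n <- nrow(pts)
  k <- max(0L, (as.integer(window) - 1L) %/% 2L)
  if (n >= 3 && k > 0) {
    sm <- pts
    for (i in 2:(n - 1)) {
      kk <- min(k, i - 1L, n - i)
      sm[i, ] <- colMeans(pts[(i - kk):(i + kk), , drop = FALSE])
    }
    keep <- c(TRUE, rowSums(abs(diff(sm))) > 1e-12)
    pts <- sm[keep, , drop = FALSE]
  }
  if (inherits(path, "skeleton_path")) {
    structure(
      list(
        points = pts, length_px = path_length(pts),
        prune_ratio = path$prune_ratio
      ),
      class = "skeleton_path"
    )
  } else {
    pts
  }
}

#' Extend a medial path along its tip tangents to the object edge
#'
#' Thinning retracts the skeleton from the worm's tapered tips. At each end
#' the direction of the last `window` path points is fit by least squares
#' (principal direction) and the path is marched outward in 0.5-px steps
#' until the first sample falls outside the mask, appending the traversed
#' subpixel points. Ends that already touch the boundary are left alone.
#'
#' @param path a `skeleton_path` or a (row, col) matrix of ordered points.
#' @param mask logical mask of the object.
#' @param window number of points used in the tangent fit.
#' @return a `skeleton_path` with extended `points` and updated `length_px`
#'   (the `prune_ratio` of the input is carried over).
#' @export
extend_to_edges <- function(path, mask, window = 5) {
  pts <- if (inherits(path, "skeleton_path")) path$points else path
  prune_ratio <- if (inherits(path, "skeleton_path")) path$prune_ratio else 1
  if (nrow(pts) < window) {
    stop("path has fewer points (", nrow(pts), ") than the tangent window")
  }
  h <- nrow(mask)
  w <- ncol(mask)
  inside <- function(p) {
    r <- round(p[1])
    c <- round(p[2])
    r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]
  }
  # an endpoint whose pixel already touches the mask boundary needs no
  # extension
  on_boundary <- function(p) {
    r <- round(p[1])
    c <- round(p[2])
    for (dr in -1:1) {
      for (dc in -1:1) {
        rr <- r + dr
        cc <- c + dc
        if (rr < 1 || rr > h || cc < 1 || cc > w || !mask[rr, cc]) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  extend_one <- function(tail_pts) {
    # tail_pts: last `window` points, endpoint last
    end <- tail_pts[nrow(tail_pts), ]
    ctr <- colMeans(tail_pts)
    sv <- svd(sweep(tail_pts, 2, ctr))
    dir <- sv$v[, 1]
    outward <- end - tail_pts[1, ]
    if (sum(dir * outward) < 0) dir <- -dir
    dir <- dir / sqrt(sum(dir^2))
    new_pts <- NULL
    for (k in seq_len(4000)) {
      p <- end + 0.5 * k * dir
      if (!inside(p)) break
      new_pts <- rbind(new_pts, p)
    }
    new_pts
  }
  head_ext <- if (on_boundary(pts[1, ])) NULL else {
    extend_one(pts[min(window, nrow(pts)):1, , drop = FALSE])
  }
  tail_ext <- if (on_boundary(pts[nrow(pts), ])) NULL else {
    extend_one(pts[(nrow(pts) - window + 1):nrow(pts), , drop = FALSE])
  }
  out <- pts
  if (!is.null(head_ext)) out <- rbind(head_ext[rev(seq_len(nrow(head_ext))), , drop = FALSE], out)
  if (!is.null(tail_ext)) out <- rbind(out, tail_ext)
  rownames(out) <- NULL
  structure(
    list(points = out, length_px = path_length(out), prune_ratio = prune_ratio),
    class = "skeleton_path"
  )
}

#' Arclength of an ordered path
#'
#' Sum of Euclidean steps between consecutive points: 1 for orthogonal and
#' `sqrt(2)` for diagonal pixel steps, exact Euclidean distance for
#' subpixel points.
#'
#' @param points (row, col) matrix, or a `skeleton_path`.
#' @return length in pixels (0 for fewer than 2 points).
#' @export
path_length <- function(points) {
  if (inherits(points, "skeleton_path")) points <- points$points
  if (is.null(points) || nrow(points) < 2) {
    return(0)
  }
  d <- diff(points)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}
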