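#' Intensity histogram of an 8-bit image
#'
#' @param image intensity matrix in \[0, 255\].
#' @return integer vector of length 256; element `j + 1` is the number of
#'   pixels with intensity `j`.
#' @export
intensity_histogram <- function(image) {
  tabulate(as.integer(image) + 1L, nbins = 256L)
}

#' Minimum-algorithm histogram threshold
#'
#' Iteratively smooths the intensity histogram with a 3-point moving
#' average (window `[1,1,1]/3`, edge bins replicated) until exactly two
#' strict local maxima remain — one for background, one for objects — and
#' returns the valley between them: the intensity `t` with
#' `y[t-1] > y[t] <= y[t+1]` in the smoothed histogram. If several valleys
#' qualify, the lowest-count one is taken, ties broken by the smallest `t`.
#' A strict local maximum is a bin strictly greater than both neighbors
#' (plateaus do not count); edge bins are compared against their single
#' neighbor.
#'
#' @param hist 256-bin histogram from [intensity_histogram()].
#' @param max_iter smoothing iteration cap.
#' @return list with `threshold` (intensity 0-255), `smoothing_iterations`,
#'   and the final `smoothed` histogram.
#' @export
minimum_threshold <- function(hist, max_iter = 10000L) {
  if (length(hist) != 256L) stop("histogram must have 256 bins")
  if (sum(hist > 0) < 2) {
    stop("no threshold: histogram has fewer than two nonzero bins")
  }
  y <- as.numeric(hist)
  iter <- 0L
  # smoothing can transiently destroy maxima through exact count ties, so
  # iterate until exactly two remain (not merely "at most two")
  while (count_strict_maxima(y) != 2L && iter < max_iter) {
    y <- smooth3(y)
    iter <- iter + 1L
  }
  if (count_strict_maxima(y) != 2L) {
    stop(
      "no threshold: histogram never reached exactly two local maxima (",
      count_strict_maxima(y), " after ", iter, " smoothing iterations)"
    )
  }
  peaks <- which(strict_maxima(y))
  lo <- peaks[1]
  hi <- peaks[2]
  valley <- integer(0)
  if (hi - lo >= 2) {
    j <- (lo + 1):(hi - 1)
    ok <- y[j - 1] > y[j] & y[j] <= y[j + 1]
    valley <- j[ok]
  }
  if (length(valley) == 0) {
    stop("no threshold: no valley between the two histogram peaks")
  }
  valley <- valley[y[valley] == min(y[valley])]
  t <- valley[1] - 1L # bins are 1-based, intensities 0-based
  list(threshold = t, smoothing_iterations = iter, smoothed = y)
}

smooth3 <- function(y) {
  n <- length(y)
  (c(y[1], y[-n]) + y + c(y[-1], y[n])) / 3
}

strict_maxima <- function(y) {
  n <- length(y)
  left <- c(-Inf, y[-n])
  right <- c(y[-1], -Inf)
  # Edge bins have one neighbor; the missing side never blocks them.
  y > left & y > right
}

count_strict_maxima <- function(y) {
  sum(strict_maxima(y))
}

#' Threshold an image into a foreground mask
#'
#' Objects are bright after light-background preprocessing, so a pixel is
#' foreground iff its intensity is greater than or equal to `t`.
#'
#' @param image intensity matrix.
#' @param t threshold intensity.
#' @return logical matrix.
#' @export
apply_threshold <- function(image, t) {
  image >= t
}

#' Label 8-connected foreground components as worm candidates
#'
#' Foreground connectivity is 8 (background 4, the complementary pair), so
#' thin diagonal worm bodies stay in one piece. Each component is returned
#' with its pixel mask, area, bounding box, and outer contour traced with
#' the Moore boundary-following algorithm.
#'
#' @param mask logical matrix.
#' @return list of worm candidate objects, ordered by first pixel position.
#' @export
connected_components <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0) {
    return(list())
  }
  pos <- integer(h * w)
  pos[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  edges <- list()
  # Half of the 8-neighborhood; the other half is implied by symmetry.
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (o in offs) {
    nr <- rr + o[1]
    nc <- cc + o[2]
    ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
    nidx <- (nc[ok] - 1L) * h + nr[ok]
    hit <- pos[nidx] > 0L
    if (any(hit)) {
      edges[[length(edges) + 1L]] <-
        cbind(pos[idx[ok]][hit], pos[nidx][hit])
    }
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  comp <- igraph::components(g)
  out <- vector("list", comp$no)
  for (k in seq_len(comp$no)) {
    members <- idx[comp$membership == k]
    cmask <- matrix(FALSE, h, w)
    cmask[members] <- TRUE
    mr <- ((members - 1L) %% h) + 1L
    mc <- ((members - 1L) %/% h) + 1L
    out[[k]] <- structure(
      list(
        mask = cmask,
        area_px2 = length(members),
        bbox = c(
          rmin = min(mr), rmax = max(mr),
          cmin = min(mc), cmax = max(mc)
        ),
        contour = moore_contour(cmask),
        first_pixel = min(members)
      ),
      class = "worm_candidate"
    )
  }
  out[order(vapply(out, function(x) x$first_pixel, numeric(1)))]
}

# Moore boundary tracing (8-connected boundary, clockwise), starting from
# the first foreground pixel in column-major order, with Jacob's stopping
# criterion. Returns an ordered (row, col) matrix of boundary pixels.
moore_contour <- function(mask) {
  h <- nrow(mask)
  w <- ncol(mask)
  inside <- function(r, c) r >= 1 && r <= h && c >= 1 && c <= w && mask[r, c]
  start_idx <- which(mask)[1]
  sr <- ((start_idx - 1L) %% h) + 1L
  sc <- ((start_idx - 1L) %/% h) + 1L
  # Clockwise Moore neighborhood in (row, col), starting west.
  nb <- rbind(
    c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
    c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L)
  )
  contour <- matrix(integer(0), 0, 2)
  cur <- c(sr, sc)
  # Backtrack: the start pixel was entered from the west (column-major scan
  # guarantees the west neighbor is background or out of bounds).
  back <- 1L
  first_dir <- NA_integer_
  repeat {
    contour <- rbind(contour, cur)
    found <- FALSE
    d <- back
    for (step in 1:8) {
      d <- (d %% 8L) + 1L
      nr <- cur[1] + nb[d, 1]
      nc <- cur[2] + nb[d, 2]
      if (inside(nr, nc)) {
        if (nrow(contour) == 1L) first_dir <- d
        # next backtrack: the neighbor preceding d, pointing back toward cur
        back <- ((d + 3L) %% 8L) + 1L
        cur <- c(nr, nc)
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    if (cur[1] == sr && cur[2] == sc) {
      # Jacob's criterion: stop when re-entering the start in the same
      # direction as the first move.
      nxt <- back
      d2 <- nxt
      for (step in 1:8) {
        d2 <- (d2 %% 8L) + 1L
        if (inside(sr + nb[d2, 1], sc + nb[d2, 2])) break
      }
      if (d2 == first_dir || nrow(contour) > 4L * sum(mask)) break
    }
  }
  dimnames(contour) <- NULL
  unique(contour)
}

#' Filter candidates on area
#'
#' @param candidates list from [connected_components()].
#' @param min_px2,max_px2 inclusive area bounds.
#' @return filtered list.
#' @export
area_filter <- function(candidates, min_px2, max_px2) {
  if (min_px2 >= max_px2) stop("area_min must be < area_max")
  keep <- vapply(
    candidates,
    function(x) x$area_px2 >= min_px2 && x$area_px2 <= max_px2,
    logical(1)
  )
  candidates[keep]
}
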