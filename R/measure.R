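#' Sample radii orthogonal to the medial path
#'
#' Width at a point on the medial path is the length of the line between
#' the path and the worm's edge, orthogonal to the path. Samples are taken
#' at arclengths `0, h, 2h, ...` plus the exact path end. At each interior
#' sample the local tangent is the central difference over `window` path
#' points to either side; both normal directions are marched in 0.25-px
#' steps until the first sample outside the mask, and the one-sided
#' distance is that of the last inside sample. The radius is the mean of
#' the two one-sided distances (the width their sum), which is robust to
#' slight off-centering of the path. The path tips lie on the contour where
#' the width vanishes, so both tip samples get `r = 0`.
#'
#' @param mask logical object mask.
#' @param path `skeleton_path` (extended to the edges) or (row, col) matrix.
#' @param interval_px sampling interval `h`, >= 1.
#' @param window half-width (in path points) of the tangent estimate.
#' @return a `radius_profile` data frame with columns `s` (arclength), `r`
#'   (radius, px) and the chord endpoints `left_r, left_c, right_r,
#'   right_c` (NA at the tips); attribute `interval_px`.
#' @export
sample_radii <- function(mask, path, interval_px, window = 5) {
  stopifnot(interval_px >= 1)
  pts <- if (inherits(path, "skeleton_path")) path$points else path
  if (nrow(pts) < 2) stop("path must have at least 2 points")
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  L <- cum[length(cum)]
  targets <- seq(0, L, by = interval_px)
  if (L - targets[length(targets)] > 1e-9) targets <- c(targets, L)
  targets[length(targets)] <- L
  h <- nrow(mask)
  w <- ncol(mask)
  inside <- function(r, c) {
    ri <- round(r)
    ci <- round(c)
    ri >= 1 && ri <= h && ci >= 1 && ci <= w && mask[ri, ci]
  }
  point_at <- function(s) {
    i <- findInterval(s, cum, rightmost.closed = TRUE)
    i <- min(max(i, 1L), nrow(pts) - 1L)
    t <- if (seg[i] > 0) (s - cum[i]) / seg[i] else 0
    pts[i, ] + t * (pts[i + 1, ] - pts[i, ])
  }
  march <- function(origin, dir) {
    d_in <- NA_real_
    last <- c(NA_real_, NA_real_)
    for (k in seq_len(4000)) {
      p <- origin + 0.25 * k * dir
      if (!inside(p[1], p[2])) {
        return(list(d = if (k == 1) 0 else 0.25 * (k - 1), end = last))
      }
      last <- p
    }
    stop("normal ray failed to exit the mask within 1000 px; degenerate mask")
  }
  n <- length(targets)
  out <- data.frame(
    s = targets, r = 0,
    left_r = NA_real_, left_c = NA_real_,
    right_r = NA_real_, right_c = NA_real_
  )
  if (n > 2) {
    for (j in 2:(n - 1)) {
      s <- targets[j]
      i <- findInterval(s, cum, rightmost.closed = TRUE)
      i <- min(max(i, 1L), nrow(pts))
      i1 <- max(1L, i - window)
      i2 <- min(nrow(pts), i + window)
      tangent <- pts[i2, ] - pts[i1, ]
      nt <- sqrt(sum(tangent^2))
      if (nt == 0) next
      tangent <- tangent / nt
      normal <- c(-tangent[2], tangent[1])
      origin <- point_at(s)
      a <- march(origin, normal)
      b <- march(origin, -normal)
      out$r[j] <- (a$d + b$d) / 2
      if (a$d > 0) {
        out$left_r[j] <- a$end[1]
        out$left_c[j] <- a$end[2]
      }
      if (b$d > 0) {
        out$right_r[j] <- b$end[1]
        out$right_c[j] <- b$end[2]
      }
    }
  }
  attr(out, "interval_px") <- interval_px
  class(out) <- c("radius_profile", "data.frame")
  out
}

#' Volume of a radius profile by frustum summation
#'
#' Assuming radial symmetry, the worm's volume is the solid of revolution
#' of its radius profile about the medial path. Each interval between
#' consecutive samples is treated as the frustum of a cone:
#' \deqn{V = \sum_i \frac{\pi (s_{i+1}-s_i)}{3}\,(r_i^2 + r_i r_{i+1} + r_{i+1}^2),}
#' the solid-of-revolution analogue of the trapezoid rule. The sum is exact
#' for constant radii (cylinders) and linear tapers (cones).
#'
#' @param profile `radius_profile` from [sample_radii()], or any data frame
#'   with columns `s` and `r`.
#' @return volume in cubic pixels.
#' @export
frustum_volume <- function(profile) {
  s <- profile$s
  r <- profile$r
  if (length(s) < 2) {
    warning("fewer than 2 samples; volume is 0")
    return(0)
  }
  if (any(diff(s) <= 0)) stop("arclength positions must be strictly increasing")
  if (any(r < 0)) stop("radii must be nonnegative")
  n <- length(s)
  sum(pi * diff(s) / 3 * (r[-n]^2 + r[-n] * r[-1] + r[-1]^2))
}

#' Cylinder-approximation volume
#'
#' The coarse estimate used by manual methods: a cylinder with the worm's
#' length and its width at the middle of the skeleton,
#' `pi * (mid_width/2)^2 * length`. Ignores tapering, so for mid-widest
#' (tapered) worms it exceeds the frustum volume.
#'
#' @param length_px worm length.
#' @param mid_width_px width at the middle of the skeleton.
#' @return volume in cubic pixels.
#' @export
cylinder_volume <- function(length_px, mid_width_px) {
  stopifnot(length_px >= 0, mid_width_px >= 0)
  pi * (mid_width_px / 2)^2 * length_px
}

#' Measure a worm in absolute units
#'
#' Samples the radius profile, integrates the frustum volume, and converts
#' pixels to physical units: linear sizes scale by `s` (microns per pixel)
#' and volumes by `s^3`; cubic microns convert to picoliters by division by
#' 1000 (1 pl = 1000 um^3). The middle width is the width at the sample
#' nearest to half the arclength; the average width is the mean over
#' samples excluding the two zero tip samples (which would otherwise bias
#' it low by construction).
#'
#' @param mask logical object mask.
#' @param path `skeleton_path` extended to the edges.
#' @param scale_um_per_px physical scale, > 0.
#' @param interval_px radius sampling interval.
#' @param window tangent window for [sample_radii()].
#' @return a `worm_measurement` list with fields `length_um`,
#'   `avg_width_um`, `mid_width_um`, `volume_pl`, `cylinder_volume_pl` and
#'   their pixel-native counterparts, plus the `profile`.
#' @export
measure_worm <- function(mask, path, scale_um_per_px, interval_px = 10,
                         window = 5) {
  stopifnot(scale_um_per_px > 0)
  profile <- sample_radii(mask, path, interval_px, window)
  measure_profile(profile, scale_um_per_px)
}

# Measurement from an existing profile (shared by measure_worm and the
# interval sweep).
measure_profile <- function(profile, scale_um_per_px) {
  s <- profile$s
  r <- profile$r
  L <- s[length(s)]
  interior <- if (length(r) > 2) r[2:(length(r) - 1)] else numeric(0)
  avg_width_px <- if (length(interior) > 0) mean(2 * interior) else 0
  mid_idx <- which.min(abs(s - L / 2))
  mid_width_px <- 2 * r[mid_idx]
  vol_px3 <- frustum_volume(profile)
  cyl_px3 <- cylinder_volume(L, mid_width_px)
  k <- scale_um_per_px
  structure(
    list(
      length_px = L,
      avg_width_px = avg_width_px,
      mid_width_px = mid_width_px,
      volume_px3 = vol_px3,
      cylinder_volume_px3 = cyl_px3,
      length_um = L * k,
      avg_width_um = avg_width_px * k,
      mid_width_um = mid_width_px * k,
      volume_pl = vol_px3 * k^3 / 1000,
      cylinder_volume_pl = cyl_px3 * k^3 / 1000,
      profile = profile
    ),
    class = "worm_measurement"
  )
}

#' Volume stability across sampling intervals
#'
#' Recomputes the frustum volume of one worm for each sampling interval and
#' reports the coefficient of variation across intervals — the robustness
#' check for the choice of interval size.
#'
#' @param mask logical object mask.
#' @param path `skeleton_path` extended to the edges.
#' @param scale_um_per_px physical scale.
#' @param intervals vector of sampling intervals (px), all >= 1.
#' @param window tangent window for [sample_radii()].
#' @return list with `volumes_pl` (named by interval) and `cv_percent`
#'   (100 * sd/mean; 0 for a single interval).
#' @export
interval_sweep <- function(mask, path, scale_um_per_px, intervals,
                           window = 5) {
  stopifnot(all(intervals >= 1))
  vols <- vapply(intervals, function(h) {
    measure_worm(mask, path, scale_um_per_px, interval_px = h,
      window = window
    )$volume_pl
  }, numeric(1))
  names(vols) <- intervals
  cv <- if (length(vols) > 1) 100 * stats::sd(vols) / mean(vols) else 0
  list(volumes_pl = vols, cv_percent = cv)
}
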