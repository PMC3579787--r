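#' Invert an 8-bit image
#'
#' @param image intensity matrix in \[0, 255\].
#' @return `255 - image`.
#' @export
invert <- function(image) {
  255 - image
}

#' Rolling-ball background subtraction
#'
#' Corrects uneven illumination by modelling the background as the surface
#' traced by a ball rolled under the image intensity landscape (Sternberg's
#' rolling ball): a grayscale morphological opening with a spherical-cap
#' structuring element of the given radius. The estimated background is
#' replaced by its global mean, so the output is
#' `image - background + mean(background)`, clipped to \[0, 255\].
#'
#' With `light_background = TRUE` (brightfield: dark worms on bright agar)
#' the image is inverted before estimation, and the returned image keeps the
#' objects-bright orientation: worms come out bright on a dark, flat
#' background, ready for `foreground >= t` thresholding.
#'
#' For radii above 15 px the image is first shrunk (factor 2, 4 or 8 by
#' radius, taking the minimum of each block), the opening is computed on the
#' reduced image with a proportionally reduced ball, and the background is
#' upsampled by bilinear interpolation — the standard speed optimization for
#' this filter; the background is smooth at the ball scale so the
#' interpolation error is negligible.
#'
#' @param image intensity matrix in \[0, 255\].
#' @param ball_radius_px ball radius, >= 1.
#' @param light_background logical; TRUE for brightfield images.
#' @return corrected intensity matrix (objects bright).
#' @export
subtract_background <- function(image, ball_radius_px, light_background = TRUE) {
  if (ball_radius_px < 1) stop("ball_radius_px must be >= 1")
  if (ball_radius_px >= max(dim(image))) {
    stop(
      "ball radius (", ball_radius_px, ") must be smaller than the image (",
      nrow(image), "x", ncol(image), ")"
    )
  }
  work <- if (light_background) invert(image) else image
  bg <- rolling_ball_background(work, ball_radius_px)
  out <- round(work - bg + mean(bg))
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

# Background = grayscale opening with a spherical-cap structuring function,
# computed on a shrunk image for large radii.
rolling_ball_background <- function(image, radius) {
  shrink <- if (radius <= 15) {
    1L
  } else if (radius <= 30) {
    2L
  } else if (radius <= 60) {
    4L
  } else {
    8L
  }
  if (shrink == 1L) {
    return(gray_opening_ball(image, radius))
  }
  small <- block_reduce_min(image, shrink)
  bg_small <- gray_opening_ball(small, radius, lateral_scale = shrink)
  upsample_bilinear(bg_small, shrink, nrow(image), ncol(image))
}

# Spherical-cap structuring function for a ball of the given radius:
# height below the cap's top at lateral offset d is sqrt(r^2 - d^2) - r.
# When the image has been shrunk laterally by `lateral_scale`, offsets are
# in shrunk pixels but the intensity axis is unscaled, so the cap keeps its
# full depth (otherwise a too-shallow ball sags into sloped regions).
ball_element <- function(radius, lateral_scale = 1) {
  r_int <- floor(radius / lateral_scale)
  off <- expand.grid(dr = -r_int:r_int, dc = -r_int:r_int)
  d2 <- (off$dr^2 + off$dc^2) * lateral_scale^2
  keep <- d2 <= radius^2
  list(
    dr = off$dr[keep], dc = off$dc[keep],
    z = sqrt(radius^2 - d2[keep]) - radius # <= 0, 0 at center
  )
}

# Grayscale erosion/dilation with a non-flat structuring function, by
# scanning structuring-element offsets with vectorized shifted windows.
gray_opening_ball <- function(image, radius, lateral_scale = 1) {
  se <- ball_element(radius, lateral_scale)
  er <- se_scan(image, se, erode = TRUE)
  se_scan(er, se, erode = FALSE)
}

se_scan <- function(image, se, erode) {
  h <- nrow(image)
  w <- ncol(image)
  r <- max(abs(c(se$dr, se$dc)))
  # replicate-pad: the ball sees the edge value continued beyond the
  # border, avoiding corner bias in the background estimate
  ri <- pmin(pmax(seq_len(h + 2 * r) - r, 1), h)
  ci <- pmin(pmax(seq_len(w + 2 * r) - r, 1), w)
  padded <- image[ri, ci]
  acc <- matrix(if (erode) Inf else -Inf, h, w)
  for (k in seq_along(se$dr)) {
    win <- padded[r + se$dr[k] + seq_len(h), r + se$dc[k] + seq_len(w)]
    acc <- if (erode) pmin(acc, win - se$z[k]) else pmax(acc, win + se$z[k])
  }
  acc
}

# Reduce by integer factor, taking the min of each s x s block (partial
# blocks at the edges are allowed).
block_reduce_min <- function(image, s) {
  h <- nrow(image)
  w <- ncol(image)
  hi <- ceiling(h / s)
  wi <- ceiling(w / s)
  ri <- rep(seq_len(hi), each = s)[seq_len(h)]
  ci <- rep(seq_len(wi), each = s)[seq_len(w)]
  grp <- ri[row(image)] + (ci[col(image)] - 1) * hi
  matrix(
    vapply(split(as.vector(image), grp), min, numeric(1))[as.character(seq_len(hi * wi))],
    hi, wi
  )
}

# Bilinear upsampling of a reduced background grid back to full size.
# Reduced cell (i, j) represents full-resolution block centered at
# ((i-0.5)*s + 0.5, (j-0.5)*s + 0.5).
upsample_bilinear <- function(small, s, h, w) {
  ctr_r <- (seq_len(nrow(small)) - 0.5) * s + 0.5
  ctr_c <- (seq_len(ncol(small)) - 0.5) * s + 0.5
  rf <- stats::approx(ctr_r, seq_len(nrow(small)), xout = seq_len(h), rule = 2)$y
  cf <- stats::approx(ctr_c, seq_len(ncol(small)), xout = seq_len(w), rule = 2)$y
  r0 <- pmin(floor(rf), nrow(small) - 1L)
  r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(cf), ncol(small) - 1L)
  c0 <- pmax(c0, 1L)
  tr <- rf - r0
  tc <- cf - c0
  TR <- matrix(tr, h, w)
  TC <- matrix(tc, h, w, byrow = TRUE)
  R0 <- matrix(r0, h, w)
  C0 <- matrix(c0, h, w, byrow = TRUE)
  v00 <- small[cbind(as.vector(R0), as.vector(C0))]
  v10 <- small[cbind(as.vector(R0 + 1L), as.vector(C0))]
  v01 <- small[cbind(as.vector(R0), as.vector(C0 + 1L))]
  v11 <- small[cbind(as.vector(R0 + 1L), as.vector(C0 + 1L))]
  out <- (1 - TR) * (1 - TC) * matrix(v00, h, w) +
    TR * (1 - TC) * matrix(v10, h, w) +
    (1 - TR) * TC * matrix(v01, h, w) +
    TR * TC * matrix(v11, h, w)
  out
}
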