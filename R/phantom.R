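#' Specification of a synthetic worm phantom
#'
#' A phantom is a radially symmetric tube: a smooth backbone curve with a
#' radius profile `r(u)`, `u` in \[0, 1\], vanishing at both tips, rendered
#' as dark pixels on a bright, optionally tilted and noisy background —
#' emulating a nematode on agar imaged in brightfield. The analytic ground
#' truth (length, mid width, volume, exact mask) is computed alongside the
#' rendering, making phantoms the reference objects for validating the
#' measurement pipeline.
#'
#' @param backbone_control_points (x, y) matrix of control points in px,
#'   x = column, y = row, origin top-left.
#' @param radius_profile function `r(u)` returning the tube radius in px
#'   for `u` in \[0, 1\], with `r(0) = r(1) = 0` and `r >= 0` everywhere.
#' @param image_size `c(width, height)` in px, or NULL to fit the worm
#'   with a 10-px margin beyond the maximum radius.
#' @param background_level,foreground_level intensities in \[0, 255\];
#'   the foreground (worm) must be darker than the background.
#' @param illumination_gradient peak-to-peak intensity of a smooth linear
#'   background ramp, emulating uneven illumination.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param scale_um_per_px physical scale.
#' @param seed integer RNG seed (mandatory: rendering is deterministic).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(backbone_control_points,
                         radius_profile,
                         image_size = NULL,
                         background_level = 200,
                         foreground_level = 60,
                         illumination_gradient = 0,
                         noise_sd = 0,
                         scale_um_per_px = 1,
                         seed = 1L) {
  cp <- as.matrix(backbone_control_points)
  if (nrow(cp) < 2 || ncol(cp) != 2) {
    stop("backbone_control_points must be an n x 2 (x, y) matrix with n >= 2")
  }
  stopifnot(is.function(radius_profile))
  if (foreground_level >= background_level) {
    stop("foreground_level must be darker (smaller) than background_level")
  }
  u <- seq(0, 1, length.out = 201)
  rv <- radius_profile(u)
  if (any(rv < 0)) stop("radius profile must be nonnegative")
  if (rv[1] > 1e-9 || rv[201] > 1e-9) {
    stop("radius profile must vanish at the tips: r(0) = r(1) = 0")
  }
  structure(
    list(
      backbone_control_points = cp,
      radius_profile = radius_profile,
      image_size = image_size,
      background_level = background_level,
      foreground_level = foreground_level,
      illumination_gradient = illumination_gradient,
      noise_sd = noise_sd,
      scale_um_per_px = scale_um_per_px,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Resample a backbone curve at a fixed arclength step
#'
#' Interpolates a natural cubic spline through the control points
#' (parameterized by cumulative chord length) and reparameterizes it by
#' arclength, computed by dense polyline summation at 0.25-px resolution.
#'
#' @param control_points (x, y) matrix with >= 2 rows.
#' @param step arclength spacing of the output points, > 0.
#' @return (x, y) matrix of points ~`step` apart covering the full curve,
#'   with attribute `"arclength"` (total curve length in px).
#' @export
resample_backbone <- function(control_points, step) {
  cp <- as.matrix(control_points)
  if (nrow(cp) < 2) stop("need at least 2 control points")
  stopifnot(step > 0)
  dense <- dense_backbone(cp, 0.25)
  L <- attr(dense, "arclength")
  s_out <- seq(0, L, by = step)
  if (L - s_out[length(s_out)] > 1e-9) s_out <- c(s_out, L)
  cum <- attr(dense, "cumlen")
  x <- stats::approx(cum, dense[, 1], xout = s_out, rule = 2)$y
  y <- stats::approx(cum, dense[, 2], xout = s_out, rule = 2)$y
  out <- cbind(x = x, y = y)
  attr(out, "arclength") <- L
  out
}

# Natural cubic spline through the control points, evaluated densely
# (~`res` px spacing along the curve), with cumulative arclength attached.
dense_backbone <- function(cp, res = 0.25) {
  chord <- c(0, cumsum(sqrt(rowSums(diff(cp)^2))))
  if (any(diff(chord) == 0)) stop("coincident consecutive control points")
  n_dense <- max(16L, ceiling(chord[length(chord)] / res) * 4L)
  tt <- seq(0, chord[length(chord)], length.out = n_dense)
  if (nrow(cp) == 2) {
    x <- stats::approx(chord, cp[, 1], xout = tt)$y
    y <- stats::approx(chord, cp[, 2], xout = tt)$y
  } else {
    x <- stats::spline(chord, cp[, 1], xout = tt, method = "natural")$y
    y <- stats::spline(chord, cp[, 2], xout = tt, method = "natural")$y
  }
  pts <- cbind(x = x, y = y)
  cum <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  attr(pts, "cumlen") <- cum
  attr(pts, "arclength") <- cum[length(cum)]
  pts
}

#' Exact volume of a radius profile by quadrature
#'
#' The volume of a radially symmetric tube is the solid-of-revolution
#' integral \eqn{\int_0^L \pi r(s)^2 ds}, evaluated here by adaptive
#' quadrature to relative error < 1e-6. This is the analytic ground truth
#' against which the frustum summation is validated.
#'
#' @param radius_profile function `r(u)` over `u` in \[0, 1\] (px).
#' @param length_px curve length `L`, > 0.
#' @return volume in cubic pixels.
#' @export
true_volume <- function(radius_profile, length_px) {
  stopifnot(length_px > 0)
  u <- seq(0, 1, length.out = 1001)
  if (any(radius_profile(u) < 0)) stop("radius profile must be nonnegative")
  stats::integrate(
    function(u) pi * radius_profile(u)^2 * length_px,
    0, 1,
    rel.tol = 1e-9, subdivisions = 500L
  )$value
}

#' Render a phantom image with its ground truth
#'
#' Rasterization rule: a pixel is foreground iff its center lies within
#' distance `r(u*)` of the backbone, where `u*` is the nearest backbone
#' parameter found by dense sampling at 0.25 px. The background is
#' `background_level` plus a smooth linear ramp of the requested
#' peak-to-peak amplitude; foreground pixels are set to
#' `foreground_level`; Gaussian noise of sd `noise_sd` is added last and
#' the result rounded and clipped to \[0, 255\]. Ground truth is computed
#' before noise. Rendering is deterministic for a fixed seed and leaves the
#' global RNG state untouched.
#'
#' @param spec a [phantom_spec()].
#' @return list with `image` (intensity matrix with scale attribute),
#'   `truth` (a `phantom_truth` list: `length_px`, `mid_width_px`,
#'   `volume_px3`, `mask`, `length_um`, `mid_width_um`, `volume_pl`) and
#'   the `spec`.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dense <- dense_backbone(spec$backbone_control_points, 0.25)
  cum <- attr(dense, "cumlen")
  L <- attr(dense, "arclength")
  u <- cum / L
  r <- spec$radius_profile(u)
  max_r <- max(r)
  check_self_intersection(dense, cum, u, max_r)

  margin <- max_r + 10
  if (is.null(spec$image_size)) {
    xmin <- floor(min(dense[, 1]) - margin)
    ymin <- floor(min(dense[, 2]) - margin)
    # shift the worm so the image starts at pixel (1, 1)
    dense[, 1] <- dense[, 1] - xmin + 1
    dense[, 2] <- dense[, 2] - ymin + 1
    w <- ceiling(max(dense[, 1]) + margin)
    h <- ceiling(max(dense[, 2]) + margin)
  } else {
    w <- spec$image_size[1]
    h <- spec$image_size[2]
    if (min(dense[, 1]) < margin || max(dense[, 1]) > w - margin + 1 ||
      min(dense[, 2]) < margin || max(dense[, 2]) > h - margin + 1) {
      stop("image_size too small to contain the worm plus a 10-px margin")
    }
  }

  mask <- rasterize_tube(dense, r, h, w)
  bg <- matrix(spec$background_level, h, w)
  if (spec$illumination_gradient != 0) {
    ramp <- outer(seq_len(h) / h, seq_len(w) / w, function(a, b) (a + b) / 2)
    bg <- bg + spec$illumination_gradient * (ramp - 0.5)
  }
  img <- bg
  img[mask] <- spec$foreground_level
  if (spec$noise_sd > 0) {
    noise <- with_preserved_rng(spec$seed, {
      matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w)
    })
    img <- img + noise
  }
  img <- round(img)
  img[img < 0] <- 0
  img[img > 255] <- 255
  attr(img, "scale_um_per_px") <- spec$scale_um_per_px
  k <- spec$scale_um_per_px
  vol_px3 <- true_volume(spec$radius_profile, L)
  truth <- structure(
    list(
      length_px = L,
      mid_width_px = 2 * spec$radius_profile(0.5),
      volume_px3 = vol_px3,
      mask = mask,
      backbone = dense,
      length_um = L * k,
      mid_width_um = 2 * spec$radius_profile(0.5) * k,
      volume_pl = vol_px3 * k^3 / 1000
    ),
    class = "phantom_truth"
  )
  list(image = img, truth = truth, spec = spec)
}

# Reject backbones that approach themselves: any two samples separated by
# more than 4 * max_r of arclength must be at least 2 * max_r apart.
check_self_intersection <- function(dense, cum, u, max_r) {
  if (max_r <= 0) {
    return(invisible(TRUE))
  }
  keep <- seq(1, nrow(dense), by = 8) # ~2-px spacing
  p <- dense[keep, , drop = FALSE]
  s <- cum[keep]
  uu <- u[keep]
  n <- nrow(p)
  if (n < 3) {
    return(invisible(TRUE))
  }
  d2 <- as.matrix(stats::dist(p))^2
  sep <- abs(outer(s, s, "-"))
  bad <- which(sep > 4 * max_r & d2 < (2 * max_r)^2, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]
    j <- bad[1, 2]
    stop(sprintf(
      "backbone self-intersects within tube diameter near u = %.3f and u = %.3f",
      uu[i], uu[j]
    ))
  }
  invisible(TRUE)
}

# Foreground = pixel centers within r(u*) of the backbone, u* the nearest
# dense sample. The nearest sample is found by scanning the dense samples
# and keeping the first strict minimum per pixel (deterministic ties), each
# sample only updating the window of pixels that could possibly be
# foreground (within max(r) + 1 of some sample).
rasterize_tube <- function(dense, r, h, w) {
  max_r <- max(r)
  mask <- matrix(FALSE, h, w)
  if (max_r <= 0) {
    return(mask)
  }
  rmin <- max(1L, as.integer(floor(min(dense[, 2]) - max_r - 1)))
  rmax <- min(h, as.integer(ceiling(max(dense[, 2]) + max_r + 1)))
  cmin <- max(1L, as.integer(floor(min(dense[, 1]) - max_r - 1)))
  cmax <- min(w, as.integer(ceiling(max(dense[, 1]) + max_r + 1)))
  nr <- rmax - rmin + 1L
  nc <- cmax - cmin + 1L
  bestd2 <- matrix(Inf, nr, nc)
  bestidx <- matrix(0L, nr, nc)
  win <- as.integer(ceiling(max_r)) + 1L
  for (j in seq_len(nrow(dense))) {
    x <- dense[j, 1]
    y <- dense[j, 2]
    r1 <- max(1L, as.integer(floor(y - win)) - rmin + 1L)
    r2 <- min(nr, as.integer(ceiling(y + win)) - rmin + 1L)
    c1 <- max(1L, as.integer(floor(x - win)) - cmin + 1L)
    c2 <- min(nc, as.integer(ceiling(x + win)) - cmin + 1L)
    if (r1 > r2 || c1 > c2) next
    dr <- (r1:r2) + rmin - 1L - y
    dc <- (c1:c2) + cmin - 1L - x
    d2 <- outer(dr^2, dc^2, "+")
    sub_best <- bestd2[r1:r2, c1:c2]
    upd <- d2 < sub_best
    if (any(upd)) {
      sub_best[upd] <- d2[upd]
      bestd2[r1:r2, c1:c2] <- sub_best
      sub_idx <- bestidx[r1:r2, c1:c2]
      sub_idx[upd] <- j
      bestidx[r1:r2, c1:c2] <- sub_idx
    }
  }
  hit <- bestidx > 0L
  fg <- hit & sqrt(bestd2) <= matrix(r[pmax(bestidx, 1L)], nr, nc)
  mask[rmin:rmax, cmin:cmax] <- fg
  mask
}

# Evaluate expr with a private RNG stream; global .Random.seed untouched.
with_preserved_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Worm-like radius profile
#'
#' A smooth mid-plateaued profile `r(u) = r_mid * sin(pi u)^p`: near the
#' mid-body the radius is close to `r_mid`, tapering smoothly to zero at
#' both tips. The default exponent 0.4 gives the broad middle and short
#' taper typical of C. elegans larvae and adults.
#'
#' @param r_mid mid-body radius in px.
#' @param p taper exponent (smaller = blunter tips).
#' @return function `r(u)`.
#' @export
worm_radius_profile <- function(r_mid, p = 0.4) {
  force(r_mid)
  force(p)
  function(u) {
    r <- r_mid * sin(pi * pmin(pmax(u, 0), 1))^p
    r[u <= 0 | u >= 1] <- 0
    r
  }
}

#' Default phantom specs at the two study scales
#'
#' `phantom_adult()` mimics a 48-h young adult (length ~720 um, mid radius
#' ~30 um) and `phantom_l1()` an arrested L1 larva (length ~205 um, mid
#' radius ~10 um). The backbone is a gentle sinusoid; `bend` scales its
#' amplitude.
#'
#' @param seed RNG seed for the rendering noise.
#' @param scale_um_per_px physical scale (defaults chosen so the adult spans
#'   ~400 px, matching typical stereomicroscope zooms).
#' @param noise_sd,illumination_gradient imaging imperfections (intensity
#'   units).
#' @param bend backbone sinusoid amplitude factor (0 = straight).
#' @param angle_deg rigid rotation of the backbone about its start.
#' @return a [phantom_spec()].
#' @export
phantom_adult <- function(seed = 1L, scale_um_per_px = 1.8, noise_sd = 3,
                          illumination_gradient = 30, bend = 1,
                          angle_deg = 0) {
  len_px <- 720 / scale_um_per_px
  r_mid <- 30 / scale_um_per_px
  make_bent_spec(len_px, r_mid, seed, scale_um_per_px, noise_sd,
    illumination_gradient, bend, angle_deg
  )
}

#' @rdname phantom_adult
#' @export
phantom_l1 <- function(seed = 1L, scale_um_per_px = 0.5, noise_sd = 3,
                       illumination_gradient = 30, bend = 1,
                       angle_deg = 0) {
  len_px <- 205 / scale_um_per_px
  r_mid <- 10 / scale_um_per_px
  make_bent_spec(len_px, r_mid, seed, scale_um_per_px, noise_sd,
    illumination_gradient, bend, angle_deg
  )
}

make_bent_spec <- function(len_px, r_mid, seed, scale_um_per_px, noise_sd,
                           illumination_gradient, bend, angle_deg) {
  # control points along a chord with a sinusoidal offset; the arclength
  # slightly exceeds the chord, so shrink the chord to land near len_px
  amp <- bend * 0.08 * len_px
  chord <- len_px * 0.985^(bend^2)
  x <- seq(0, chord, length.out = 9)
  y <- amp * sin(seq(0, pi, length.out = 9))
  cp <- cbind(x, y)
  if (angle_deg != 0) {
    a <- angle_deg * pi / 180
    rot <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
    cp <- cp %*% t(rot)
  }
  phantom_spec(
    backbone_control_points = cp,
    radius_profile = worm_radius_profile(r_mid),
    background_level = 200,
    foreground_level = 60,
    illumination_gradient = illumination_gradient,
    noise_sd = noise_sd,
    scale_um_per_px = scale_um_per_px,
    seed = seed
  )
}

#' Write a set of phantoms to disk with a truth table
#'
#' Renders each spec to an 8-bit grayscale PNG and writes `truth.csv`
#' (columns: file, length_px, mid_width_px, volume_px3, length_um,
#' volume_pl, scale_um_per_px, seed).
#'
#' @param specs list of [phantom_spec()] objects.
#' @param out_dir output directory (created if needed).
#' @return path of the truth CSV, invisibly.
#' @export
write_phantom_set <- function(specs, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(specs), function(i) {
    ph <- render_phantom(specs[[i]])
    file <- sprintf("phantom_%03d.png", i)
    write_image(ph$image, file.path(out_dir, file))
    data.frame(
      file = file,
      length_px = ph$truth$length_px,
      mid_width_px = ph$truth$mid_width_px,
      volume_px3 = ph$truth$volume_px3,
      length_um = ph$truth$length_um,
      volume_pl = ph$truth$volume_pl,
      scale_um_per_px = specs[[i]]$scale_um_per_px,
      seed = specs[[i]]$seed
    )
  })
  truth <- do.call(rbind, rows)
  path <- file.path(out_dir, "truth.csv")
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
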