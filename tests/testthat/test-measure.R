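test_that("radius sampling recovers the half-height of a rectangle", {
  mask <- rect_mask(21, 100)
  path <- structure(
    list(points = cbind(rep(11, 100), 1:100), length_px = 99, prune_ratio = 1),
    class = "skeleton_path"
  )
  prof <- sample_radii(mask, path, interval_px = 10)
  interior <- prof$r[prof$s > 0 & prof$s < max(prof$s)]
  expect_true(all(abs(interior - 10) <= 0.5))
  # tips are zero by construction, positions strictly increasing to the end
  expect_equal(prof$r[1], 0)
  expect_equal(prof$r[nrow(prof)], 0)
  expect_equal(prof$s[1], 0)
  expect_equal(prof$s[nrow(prof)], 99)
  expect_true(all(diff(prof$s) > 0))
})

test_that("degenerate 1-px masks give sub-half-pixel radii", {
  mask <- matrix(FALSE, 5, 30)
  mask[3, 2:29] <- TRUE
  path <- cbind(rep(3, 28), 2:29)
  prof <- sample_radii(mask, path, interval_px = 5)
  expect_true(all(prof$r <= 0.5))
})

test_that("sampled radii track the phantom's analytic profile", {
  spec <- phantom_adult(seed = 13, noise_sd = 0, illumination_gradient = 0)
  ph <- render_phantom(spec)
  # measure along the true backbone ((x,y) -> (row,col))
  bb <- ph$truth$backbone
  path <- cbind(bb[, 2], bb[, 1])
  prof <- sample_radii(ph$truth$mask, path, interval_px = 10)
  L <- ph$truth$length_px
  true_r <- spec$radius_profile(prof$s / L)
  # compare away from the tips, where the sampled radius is r = 0 by
  # construction while the analytic profile is still nonzero
  body <- prof$s >= 2 & prof$s <= L - 2
  expect_true(all(abs(prof$r - true_r)[body] <= 1))
})

test_that("frustum sums are exact for cylinders and cones", {
  cyl <- data.frame(s = seq(0, 100, by = 10), r = 10)
  expect_equal(frustum_volume(cyl), pi * 100 * 100, tolerance = 1e-12)
  cone <- data.frame(s = seq(0, 90, by = 10), r = 10 * (1 - seq(0, 90, by = 10) / 90))
  expect_equal(frustum_volume(cone), pi * 100 * 90 / 3, tolerance = 1e-12)
  # irregular spacing changes nothing for linear tapers
  s_irr <- c(0, 7, 13, 40, 41, 90)
  cone_irr <- data.frame(s = s_irr, r = 10 * (1 - s_irr / 90))
  expect_equal(frustum_volume(cone_irr), pi * 100 * 90 / 3, tolerance = 1e-12)
})

test_that("frustum sums converge to the quadrature volume for curved profiles", {
  s <- seq(0, 100, by = 5)
  prof <- data.frame(s = s, r = 10 * sin(pi * s / 100))
  truth <- true_volume(function(u) 10 * sin(pi * u), 100)
  expect_lt(abs(frustum_volume(prof) - truth) / truth, 0.01)
})

test_that("frustum volume is monotone under pointwise radius increase", {
  set.seed(3)
  for (i in 1:20) {
    s <- sort(c(0, runif(8, 1, 99), 100))
    r1 <- runif(10, 0, 5)
    r2 <- r1 + runif(10, 0, 2)
    expect_gte(
      frustum_volume(data.frame(s = s, r = r2)),
      frustum_volume(data.frame(s = s, r = r1))
    )
  }
})

test_that("degenerate profiles warn and return zero", {
  expect_warning(v <- frustum_volume(data.frame(s = 0, r = 5)), "fewer than 2")
  expect_equal(v, 0)
})

test_that("cylinder approximation matches closed form and study magnitudes", {
  expect_equal(cylinder_volume(100, 20), pi * 100 * 100, tolerance = 1e-12)
  expect_equal(cylinder_volume(100, 0), 0)
  # L1-arrest magnitudes: length 205 um, mid width 20.2 um -> ~65.7 pl,
  # the order of the reported mean cylinder volume (66.3 pl)
  v_pl <- cylinder_volume(205, 20.2) / 1000
  expect_equal(v_pl, 65.70, tolerance = 0.01)
  expect_lt(abs(v_pl - 66.3) / 66.3, 0.1)
})

test_that("cylinder approximation exceeds frustum volume for mid-widest worms", {
  set.seed(5)
  for (i in 1:20) {
    s <- seq(0, 100, length.out = 21)
    u <- s / 100
    rmid <- runif(1, 3, 15)
    p <- runif(1, 0.3, 2)
    prof <- data.frame(s = s, r = rmid * sin(pi * u)^p)
    expect_gte(
      cylinder_volume(100, 2 * rmid),
      frustum_volume(prof)
    )
  }
})

test_that("unit conversion follows the cubic scaling law", {
  prof <- data.frame(s = seq(0, 100, by = 10), r = 10)
  m1 <- nemameter:::measure_profile(prof, scale_um_per_px = 1)
  expect_equal(m1$volume_pl, 31.41593, tolerance = 1e-4)
  expect_equal(m1$length_um, 100)
  m2 <- nemameter:::measure_profile(prof, scale_um_per_px = 0.5)
  expect_equal(m2$length_um, m1$length_um / 2)
  expect_equal(m2$volume_pl, m1$volume_pl / 8)
  expect_equal(m2$volume_px3, m1$volume_px3)
})

test_that("volume is stable across sampling intervals", {
  # constant-radius profiles: every interval gives the exact same volume
  vols <- vapply(c(5, 10, 20, 40), function(h) {
    s <- unique(c(seq(0, 100, by = h), 100))
    frustum_volume(data.frame(s = s, r = 10))
  }, numeric(1))
  expect_lt(100 * stats::sd(vols) / mean(vols), 0.5)

  # tapered phantom ~396 px long through the pipeline
  ph <- render_phantom(phantom_adult(seed = 31))
  res <- process_image(ph$image, run_config(), 1.8)
  worm <- res$worms[[which(sapply(res$worms, `[[`, "status") == "measured")[1]]]
  path <- structure(
    list(points = worm$path, length_px = path_length(worm$path), prune_ratio = 1),
    class = "skeleton_path"
  )
  sw <- interval_sweep(worm$mask, path, 1.8, seq(5, 40, by = 5))
  expect_lte(sw$cv_percent, 2.3)

  # single interval: CV is zero by definition
  expect_equal(interval_sweep(worm$mask, path, 1.8, 10)$cv_percent, 0)
})

test_that("the full pipeline recovers phantom truth within tolerance", {
  for (seed in c(41, 42, 43)) {
    spec <- phantom_adult(seed = seed)
    ph <- render_phantom(spec)
    res <- process_image(ph$image, run_config(), spec$scale_um_per_px)
    st <- sapply(res$worms, `[[`, "status")
    worm <- res$worms[[which(st == "measured")[1]]]
    m <- worm$measurement
    expect_lt(abs(m$volume_px3 - ph$truth$volume_px3) / ph$truth$volume_px3, 0.05)
    expect_lt(abs(m$length_px - ph$truth$length_px) / ph$truth$length_px, 0.03)
    expect_lt(
      abs(m$mid_width_px - ph$truth$mid_width_px) / ph$truth$mid_width_px,
      0.10
    )
  }
})
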