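test_that("lossless formats round-trip intensity-identically", {
  img <- matrix(sample(0:255, 40 * 30, replace = TRUE), 40, 30)
  dir <- withr::local_tempdir()
  for (ext in c("png", "tiff", "bmp")) {
    path <- file.path(dir, paste0("x.", ext))
    write_image(img, path)
    back <- load_image(path)
    expect_identical(unname(back), unname(img * 1.0), label = ext)
  }
})

test_that("zero and gray images load as expected", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "zero.png")
  png::writePNG(matrix(0, 10, 10), p)
  expect_true(all(load_image(p) == 0))

  # RGB uniform gray (128,128,128) -> 128 via luminance weighting
  rgb <- array(128 / 255, c(6, 6, 3))
  p2 <- file.path(dir, "gray.png")
  png::writePNG(rgb, p2)
  expect_true(all(load_image(p2) == 128))

  # same through JPEG (uniform images survive the lossy codec)
  p3 <- file.path(dir, "gray.jpg")
  jpeg::writeJPEG(rgb, p3, quality = 1)
  expect_true(all(load_image(p3) == 128))
})

test_that("16-bit TIFF input is min-max rescaled so the max maps to 255", {
  dir <- withr::local_tempdir()
  x <- matrix(seq(1000, 30000, length.out = 64) / 65535, 8, 8)
  p <- file.path(dir, "deep.tiff")
  tiff::writeTIFF(x, p, bits.per.sample = 16L)
  img <- load_image(p)
  expect_equal(max(img), 255)
  expect_equal(min(img), 0)
})

test_that("unsupported or missing files raise I/O errors naming the path", {
  expect_error(load_image("/no/such/file.png"), "file.png")
  dir <- withr::local_tempdir()
  p <- file.path(dir, "x.gif")
  writeLines("not an image", p)
  expect_error(load_image(p), "gif")
})

test_that("scale interpolation is linear, exact at entries, refuses extrapolation", {
  tab <- scale_table(c(10, 20, 40), c(1.0, 0.5, 0.25))
  expect_equal(scale_for_zoom(tab, 15), 0.75)
  expect_equal(scale_for_zoom(tab, 10), 1.0)
  expect_equal(scale_for_zoom(tab, 30), 0.375)
  expect_error(scale_for_zoom(tab, 50), "outside recorded range")
  expect_error(scale_table(c(10, 10), c(1, 2)), "distinct")
  # monotone between entries when entries are monotone
  z <- seq(10, 40, by = 1)
  s <- scale_for_zoom(tab, z)
  expect_true(all(diff(s) <= 0))
})

test_that("measurement CSVs round-trip losslessly", {
  cfg <- run_config()
  prof <- data.frame(s = c(0, 50, 100), r = c(0, 10.123456789, 0))
  m <- nemameter:::measure_profile(prof, scale_um_per_px = 1 / 3)
  rec <- measurement_record(
    "img.png", "img_w01", TRUE, m,
    scale_um_per_px = 1 / 3, prune_ratio = 0.987654321, config = cfg
  )
  dir <- withr::local_tempdir()
  p <- file.path(dir, "m.csv")
  write_measurements(rec, p)
  back <- read_measurements(p)
  expect_identical(back$volume_pl, rec$volume_pl)
  expect_identical(back$length_um, rec$length_um)
  expect_identical(back$prune_ratio, rec$prune_ratio)
  expect_match(back$settings_echo, "ball_radius_px")

  # aggregate round trip over many records
  recs <- do.call(rbind, lapply(1:50, function(i) {
    r <- rec
    r$volume_pl <- rec$volume_pl * i / 7
    r$worm_id <- paste0("w", i)
    r
  }))
  write_measurements(recs, p)
  expect_identical(mean(read_measurements(p)$volume_pl), mean(recs$volume_pl))

  # empty records -> header-only file
  write_measurements(recs[0, ], p)
  expect_length(readLines(p), 1)
})

test_that("overlays show contour, skeleton and radius chords in their colors", {
  ph <- render_phantom(phantom_l1(seed = 6, scale_um_per_px = 1))
  res <- process_image(ph$image, run_config(), 1)
  worm <- res$worms[[which(sapply(res$worms, `[[`, "status") == "measured")[1]]]
  ov <- render_overlay(ph$image, worm)
  is_col <- function(r, g, b) {
    ov[, , 1] == r & ov[, , 2] == g & ov[, , 3] == b
  }
  expect_gt(sum(is_col(1, 1, 0)), 0) # yellow contour
  expect_gt(sum(is_col(0, 0, 1)), 0) # blue skeleton
  expect_gt(sum(is_col(0, 1, 1)), 0) # cyan chords

  # no cyan when the radius profile is empty
  worm2 <- worm
  worm2$profile <- worm$profile[0, ]
  ov2 <- render_overlay(ph$image, worm2)
  expect_equal(sum(ov2[, , 1] == 0 & ov2[, , 2] == 1 & ov2[, , 3] == 1), 0)

  # missing skeleton: contour-only with a warning
  worm3 <- worm
  worm3$path <- NULL
  worm3$profile <- NULL
  expect_warning(ov3 <- render_overlay(ph$image, worm3), "contour only")
  expect_gt(sum(ov3[, , 1] == 1 & ov3[, , 2] == 1 & ov3[, , 3] == 0), 0)
})

test_that("blue overlay pixels are exactly the path pixels for a straight worm", {
  ph <- render_phantom(phantom_l1(
    seed = 3, scale_um_per_px = 1, bend = 0,
    noise_sd = 0, illumination_gradient = 0
  ))
  res <- process_image(ph$image, run_config(), 1)
  worm <- res$worms[[1]]
  expect_equal(worm$status, "measured")
  ov <- render_overlay(ph$image, worm)
  blue <- which(ov[, , 1] == 0 & ov[, , 2] == 0 & ov[, , 3] == 1, arr.ind = TRUE)
  path_px <- unique(round(worm$path))
  expect_setequal(
    paste(blue[, 1], blue[, 2]),
    paste(path_px[, 1], path_px[, 2])
  )
})
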