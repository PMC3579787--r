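#' Read a grayscale image as an 8-bit intensity matrix
#'
#' Images are represented throughout the package as plain numeric matrices
#' with integer values in \[0, 255\], indexed `[row, col]` with the origin at
#' the top-left and pixel centers at integer coordinates. Supported formats
#' are TIFF, PNG, JPEG and BMP. Multi-channel inputs are converted to
#' grayscale by Rec. 601 luminance weighting (0.299 R + 0.587 G + 0.114 B)
#' and rounded; images deeper than 8 bits are rescaled to \[0, 255\] by
#' min-max mapping.
#'
#' @param path path to a TIFF, PNG, JPEG or BMP file.
#' @param scale_um_per_px optional physical scale attached to the result as
#'   attribute `"scale_um_per_px"`.
#' @return numeric matrix of intensities in \[0, 255\].
#' @export
load_image <- function(path, scale_um_per_px = NULL) {
  if (!file.exists(path)) {
    stop("image file does not exist: ", path)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    png = round(png::readPNG(path) * 255),
    jpg = ,
    jpeg = round(jpeg::readJPEG(path) * 255),
    bmp = read_bmp(path),
    stop("unsupported image format '", ext, "': ", path)
  )
  img <- to_gray8(raw)
  if (!is.null(scale_um_per_px)) {
    attr(img, "scale_um_per_px") <- scale_um_per_px
  }
  img
}

# Collapse channels by luminance, rescale >8-bit data, round to integers.
to_gray8 <- function(x) {
  if (length(dim(x)) == 3) {
    nch <- dim(x)[3]
    if (nch >= 3) {
      x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
    } else {
      x <- x[, , 1]
    }
  }
  x <- as.matrix(x)
  if (max(x) > 255) {
    rng <- range(x)
    x <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1]) * 255 else x * 0
  }
  m <- round(x)
  m[m < 0] <- 0
  m[m > 255] <- 255
  m
}

#' Write an 8-bit grayscale image
#'
#' PNG, TIFF and BMP are supported (all lossless); JPEG is deliberately not
#' written. Re-reading a written image reproduces the matrix exactly.
#'
#' @param image intensity matrix in \[0, 255\].
#' @param path output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  norm <- pmin(pmax(round(image), 0), 255) / 255
  switch(ext,
    png = png::writePNG(norm, path),
    tif = ,
    tiff = tiff::writeTIFF(norm, path, bits.per.sample = 8L),
    bmp = write_bmp(pmin(pmax(round(image), 0), 255), path),
    stop("unsupported output format '", ext, "' (use png, tiff or bmp)")
  )
  invisible(path)
}

# Minimal reader for uncompressed Windows BMP (8-bit palette or 24-bit BGR).
# Returns a matrix (8-bit gray) or array h x w x 3 in [0,255].
read_bmp <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 2)
  if (!identical(rawToChar(magic), "BM")) {
    stop("not a BMP file: ", path)
  }
  readBin(con, "integer", 1, 4)              # file size
  readBin(con, "integer", 2, 2)              # reserved
  data_offset <- readBin(con, "integer", 1, 4)
  header_size <- readBin(con, "integer", 1, 4)
  if (header_size < 40) stop("unsupported BMP header in ", path)
  width <- readBin(con, "integer", 1, 4)
  height <- readBin(con, "integer", 1, 4)
  readBin(con, "integer", 1, 2)              # planes
  bpp <- readBin(con, "integer", 1, 2)
  compression <- readBin(con, "integer", 1, 4)
  if (compression != 0) stop("compressed BMP not supported: ", path)
  if (!bpp %in% c(8L, 24L)) {
    stop("only 8-bit and 24-bit BMP supported (got ", bpp, "-bit): ", path)
  }
  bottom_up <- height > 0
  height <- abs(height)
  palette <- NULL
  if (bpp == 8L) {
    seek(con, 14 + header_size)
    ncol_pal <- (data_offset - 14 - header_size) %/% 4
    pal_raw <- readBin(con, "raw", ncol_pal * 4)
    pal <- matrix(as.integer(pal_raw), ncol = 4, byrow = TRUE)  # B,G,R,0
    palette <- 0.299 * pal[, 3] + 0.587 * pal[, 2] + 0.114 * pal[, 1]
  }
  seek(con, data_offset)
  bytes_per_px <- bpp %/% 8
  row_bytes <- ((width * bytes_per_px + 3) %/% 4) * 4
  data <- readBin(con, "raw", row_bytes * height)
  rows <- matrix(as.integer(data), nrow = row_bytes)[seq_len(width * bytes_per_px), , drop = FALSE]
  row_order <- if (bottom_up) rev(seq_len(height)) else seq_len(height)
  if (bpp == 8L) {
    img <- matrix(0, height, width)
    img[row_order, ] <- t(rows)
    round(matrix(palette[img + 1], height, width))
  } else {
    b <- rows[seq(1, width * 3, by = 3), , drop = FALSE]
    g <- rows[seq(2, width * 3, by = 3), , drop = FALSE]
    r <- rows[seq(3, width * 3, by = 3), , drop = FALSE]
    out <- array(0, c(height, width, 3))
    out[row_order, , 1] <- t(r)
    out[row_order, , 2] <- t(g)
    out[row_order, , 3] <- t(b)
    out
  }
}

# Minimal writer: 8-bit grayscale palette BMP, bottom-up, uncompressed.
write_bmp <- function(image, path) {
  image <- as.matrix(image)
  h <- nrow(image)
  w <- ncol(image)
  row_bytes <- ((w + 3) %/% 4) * 4
  data_offset <- 14L + 40L + 256L * 4L
  file_size <- data_offset + row_bytes * h
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  writeBin(as.integer(file_size), con, 4)
  writeBin(c(0L, 0L), con, 2)
  writeBin(as.integer(data_offset), con, 4)
  writeBin(40L, con, 4)
  writeBin(as.integer(w), con, 4)
  writeBin(as.integer(h), con, 4)          # positive: bottom-up
  writeBin(1L, con, 2)
  writeBin(8L, con, 2)
  writeBin(0L, con, 4)                     # no compression
  writeBin(as.integer(row_bytes * h), con, 4)
  writeBin(c(2835L, 2835L), con, 4)        # 72 dpi
  writeBin(c(256L, 0L), con, 4)
  pal <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
  writeBin(pal, con)
  pad <- row_bytes - w
  for (i in rev(seq_len(h))) {
    writeBin(as.raw(image[i, ]), con)
    if (pad > 0) writeBin(raw(pad), con)
  }
  invisible(path)
}

#' Build a zoom-to-scale calibration table
#'
#' Micrometer calibrations recorded at discrete zoom levels of a
#' stereomicroscope. Scales for zooms between recorded levels are obtained
#' by linear interpolation; zooms outside the recorded range are refused
#' (no extrapolation).
#'
#' @param zoom numeric vector of distinct zoom levels.
#' @param um_per_px positive scale (microns per pixel) at each zoom.
#' @return a `scale_table` data frame sorted by zoom.
#' @export
scale_table <- function(zoom, um_per_px) {
  if (length(zoom) < 1 || length(zoom) != length(um_per_px)) {
    stop("zoom and um_per_px must be nonempty vectors of equal length")
  }
  if (anyDuplicated(zoom)) stop("zoom levels must be distinct")
  if (any(um_per_px <= 0)) stop("all scales must be > 0")
  ord <- order(zoom)
  structure(
    data.frame(zoom = zoom[ord], um_per_px = um_per_px[ord]),
    class = c("scale_table", "data.frame")
  )
}

#' Read a scale table from a `zoom,um_per_px` CSV
#' @param path CSV file with columns `zoom` and `um_per_px`.
#' @return a [scale_table()].
#' @export
read_scale_table <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("zoom", "um_per_px") %in% names(df))) {
    stop("scale table must have columns 'zoom' and 'um_per_px': ", path)
  }
  scale_table(df$zoom, df$um_per_px)
}

#' Interpolate the image scale at a zoom level
#'
#' Exact at recorded zooms; linear interpolation between the two bracketing
#' recorded zooms otherwise.
#'
#' @param table a [scale_table()].
#' @param zoom zoom level(s) to resolve.
#' @return microns per pixel.
#' @export
scale_for_zoom <- function(table, zoom) {
  if (nrow(table) == 0) stop("scale table is empty")
  out_of_range <- zoom < min(table$zoom) | zoom > max(table$zoom)
  if (any(out_of_range)) {
    stop(
      "zoom ", paste(zoom[out_of_range], collapse = ", "),
      " outside recorded range [", min(table$zoom), ", ", max(table$zoom),
      "]; no extrapolation"
    )
  }
  if (nrow(table) == 1) {
    return(rep(table$um_per_px, length(zoom)))
  }
  stats::approx(table$zoom, table$um_per_px, xout = zoom, rule = 1)$y
}

#' Processing configuration for the measurement pipeline
#'
#' Holds every tunable parameter of the image-processing chain with its
#' default. Values are validated on construction.
#'
#' @param ball_radius_px rolling-ball radius for background subtraction.
#' @param light_background TRUE for brightfield (dark worms, bright agar).
#' @param threshold_algorithm name of the thresholding rule; only
#'   `"minimum"` is built in.
#' @param area_min_px2,area_max_px2 candidate area filter bounds.
#' @param prune_ratio_min minimum pruned/original skeleton length ratio.
#' @param interval_px radius sampling interval along the skeleton.
#' @param extension_window_px number of path points used for tangent fits
#'   at the tips.
#' @param path_smooth_window moving-average window (points) applied to the
#'   pruned path before extension and measurement; see [smooth_path()].
#' @return a `run_config` list.
#' @export
run_config <- function(ball_radius_px = 50,
                       light_background = TRUE,
                       threshold_algorithm = "minimum",
                       area_min_px2 = 100,
                       area_max_px2 = 1e6,
                       prune_ratio_min = 0.8,
                       interval_px = 10,
                       extension_window_px = 5,
                       path_smooth_window = 7) {
  stopifnot(
    ball_radius_px >= 1,
    interval_px >= 1,
    prune_ratio_min >= 0, prune_ratio_min <= 1,
    area_min_px2 < area_max_px2,
    extension_window_px >= 2,
    path_smooth_window >= 1
  )
  if (!identical(threshold_algorithm, "minimum")) {
    stop("only the 'minimum' threshold algorithm is built in")
  }
  structure(
    list(
      ball_radius_px = ball_radius_px,
      light_background = isTRUE(light_background),
      threshold_algorithm = threshold_algorithm,
      area_min_px2 = area_min_px2,
      area_max_px2 = area_max_px2,
      prune_ratio_min = prune_ratio_min,
      interval_px = interval_px,
      extension_window_px = extension_window_px,
      path_smooth_window = path_smooth_window
    ),
    class = "run_config"
  )
}

#' Write worm measurements to CSV
#'
#' One row per worm with sizes in absolute units plus an echo of the
#' processing settings. Numbers are written with full precision (17
#' significant digits) so that re-reading reproduces values exactly.
#'
#' @param records data frame of measurement records (see
#'   [measurement_record()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  out <- records
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) sprintf("%.17g", x))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a measurements CSV written by [write_measurements()]
#' @param path CSV path.
#' @return data frame with numeric measurement columns.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in intersect(measurement_numeric_cols, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

measurement_numeric_cols <- c(
  "length_um", "avg_width_um", "mid_width_um", "volume_pl",
  "cylinder_volume_pl", "scale_um_per_px", "length_px", "avg_width_px",
  "mid_width_px", "volume_px3", "cylinder_volume_px3", "prune_ratio"
)

#' Assemble a measurement record row
#'
#' @param image_file source image file name.
#' @param worm_id worm identifier, unique within a run.
#' @param pass_flag logical quality flag.
#' @param measurement a `worm_measurement` from [measure_worm()].
#' @param scale_um_per_px scale used.
#' @param prune_ratio pruned/original skeleton length ratio.
#' @param config the [run_config()] used (echoed as compact JSON).
#' @return one-row data frame.
#' @export
measurement_record <- function(image_file, worm_id, pass_flag, measurement,
                               scale_um_per_px, prune_ratio, config) {
  data.frame(
    image_file = image_file,
    worm_id = worm_id,
    pass_flag = pass_flag,
    length_um = measurement$length_um,
    avg_width_um = measurement$avg_width_um,
    mid_width_um = measurement$mid_width_um,
    volume_pl = measurement$volume_pl,
    cylinder_volume_pl = measurement$cylinder_volume_pl,
    length_px = measurement$length_px,
    avg_width_px = measurement$avg_width_px,
    mid_width_px = measurement$mid_width_px,
    volume_px3 = measurement$volume_px3,
    cylinder_volume_px3 = measurement$cylinder_volume_px3,
    prune_ratio = prune_ratio,
    scale_um_per_px = scale_um_per_px,
    settings_echo = as.character(jsonlite::toJSON(unclass(config),
      auto_unbox = TRUE, digits = NA
    )),
    stringsAsFactors = FALSE
  )
}

#' Render a review overlay for one worm
#'
#' Draws the worm contour in yellow, its medial path in blue, and the
#' sampled radius chords in cyan over the grayscale image, mirroring the
#' review rendering of the original tool.
#'
#' @param image intensity matrix.
#' @param worm a worm object carrying `contour`, `path` and optionally
#'   `profile` (with chord endpoints) fields.
#' @return array `h x w x 3` with values in \[0, 1\], writable with
#'   [png::writePNG()].
#' @export
render_overlay <- function(image, worm) {
  h <- nrow(image)
  w <- ncol(image)
  base <- pmin(pmax(image, 0), 255) / 255
  out <- array(rep(base, 3), c(h, w, 3))
  paint <- function(out, rc, col) {
    rc <- round(rc)
    keep <- rc[, 1] >= 1 & rc[, 1] <= h & rc[, 2] >= 1 & rc[, 2] <= w
    rc <- rc[keep, , drop = FALSE]
    if (nrow(rc) == 0) {
      return(out)
    }
    for (k in 1:3) {
      out[cbind(rc, k)] <- col[k]
    }
    out
  }
  profile <- worm$profile
  if (!is.null(profile) && nrow(profile) > 0) {
    chords <- profile[!is.na(profile$left_r) & !is.na(profile$right_r), ,
      drop = FALSE
    ]
    for (i in seq_len(nrow(chords))) {
      p1 <- c(chords$left_r[i], chords$left_c[i])
      p2 <- c(chords$right_r[i], chords$right_c[i])
      n <- max(2, ceiling(sqrt(sum((p2 - p1)^2)) / 0.25))
      t <- seq(0, 1, length.out = n)
      pts <- cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]))
      out <- paint(out, pts, c(0, 1, 1))
    }
  }
  if (!is.null(worm$contour) && nrow(worm$contour) > 0) {
    out <- paint(out, worm$contour, c(1, 1, 0))
  }
  if (is.null(worm$path) || nrow(worm$path) == 0) {
    warning("worm has no skeleton path; overlay shows contour only")
  } else {
    pts <- worm$path
    dense <- lapply(seq_len(nrow(pts) - 1), function(i) {
      p1 <- pts[i, ]
      p2 <- pts[i + 1, ]
      n <- max(2, ceiling(sqrt(sum((p2 - p1)^2)) / 0.25))
      t <- seq(0, 1, length.out = n)
      cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]))
    })
    out <- paint(out, do.call(rbind, dense), c(0, 0, 1))
  }
  out
}
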