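#' Process one image into measured worms
#'
#' Runs the full chain on a single image: rolling-ball background
#' subtraction, Minimum thresholding, 8-connected components, area filter,
#' thinning, branch pruning (skeleton cycles auto-fail), prune-ratio
#' filter, tip extension, and measurement. Candidates are never silently
#' dropped after segmentation: each carries a status of `"measured"` or
#' `"auto-failed:<reason>"`.
#'
#' @param image intensity matrix.
#' @param config a [run_config()].
#' @param scale_um_per_px physical scale for this image.
#' @return list with `worms` (worm objects with `status`, and for measured
#'   worms `path`, `contour`, `profile`, `measurement`, `prune_ratio`),
#'   `threshold` (the `minimum_threshold()` result or NULL), and
#'   `n_candidates`.
#' @export
process_image <- function(image, config = run_config(), scale_um_per_px = 1) {
  corrected <- subtract_background(
    image, config$ball_radius_px, config$light_background
  )
  thr <- tryCatch(
    minimum_threshold(intensity_histogram(corrected)),
    error = function(e) e
  )
  if (inherits(thr, "error")) {
    return(list(
      worms = list(), threshold = NULL, n_candidates = 0L,
      skip_reason = conditionMessage(thr)
    ))
  }
  mask <- apply_threshold(corrected, thr$threshold)
  candidates <- connected_components(mask)
  n_candidates <- length(candidates)
  candidates <- area_filter(candidates, config$area_min_px2, config$area_max_px2)
  worms <- lapply(candidates, function(cand) {
    skel <- thin_mask(cand$mask)
    path <- tryCatch(prune_to_path(skel), error = function(e) e)
    if (inherits(path, "nm_skeleton_cycle")) {
      cand$status <- "auto-failed:skeleton-cycle"
      return(cand)
    }
    if (inherits(path, "error")) {
      cand$status <- paste0("auto-failed:", conditionMessage(path))
      return(cand)
    }
    if (!ratio_filter(path, config$prune_ratio_min)) {
      cand$status <- "auto-failed:prune-ratio"
      cand$prune_ratio <- path$prune_ratio
      return(cand)
    }
    if (nrow(path$points) < config$extension_window_px) {
      cand$status <- "auto-failed:path-too-short"
      return(cand)
    }
    smoothed <- smooth_path(path, config$path_smooth_window)
    extended <- extend_to_edges(smoothed, cand$mask, config$extension_window_px)
    meas <- tryCatch(
      measure_worm(cand$mask, extended,
        scale_um_per_px = scale_um_per_px,
        interval_px = config$interval_px,
        window = config$extension_window_px
      ),
      error = function(e) e
    )
    if (inherits(meas, "error")) {
      cand$status <- paste0("auto-failed:", conditionMessage(meas))
      return(cand)
    }
    cand$status <- "measured"
    cand$skeleton <- skel
    cand$path <- extended$points
    cand$prune_ratio <- path$prune_ratio
    cand$profile <- meas$profile
    cand$measurement <- meas
    cand
  })
  list(worms = worms, threshold = thr, n_candidates = n_candidates)
}

#' Run the measurement pipeline over an image directory
#'
#' Processes every supported image (TIFF/PNG/JPEG/BMP) in `image_dir` and
#' writes to `out_dir`: `measurements.csv` (one row per measured worm, all
#' flagged pass by default), `review.csv` (an editable pass/fail sidecar),
#' `manifest.json` (per-image accounting of candidates and failures plus a
#' config echo), and one review overlay PNG per measured worm under
#' `overlays/`. Reruns on identical inputs are byte-identical: the
#' measurement path contains no randomness.
#'
#' The per-image scale is resolved in this order of precedence: an
#' `image,um_per_px` data frame (or CSV path) given as `scale`, else the
#' single numeric `scale` applied to every image.
#'
#' @param image_dir directory of input images.
#' @param config a [run_config()].
#' @param scale single numeric scale (um/px), a data frame with columns
#'   `image` and `um_per_px`, or the path of such a CSV.
#' @param out_dir output directory (created).
#' @param overlays write overlay PNGs (default TRUE).
#' @return invisibly, the measurements data frame.
#' @export
run_pipeline <- function(image_dir, config = run_config(), scale = 1,
                         out_dir, overlays = TRUE) {
  files <- sort(list.files(image_dir,
    pattern = "\\.(tif|tiff|png|jpg|jpeg|bmp)$",
    ignore.case = TRUE
  ))
  if (length(files) == 0) stop("no supported images found in ", image_dir)
  if (is.character(scale) && length(scale) == 1 && file.exists(scale)) {
    scale <- utils::read.csv(scale, stringsAsFactors = FALSE)
  }
  scale_for <- function(file) {
    if (is.data.frame(scale)) {
      hit <- match(file, scale$image)
      if (is.na(hit)) stop("no scale entry for image ", file)
      scale$um_per_px[hit]
    } else {
      as.numeric(scale)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (overlays) {
    dir.create(file.path(out_dir, "overlays"), showWarnings = FALSE)
  }
  records <- list()
  manifest_images <- list()
  for (file in files) {
    img <- tryCatch(load_image(file.path(image_dir, file)),
      error = function(e) e
    )
    if (inherits(img, "error")) {
      manifest_images[[file]] <- list(
        status = "skipped:unreadable", detail = conditionMessage(img)
      )
      next
    }
    sc <- scale_for(file)
    res <- process_image(img, config, sc)
    if (!is.null(res$skip_reason)) {
      manifest_images[[file]] <- list(
        status = "skipped:no-threshold", detail = res$skip_reason
      )
      next
    }
    statuses <- vapply(res$worms, function(w) w$status, character(1))
    worm_entries <- list()
    mi <- 0L
    for (k in seq_along(res$worms)) {
      worm <- res$worms[[k]]
      worm_id <- sprintf(
        "%s_w%02d", tools::file_path_sans_ext(file), k
      )
      worm_entries[[worm_id]] <- worm$status
      if (worm$status != "measured") next
      mi <- mi + 1L
      records[[length(records) + 1L]] <- measurement_record(
        image_file = file, worm_id = worm_id, pass_flag = TRUE,
        measurement = worm$measurement, scale_um_per_px = sc,
        prune_ratio = worm$prune_ratio, config = config
      )
      if (overlays) {
        ov <- render_overlay(img, worm)
        png::writePNG(ov, file.path(
          out_dir, "overlays", paste0(worm_id, ".png")
        ))
      }
    }
    manifest_images[[file]] <- list(
      status = "processed",
      threshold = res$threshold$threshold,
      candidates = res$n_candidates,
      kept_after_area_filter = length(res$worms),
      measured = sum(statuses == "measured"),
      worms = worm_entries
    )
  }
  measurements <- if (length(records) > 0) {
    do.call(rbind, records)
  } else {
    data.frame()
  }
  manifest <- list(
    software = paste0(
      "nemameter ",
      as.character(utils::packageVersion("nemameter"))
    ),
    config = unclass(config),
    images = manifest_images
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  if (nrow(measurements) > 0) {
    write_measurements(measurements, file.path(out_dir, "measurements.csv"))
    utils::write.csv(
      data.frame(
        image = measurements$image_file,
        worm_id = measurements$worm_id,
        pass = TRUE
      ),
      file.path(out_dir, "review.csv"),
      row.names = FALSE
    )
  } else {
    stop("pipeline produced no measured worms")
  }
  invisible(measurements)
}

#' Apply a manual pass/fail review to a measurements table
#'
#' The review sidecar (`review.csv`: columns `image`, `worm_id`, `pass`)
#' replaces the interactive review window: users edit the `pass` column and
#' the final table keeps only passed worms.
#'
#' @param measurements measurements data frame or CSV path.
#' @param review review data frame or CSV path.
#' @return filtered measurements data frame with `pass_flag` updated.
#' @export
apply_review <- function(measurements, review) {
  if (is.character(measurements)) measurements <- read_measurements(measurements)
  if (is.character(review)) review <- utils::read.csv(review)
  unknown <- setdiff(review$worm_id, measurements$worm_id)
  if (length(unknown) > 0) {
    stop(
      "review references unknown worm ids: ",
      paste(unknown, collapse = ", ")
    )
  }
  pass <- as.logical(review$pass[match(measurements$worm_id, review$worm_id)])
  pass[is.na(pass)] <- TRUE
  measurements$pass_flag <- pass
  measurements[pass, , drop = FALSE]
}

#' Population size and shape statistics from grouped measurements
#'
#' Reproduces the two statistical summaries of the study design from a
#' measurements table annotated with `strain`, `time` and `replicate`
#' columns. `size_comparison_table()` tests length, middle width and
#' volume of each strain/time cell against the control strain at the same
#' time with the balanced subsampled Bonferroni t-test, and reports volume
#' skewness and excess kurtosis per cell. `shape_comparison_table()` fits
#' each strain's width-on-length regression (all times pooled) and tests
#' its slope against the control's with [compare_slopes()], Bonferroni
#' corrected.
#'
#' @param df measurements data frame with columns `strain`, `time`,
#'   `length_um`, `mid_width_um`, `volume_pl` (and `replicate`, carried but
#'   pooled: balancing is on total counts).
#' @param control name of the control strain.
#' @param n_iter subsampling iterations per test.
#' @param seed RNG seed for the subsampling.
#' @return a data frame (one row per strain/time or per strain).
#' @export
size_comparison_table <- function(df, control, n_iter = 1000L, seed = 1L) {
  cells <- unique(df[, c("strain", "time")])
  cells <- cells[order(cells$strain, cells$time), ]
  test_cells <- cells[cells$strain != control, ]
  n_comp <- 3L * nrow(test_cells)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    strain <- cells$strain[i]
    time <- cells$time[i]
    sub <- df[df$strain == strain & df$time == time, ]
    ctl <- df[df$strain == control & df$time == time, ]
    out <- data.frame(
      strain = strain, time = time,
      length_p = NA_real_, width_p = NA_real_, volume_p = NA_real_,
      volume_skewness = sample_skewness(sub$volume_pl),
      volume_kurtosis = excess_kurtosis(sub$volume_pl)
    )
    if (strain != control && nrow(ctl) >= 2 && nrow(sub) >= 2) {
      ps <- vapply(
        c("length_um", "mid_width_um", "volume_pl"),
        function(col) {
          balanced_subsample_ttest(ctl[[col]], sub[[col]],
            n_iter = n_iter, n_comparisons = n_comp,
            seed = seed + i
          )$p_adjusted
        },
        numeric(1)
      )
      out$length_p <- ps[1]
      out$width_p <- ps[2]
      out$volume_p <- ps[3]
    }
    out
  })
  do.call(rbind, rows)
}

#' @rdname size_comparison_table
#' @export
shape_comparison_table <- function(df, control) {
  strains <- setdiff(unique(df$strain), control)
  ctl <- df[df$strain == control, ]
  n_comp <- length(strains)
  ctl_fit <- stats::lm(mid_width_um ~ length_um, data = ctl)
  rows <- lapply(strains, function(strain) {
    sub <- df[df$strain == strain, ]
    cmp <- compare_slopes(
      sub$length_um, sub$mid_width_um,
      ctl$length_um, ctl$mid_width_um
    )
    data.frame(
      strain = strain,
      slope = cmp$b1,
      p = min(1, cmp$p * n_comp)
    )
  })
  rbind(
    do.call(rbind, rows),
    data.frame(
      strain = control,
      slope = unname(stats::coef(ctl_fit)[2]),
      p = NA_real_
    )
  )
}
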