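# Image I/O, pipeline configuration, end-to-end driver and segmentation
# evaluation utilities.

#' Pipeline configuration
#'
#' All parameters of the detection and measurement pipeline with their
#' default values. The wavelet levels to sum are the only parameter that
#' normally needs adjusting between image resolutions; everything else is
#' defined relative to the FOV or to the estimated vessel width and can
#' usually be left alone.
#'
#' @param wavelet_levels Wavelet levels summed before thresholding
#'   (default `c(2, 3)`, suited to ~565-px fundus images).
#' @param threshold_percent Percentage of FOV coefficients marked as
#'   vessel (default 20).
#' @param polarity `"dark"` for fundus photographs, `"bright"` for
#'   fluorescein angiograms.
#' @param min_object_area,max_hole_area Pixel areas, or strings such as
#'   `"0.05%"` interpreted as a fraction of the FOV pixel count
#'   (defaults `"0.05%"` each).
#' @param fov_threshold,fov_erosion_radius FOV computation parameters
#'   (defaults 20 and 1); see [fov_mask()].
#' @param spur_length Centreline spur and short-segment removal length in
#'   pixels (default 10).
#' @param break_spacing Spline piece spacing in centreline pixels
#'   (default 10).
#' @param profile_spacing Arc-length spacing of profiles in pixels
#'   (default 1).
#' @param parallel_scale,perpendicular_scale Anisotropic smoothing scale
#'   factors (defaults 2 and 0.1); sigmas are these times the square
#'   root of the estimated width.
#' @param channel Channel of a colour image used for analysis
#'   (default `"green"`, which has the best vessel contrast).
#' @return Named list of class `vessel_config`.
#' @export
vessel_config <- function(wavelet_levels = c(2, 3),
                          threshold_percent = 20,
                          polarity = c("dark", "bright"),
                          min_object_area = "0.05%",
                          max_hole_area = "0.05%",
                          fov_threshold = 20,
                          fov_erosion_radius = 1,
                          spur_length = 10,
                          break_spacing = 10,
                          profile_spacing = 1,
                          parallel_scale = 2,
                          perpendicular_scale = 0.1,
                          channel = c("green", "red", "gray", "luminance")) {
  polarity <- match.arg(polarity)
  channel <- match.arg(channel)
  stopifnot(threshold_percent > 0, threshold_percent <= 100,
            spur_length >= 0, break_spacing > 0, profile_spacing > 0,
            parallel_scale > 0, perpendicular_scale > 0)
  structure(
    list(wavelet_levels = as.integer(wavelet_levels),
         threshold_percent = threshold_percent, polarity = polarity,
         min_object_area = min_object_area, max_hole_area = max_hole_area,
         fov_threshold = fov_threshold,
         fov_erosion_radius = fov_erosion_radius,
         spur_length = spur_length, break_spacing = break_spacing,
         profile_spacing = profile_spacing,
         parallel_scale = parallel_scale,
         perpendicular_scale = perpendicular_scale,
         channel = channel),
    class = c("vessel_config", "list")
  )
}

#' Read a configuration from a YAML file
#'
#' Fields present in the file override [vessel_config()] defaults;
#' unknown fields are an error.
#'
#' @param path Path to a YAML file.
#' @return A `vessel_config` list.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(vessel_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(vessel_config, vals)
}

#' Load an image as a grayscale intensity matrix
#'
#' Reads PNG, TIFF or JPEG. Colour images are reduced per `channel`
#' (default green, the channel with best vessel contrast in fundus
#' photographs); the red channel is returned alongside for FOV
#' computation. TIFF integer data are preserved without rescaling
#' (16-bit values stay 16-bit); PNG and JPEG readers normalise to
#' \[0, 1\], so values are scaled to the conventional 0--255 range.
#'
#' @param path Image path.
#' @param channel `"green"`, `"red"`, `"gray"` (error if not grayscale)
#'   or `"luminance"` (Rec. 601 weights).
#' @return List with `image` (numeric matrix, rows x cols) and `red`
#'   (red-channel matrix, or the image itself for grayscale input).
#' @export
load_image <- function(path, channel = c("green", "red", "gray", "luminance")) {
  channel <- match.arg(channel)
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path) * 255,
    tif = ,
    tiff = tiff::readTIFF(path, as.is = TRUE),
    jpg = ,
    jpeg = {
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img) * 255
      if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
    },
    stop("unsupported image format: ", ext, call. = FALSE)
  )
  arr <- arr * 1.0
  if (length(dim(arr)) == 2L) {
    return(list(image = arr, red = arr))
  }
  red <- arr[, , 1]
  img <- switch(channel,
    red = red,
    green = arr[, , 2],
    gray = stop("image is not grayscale; choose a channel", call. = FALSE),
    luminance = 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
  )
  list(image = img, red = red)
}

#' Evaluate a segmentation against a reference mask
#'
#' Confusion counts restricted to the evaluation FOV. The true positive
#' rate is the proportion of reference vessel pixels detected, the false
#' positive rate the proportion of reference background pixels marked as
#' vessel, and the accuracy the fraction of correctly assigned pixels
#' (vessel or non-vessel) among all FOV pixels.
#'
#' @param pred,truth,fov Logical matrices of equal shape.
#' @return List with `tp`, `fp`, `tn`, `fn`, `tpr`, `fpr`, `accuracy`.
#' @export
evaluate_segmentation <- function(pred, truth, fov) {
  stopifnot(all(dim(pred) == dim(truth)), all(dim(pred) == dim(fov)))
  if (!any(fov)) stop("empty evaluation FOV", call. = FALSE)
  p <- pred[fov]; t <- truth[fov]
  tp <- sum(p & t); fp <- sum(p & !t)
  fn <- sum(!p & t); tn <- sum(!p & !t)
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       tpr = tp / (tp + fn), fpr = fp / (fp + tn),
       accuracy = (tp + tn) / (tp + fp + tn + fn))
}

#' Detect and measure all vessels in an image
#'
#' The in-memory end-to-end pipeline: segmentation, centreline
#' extraction, and per-segment calibre measurement with profiles at
#' least twice the largest diameter estimate. Deterministic for a given
#' image and configuration.
#'
#' @param image Numeric matrix (the analysis channel).
#' @param config A [vessel_config()].
#' @param fov Optional FOV mask; computed from `image` when missing
#'   (pass one computed from the red channel for colour images).
#' @param red Optional red-channel matrix used for FOV computation.
#' @return List with `fov`, `segmentation`, `chains` and `measurements`
#'   (a data frame with a `segment_id` column followed by the per-profile
#'   fields of [link_zero_crossings()]).
#' @export
measure_image <- function(image, config = vessel_config(), fov = NULL,
                          red = NULL) {
  stopifnot_image(image)
  if (is.null(fov)) {
    src <- if (is.null(red)) image else red
    fov <- fov_mask(src, config$fov_threshold, config$fov_erosion_radius)
  }
  seg <- segment_vessels(image, config, fov)
  chains <- extract_centrelines(seg, config$spur_length)
  meas <- list()
  if (length(chains)) {
    max_d <- max(vapply(chains, `[[`, numeric(1), "diameter_estimate"))
    plen <- max(2 * max_d, 7)
    for (i in seq_along(chains)) {
      m <- measure_segment(image, seg, fov, chains[[i]], config, plen)
      if (nrow(m)) m <- cbind(segment_id = i, m)
      meas[[i]] <- m
    }
  }
  meas <- if (length(meas)) do.call(rbind, meas[vapply(meas, nrow, 1L) > 0])
          else NULL
  if (is.null(meas)) {
    meas <- data.frame(
      segment_id = integer(0), profile_index = integer(0),
      centre_row = numeric(0), centre_col = numeric(0),
      left_row = numeric(0), left_col = numeric(0),
      right_row = numeric(0), right_col = numeric(0),
      diameter = numeric(0), valid = logical(0)
    )
  }
  list(fov = fov, segmentation = seg, chains = chains, measurements = meas)
}

#' Run the pipeline on an image file and write results
#'
#' Loads the image, computes the FOV from the red channel, runs
#' [measure_image()] and writes: the segmentation mask
#' (`segmentation.png`, 8-bit 0/255), the centreline table
#' (`centrelines.csv`: segment_id, point_index, row, col), the
#' measurement table (`measurements.csv`) and a JSON run report
#' (`report.json` with the parameters, counts and any warnings).
#'
#' @param image_path Input image.
#' @param config A [vessel_config()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the [measure_image()] result.
#' @export
run_pipeline <- function(image_path, config = vessel_config(),
                         out_dir = ".") {
  loaded <- load_image(image_path, config$channel)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  warnings_seen <- character(0)
  res <- withCallingHandlers(
    {
      fov <- fov_mask(loaded$red, config$fov_threshold,
                      config$fov_erosion_radius)
      measure_image(loaded$image, config, fov)
    },
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  png::writePNG(res$segmentation * 1.0,
                file.path(out_dir, "segmentation.png"))
  cl <- do.call(rbind, lapply(seq_along(res$chains), function(i) {
    pts <- res$chains[[i]]$points
    data.frame(segment_id = i, point_index = seq_len(nrow(pts)),
               row = pts[, 1], col = pts[, 2])
  }))
  if (is.null(cl)) {
    cl <- data.frame(segment_id = integer(0), point_index = integer(0),
                     row = integer(0), col = integer(0))
  }
  utils::write.csv(cl, file.path(out_dir, "centrelines.csv"),
                   row.names = FALSE)
  utils::write.csv(res$measurements, file.path(out_dir, "measurements.csv"),
                   row.names = FALSE)
  report <- list(
    input = image_path,
    parameters = unclass(config),
    n_segments = length(res$chains),
    n_profiles = nrow(res$measurements),
    n_valid = sum(res$measurements$valid),
    warnings = warnings_seen
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
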