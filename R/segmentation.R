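#' Compute a field-of-view mask by global thresholding
#'
#' Fundus photographs show the retina inside a roughly circular field of
#' view (FOV) surrounded by dark pixels. A usable FOV mask is obtained by
#' thresholding the image (best applied to the red channel of a colour
#' photograph, which is bright across the whole retina) and eroding the
#' result to pull the boundary safely inside the true FOV. If several
#' foreground components survive, only the largest is kept.
#'
#' @param image Numeric matrix; the red channel when available.
#' @param threshold Intensity; pixels strictly above it are foreground.
#'   Default 20 (on the 0--255 scale).
#' @param erosion_radius Radius of the square structuring element (side
#'   `2 * erosion_radius + 1`). Default 1.
#' @return Logical matrix.
#' @export
fov_mask <- function(image, threshold = 20, erosion_radius = 1) {
  stopifnot_image(image)
  m <- image > threshold
  if (!any(m)) stop("no FOV found: no pixel above threshold", call. = FALSE)
  if (erosion_radius > 0) {
    # pad with background so the image border is eroded too
    r <- as.integer(erosion_radius)
    pad <- matrix(0, nrow(m) + 2L * r, ncol(m) + 2L * r)
    pad[r + seq_len(nrow(m)), r + seq_len(ncol(m))] <- m
    brush <- EBImage::makeBrush(2L * r + 1L, shape = "box")
    er <- EBImage::erode(pad, brush) > 0.5
    m <- er[r + seq_len(nrow(m)), r + seq_len(ncol(m))]
  }
  if (!any(m)) stop("no FOV found: mask empty after erosion", call. = FALSE)
  lab <- label_components8(m)
  if (max(lab) > 1L) {
    areas <- tabulate(lab[lab > 0L])
    m <- lab == which.max(areas)
  }
  m
}

#' Threshold wavelet coefficients by percentile inside the FOV
#'
#' Marks the `percent`\% lowest-valued coefficients inside the field of
#' view (`polarity = "dark"`, for fundus images where vessels are dark) or
#' the `percent`\% highest (`polarity = "bright"`, for fluorescein
#' angiograms). The threshold value is the k-th smallest (or largest) FOV
#' coefficient with `k = round(percent/100 * n_fov)`; all pixels equal to
#' the threshold value are included, so ties may push the selected count
#' slightly above `k` (a deterministic convention). Pixels outside the FOV
#' are never selected.
#'
#' @param coeff_sum Numeric matrix, typically an [iuwt_sum_levels()] result.
#' @param fov Logical matrix, the field of view.
#' @param percent Percentage in (0, 100].
#' @param polarity `"dark"` or `"bright"`.
#' @return Logical matrix.
#' @export
percentile_threshold <- function(coeff_sum, fov, percent,
                                 polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  stopifnot(is.matrix(coeff_sum), is.logical(fov),
            all(dim(coeff_sum) == dim(fov)))
  if (length(percent) != 1L || !is.finite(percent) || percent <= 0 ||
      percent > 100) {
    stop("`percent` must lie in (0, 100]", call. = FALSE)
  }
  vals <- coeff_sum[fov]
  if (length(vals) == 0L) stop("FOV is empty", call. = FALSE)
  if (min(vals) == max(vals)) {
    warning("constant coefficient image inside FOV", call. = FALSE)
  }
  k <- round(percent / 100 * length(vals))
  out <- matrix(FALSE, nrow(coeff_sum), ncol(coeff_sum))
  if (k < 1L) return(out)
  if (polarity == "dark") {
    s <- sort(vals, partial = k)[k]
    out[fov] <- vals <= s
  } else {
    s <- -sort(-vals, partial = k)[k]
    out[fov] <- vals >= s
  }
  out
}

#' Remove small objects and fill small holes in a binary mask
#'
#' Percentile thresholding oversegments: misclassified background pixels
#' tend to cluster into small isolated objects while the vasculature forms
#' one large connected structure. Objects (8-connected foreground
#' components) with area strictly below `min_object_area` are removed,
#' then holes (4-connected background components not touching the image
#' border) with area strictly below `max_hole_area` are filled.
#'
#' @param mask Logical matrix.
#' @param min_object_area,max_hole_area Areas in pixels; 0 disables the
#'   corresponding clean-up.
#' @return Logical matrix.
#' @export
clean_binary <- function(mask, min_object_area = 0, max_hole_area = 0) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (min_object_area > 0 && any(mask)) {
    lab <- label_components8(mask)
    areas <- tabulate(lab[lab > 0L])
    drop <- which(areas < min_object_area)
    if (length(drop)) mask <- mask & !(lab %in% drop)
    mask <- matrix(mask, nrow = nrow(lab))
  }
  if (max_hole_area > 0 && any(!mask)) {
    bg <- EBImage::bwlabel(!mask)  # 4-connected background components
    border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    border <- border[border > 0]
    areas <- tabulate(bg[bg > 0L])
    fill <- setdiff(which(areas < max_hole_area), border)
    if (length(fill)) mask <- mask | matrix(bg %in% fill, nrow = nrow(bg))
  }
  mask
}

# Resolve an area given either as pixels (numeric) or as a percentage of
# the FOV pixel count (string such as "0.05%").
resolve_area <- function(area, fov_pixels) {
  if (is.character(area)) {
    if (!grepl("%$", area)) stop("character areas must end in '%'", call. = FALSE)
    as.numeric(sub("%$", "", area)) / 100 * fov_pixels
  } else {
    as.numeric(area)
  }
}

#' Segment vessels by thresholding a sum of wavelet levels
#'
#' The full segmentation stage: IUWT decomposition, summation of the
#' chosen wavelet levels, percentile thresholding inside the FOV, and
#' binary clean-up (small-object removal and hole filling). Area
#' parameters given as percentages (e.g. `"0.05%"`) are resolved against
#' the FOV pixel count.
#'
#' @param image Numeric matrix (typically the green channel of a fundus
#'   photograph).
#' @param config A [vessel_config()] list; the fields used here are
#'   `wavelet_levels`, `threshold_percent`, `polarity`,
#'   `min_object_area`, `max_hole_area`, `fov_threshold` and
#'   `fov_erosion_radius`.
#' @param fov Optional logical FOV mask; computed with [fov_mask()] from
#'   `image` when missing. (For colour images, prefer computing the FOV
#'   from the red channel and passing it in.)
#' @return Logical vessel mask (always a subset of the FOV).
#' @export
segment_vessels <- function(image, config = vessel_config(), fov = NULL) {
  stopifnot_image(image)
  if (is.null(fov)) {
    fov <- fov_mask(image, config$fov_threshold, config$fov_erosion_radius)
  }
  d <- iuwt_decompose(image, max(config$wavelet_levels))
  cs <- iuwt_sum_levels(d, config$wavelet_levels)
  m <- percentile_threshold(cs, fov, config$threshold_percent, config$polarity)
  clean_binary(
    m,
    resolve_area(config$min_object_area, sum(fov)),
    resolve_area(config$max_hole_area, sum(fov))
  )
}
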