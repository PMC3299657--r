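# Centreline refinement and profile extraction.  Discrete pixel chains are
# unsuited to computing vessel orientations, so a least-squares parametric
# cubic spline is fitted to each chain; perpendicular intensity profiles
# sampled along the spline form the "straightened" vessel image that the
# edge-detection stage works on.

#' Centripetal parameterisation of an ordered point sequence
#'
#' Parameter values for parametric curve fitting: `t[1] = 0` and
#' `t[i+1] = t[i] + sqrt(|p[i+1] - p[i]|)` (square root of the chord
#' length, Lee's centripetal scheme). Compared with chord-length
#' parameterisation this reduces overshooting near tight corners.
#' Duplicate consecutive points are collapsed before computing.
#'
#' @param points n x 2 matrix of (row, col) coordinates, n >= 2.
#' @return List with `t` (strictly increasing parameters) and `points`
#'   (the deduplicated coordinates).
#' @export
centripetal_parameters <- function(points) {
  stopifnot(is.matrix(points), ncol(points) == 2)
  if (nrow(points) < 2L) {
    stop("need at least 2 distinct points", call. = FALSE)
  }
  dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
  points <- points[!dup, , drop = FALSE]
  if (nrow(points) < 2L) {
    stop("need at least 2 distinct points", call. = FALSE)
  }
  seg <- sqrt(rowSums(diff(points)^2))
  list(t = c(0, cumsum(sqrt(seg))), points = points)
}

#' Fit a least-squares parametric cubic spline to a centreline
#'
#' Each coordinate (row and column) is fitted as a piecewise cubic
#' polynomial of the centripetal parameter by linear least squares in a
#' B-spline basis. The segment is divided into
#' `max(1, floor(n / break_spacing))` pieces spanning equal parameter
#' intervals, so breaks fall roughly every `break_spacing` centreline
#' pixels; the piece count trades smoothness against the ability to
#' follow tortuous vessels. When the chain is too short to constrain a
#' piecewise fit, a single cubic is used instead (and a lower-order
#' polynomial below 4 points).
#'
#' @param chain A `centreline_chain` or an n x 2 coordinate matrix.
#' @param break_spacing Approximate number of centreline pixels per
#'   polynomial piece (default 10).
#' @return Object of class `centre_spline` with fields `knots`,
#'   `coef` (matrix, one column per coordinate), `ord`, `range` and
#'   `n_points`.
#' @export
fit_centreline_spline <- function(chain, break_spacing = 10) {
  points <- if (inherits(chain, "centreline_chain")) chain$points else chain
  cp <- centripetal_parameters(points)
  t <- cp$t
  pts <- cp$points
  n <- nrow(pts)
  pieces <- max(1L, floor(n / break_spacing))
  ord <- 4L
  ncoef <- pieces + ord - 1L
  if (n < ncoef) {
    pieces <- 1L
    ncoef <- ord
  }
  if (n < ord) {
    ord <- n
    ncoef <- ord
  }
  brk <- seq(t[1], t[n], length.out = pieces + 1L)
  knots <- c(rep(t[1], ord), brk[-c(1L, length(brk))], rep(t[n], ord))
  B <- splines::splineDesign(knots, t, ord = ord)
  fit <- qr(B)
  coef <- cbind(qr.coef(fit, pts[, 1]), qr.coef(fit, pts[, 2]))
  structure(
    list(knots = knots, coef = coef, ord = ord, range = c(t[1], t[n]),
         n_points = n),
    class = "centre_spline"
  )
}

#' Evaluate a centreline spline (or its derivative)
#'
#' @param spline A [fit_centreline_spline()] result.
#' @param t Parameter values within the spline's range.
#' @param deriv Derivative order (0 = position).
#' @return length(t) x 2 matrix of (row, col) values.
#' @export
eval_spline <- function(spline, t, deriv = 0) {
  t <- pmin(pmax(t, spline$range[1]), spline$range[2])
  B <- splines::splineDesign(spline$knots, t, ord = spline$ord,
                             derivs = rep(deriv, length(t)))
  B %*% spline$coef
}

#' Sample a spline at regular arc-length intervals
#'
#' Positions, unit tangents and unit normals at approximately
#' `spacing`-pixel arc-length increments. Arc length has no closed form
#' for cubics, so it is approximated by dense parameter sampling (10x the
#' chain resolution) and cumulative chord length. Normals are the
#' tangents rotated by +90 degrees, with signs fixed so the same side of
#' the vessel stays on the same side of every profile.
#'
#' @param spline A [fit_centreline_spline()] result.
#' @param spacing Arc-length step in pixels (default 1).
#' @return List with matrices `position`, `tangent`, `normal` (k x 2) and
#'   vector `arc` of arc-length stations.
#' @export
sample_centreline <- function(spline, spacing = 1) {
  stopifnot(spacing > 0)
  m <- max(50L, 10L * spline$n_points)
  tt <- seq(spline$range[1], spline$range[2], length.out = m)
  pos <- eval_spline(spline, tt)
  seg <- sqrt(rowSums(diff(pos)^2))
  arc <- c(0, cumsum(seg))
  total <- arc[m]
  stations <- seq(0, total, by = spacing)
  ts <- stats::approx(arc, tt, xout = stations, ties = "ordered")$y
  p <- eval_spline(spline, ts)
  d <- eval_spline(spline, ts, deriv = 1)
  len <- sqrt(rowSums(d^2))
  ok <- len >= 1e-12
  if (!all(ok)) {
    warning("skipping sample(s) with degenerate tangent", call. = FALSE)
    p <- p[ok, , drop = FALSE]
    d <- d[ok, , drop = FALSE]
    len <- len[ok]
    stations <- stations[ok]
  }
  tan <- d / len
  nrm <- cbind(-tan[, 2], tan[, 1])
  if (nrow(nrm) > 1L) {
    for (i in 2:nrow(nrm)) {
      if (sum(nrm[i, ] * nrm[i - 1L, ]) < 0) nrm[i, ] <- -nrm[i, ]
    }
  }
  list(position = p, tangent = tan, normal = nrm, arc = stations)
}

#' Extract perpendicular profiles into a straightened vessel stack
#'
#' For every centreline sample, `profile_length` points at 1-px spacing
#' are taken along the normal direction, centred on the centreline.
#' Intensities come from bilinear interpolation of the grayscale image;
#' two aligned binary stacks come from nearest-neighbour sampling of the
#' segmentation: `own_vessel` holds the run of vessel pixels connected
#' (along each profile) to the centre column, i.e. the vessel under
#' measurement, while `excluded` holds pixels of other vessels, pixels
#' outside the FOV and samples falling outside the image — regions where
#' vessel edges must not be reported.
#'
#' @param image Numeric matrix, the raw grayscale image.
#' @param seg_mask Logical matrix, the initial segmentation.
#' @param fov Logical matrix, the field of view.
#' @param samples A [sample_centreline()] result.
#' @param profile_length Profile length in pixels; must be at least twice
#'   the largest diameter estimate so profiles stretch beyond even the
#'   widest vessels and leave room for filtering. Rounded up to odd.
#' @return Object of class `profile_stack`: list with matrices
#'   `intensities`, `own_vessel`, `excluded`, `row_coords`, `col_coords`
#'   (all P x L), `centre_index` and the `samples` used.
#' @export
extract_profiles <- function(image, seg_mask, fov, samples, profile_length) {
  stopifnot_image(image)
  P <- nrow(samples$position)
  L <- 2L * floor(profile_length / 2) + 1L
  if (L < profile_length) L <- L + 2L
  centre <- (L + 1L) %/% 2L
  off <- seq_len(L) - centre
  r <- samples$position[, 1] + outer(samples$normal[, 1], off)
  c <- samples$position[, 2] + outer(samples$normal[, 2], off)
  inten <- matrix(bilinear(image, as.vector(r), as.vector(c)), P, L)
  seg_nn <- matrix(nearest_lookup(seg_mask, as.vector(r), as.vector(c)), P, L)
  fov_nn <- matrix(nearest_lookup(fov, as.vector(r), as.vector(c)), P, L)
  invalid <- is.na(seg_nn) | !is.finite(inten)
  vessel <- !is.na(seg_nn) & seg_nn
  own <- matrix(FALSE, P, L)
  for (i in seq_len(P)) {
    v <- vessel[i, ]
    if (!v[centre]) next
    lo <- centre
    while (lo > 1L && v[lo - 1L]) lo <- lo - 1L
    hi <- centre
    while (hi < L && v[hi + 1L]) hi <- hi + 1L
    own[i, lo:hi] <- TRUE
  }
  excluded <- (vessel & !own) | invalid |
    (!is.na(fov_nn) & !fov_nn)
  structure(
    list(intensities = inten, own_vessel = own, excluded = excluded,
         row_coords = r, col_coords = c, centre_index = centre,
         samples = samples),
    class = "profile_stack"
  )
}

#' @export
print.profile_stack <- function(x, ...) {
  cat(sprintf(
    "Profile stack: %d profiles x %d samples (centre column %d)\n",
    nrow(x$intensities), ncol(x$intensities), x$centre_index
  ))
  invisible(x)
}
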