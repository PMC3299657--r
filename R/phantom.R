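# Synthetic vessel phantoms with exact ground truth.  The generator
# emulates the image structure the measurement algorithm assumes: dark
# (or bright) vessels with approximately Gaussian or blurred-rectangle
# cross-sections on a smooth background, optionally carrying a central
# light reflex (a narrow bright ridge along the vessel middle) and
# additive Gaussian noise.  Line and circular-arc centrelines admit exact
# point-to-curve distances, so the rendered intensities are analytic.

#' Describe one phantom vessel
#'
#' @param kind Centreline shape: `"line"` (from `p0` to `p1`),
#'   `"arc"` (circle `centre`/`radius` between angles `theta`), or
#'   `"points"` (polyline through `control` points).
#' @param profile Cross-section: `"gaussian"` (scale `sigma`; expected
#'   measured diameter `2 * sigma` in the noise-free limit, the distance
#'   between the inflection points) or `"rect"` (top-hat of width
#'   `width`, optionally blurred by a Gaussian PSF of scale `blur`, which
#'   leaves the edge positions unchanged).
#' @param amplitude Contrast amplitude in intensity units (> 0).
#' @param sign -1 for dark vessels (fundus), +1 for bright (angiogram).
#' @param sigma,width,blur Cross-section parameters in pixels.
#' @param p0,p1,centre,radius,theta,control Centreline geometry.
#' @param reflex Optional central light reflex:
#'   `list(amplitude =, sigma =)`, a Gaussian ridge of the opposite
#'   contrast added along the centreline.
#' @return A `phantom_vessel` list.
#' @export
phantom_vessel <- function(kind = c("line", "arc", "points"),
                           profile = c("gaussian", "rect"),
                           amplitude = 100, sign = -1,
                           sigma = 4, width = 9, blur = 0,
                           p0 = NULL, p1 = NULL,
                           centre = NULL, radius = NULL, theta = NULL,
                           control = NULL, reflex = NULL) {
  kind <- match.arg(kind)
  profile <- match.arg(profile)
  stopifnot(amplitude > 0, sign %in% c(-1, 1))
  if (profile == "gaussian") stopifnot(sigma > 0) else stopifnot(width > 0)
  if (!is.null(reflex)) {
    stopifnot(reflex$amplitude > 0, reflex$sigma > 0)
    half <- if (profile == "gaussian") sigma else width / 2
    if (2 * reflex$sigma >= 2 * half) {
      stop("reflex must be narrower than the vessel", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, profile = profile, amplitude = amplitude, sign = sign,
         sigma = sigma, width = width, blur = blur, p0 = p0, p1 = p1,
         centre = centre, radius = radius, theta = theta, control = control,
         reflex = reflex),
    class = "phantom_vessel"
  )
}

#' Describe a phantom image
#'
#' @param size Image size, `c(rows, cols)` or a single integer.
#' @param background Flat background level (default 200, a typical bright
#'   fundus background on the 0--255 scale).
#' @param gradient Amplitude of a smooth radial background bowl (0
#'   disables it); emulates the inhomogeneous illumination of real
#'   fundus images.
#' @param vessels List of [phantom_vessel()] descriptions.
#' @param noise_sd Standard deviation of additive white Gaussian noise.
#' @param seed RNG seed; rendering is byte-identical for a fixed seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = 256, background = 200, gradient = 0,
                         vessels = list(), noise_sd = 0, seed = 1L) {
  if (length(size) == 1L) size <- c(size, size)
  stopifnot(all(size >= 8), noise_sd >= 0)
  structure(
    list(size = as.integer(size), background = background,
         gradient = gradient, vessels = vessels, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# Unsigned distance from pixel grid points to a vessel centreline, plus
# the dense true centreline coordinates used as ground truth.
vessel_distance <- function(v, rows, cols) {
  R <- outer(rows, rep(1, length(cols)))
  C <- outer(rep(1, length(rows)), cols)
  if (v$kind == "line") {
    d0 <- v$p1 - v$p0
    len2 <- sum(d0^2)
    t <- ((R - v$p0[1]) * d0[1] + (C - v$p0[2]) * d0[2]) / len2
    t <- pmin(pmax(t, 0), 1)
    dist <- sqrt((R - (v$p0[1] + t * d0[1]))^2 + (C - (v$p0[2] + t * d0[2]))^2)
    # the reported true centreline extends through the rounded end caps,
    # to the limit of the rendered intensity support
    ext <- (truth_half_width(v) + 3 * v$blur) / sqrt(len2)
    n <- max(2L, ceiling(4 * sqrt(len2)))  # 0.25-px ground-truth sampling
    tt <- seq(-ext, 1 + ext, length.out = n)
    centreline <- cbind(v$p0[1] + tt * d0[1], v$p0[2] + tt * d0[2])
  } else if (v$kind == "arc") {
    dr <- R - v$centre[1]
    dc <- C - v$centre[2]
    rad <- sqrt(dr^2 + dc^2)
    t0 <- v$theta[1]; t1 <- v$theta[2]
    full <- (t1 - t0) >= 2 * pi - 1e-9  # closed circle
    span <- if (full) 2 * pi else (t1 - t0) %% (2 * pi)
    if (full) {
      dist <- abs(rad - v$radius)
    } else {
      ang <- atan2(dc, dr)
      inside <- ((ang - t0) %% (2 * pi)) <= span
      d_in <- abs(rad - v$radius)
      e0 <- v$centre + v$radius * c(cos(t0), sin(t0))
      e1 <- v$centre + v$radius * c(cos(t1), sin(t1))
      d_ends <- pmin(sqrt((R - e0[1])^2 + (C - e0[2])^2),
                     sqrt((R - e1[1])^2 + (C - e1[2])^2))
      dist <- ifelse(inside, d_in, d_ends)
    }
    n <- max(2L, ceiling(4 * span * v$radius))
    tt <- t0 + seq(0, span, length.out = n)
    centreline <- cbind(v$centre[1] + v$radius * cos(tt),
                        v$centre[2] + v$radius * sin(tt))
  } else {
    ctrl <- v$control
    # densify to ~1 px and take min distance over segments
    dist <- matrix(Inf, length(rows), length(cols))
    centreline <- NULL
    for (i in seq_len(nrow(ctrl) - 1L)) {
      p0 <- ctrl[i, ]; p1 <- ctrl[i + 1L, ]
      d0 <- p1 - p0
      len2 <- sum(d0^2)
      t <- ((R - p0[1]) * d0[1] + (C - p0[2]) * d0[2]) / max(len2, 1e-12)
      t <- pmin(pmax(t, 0), 1)
      di <- sqrt((R - (p0[1] + t * d0[1]))^2 + (C - (p0[2] + t * d0[2]))^2)
      dist <- pmin(dist, di)
      n <- max(2L, ceiling(sqrt(len2) * 10))
      tt <- seq(0, 1, length.out = n)
      centreline <- rbind(centreline,
                          cbind(p0[1] + tt * d0[1], p0[2] + tt * d0[2]))
    }
  }
  list(dist = dist, centreline = centreline)
}

# Cross-section profile value at unsigned distance d from the centreline.
profile_value <- function(v, d) {
  if (v$profile == "gaussian") {
    exp(-d^2 / (2 * v$sigma^2))
  } else if (v$blur > 0) {
    # box of width w convolved with a Gaussian PSF: analytic via pnorm
    pnorm((v$width / 2 - d) / v$blur) - pnorm((-v$width / 2 - d) / v$blur)
  } else {
    as.numeric(d <= v$width / 2)
  }
}

# Half-width used for the ground-truth mask: sigma for a Gaussian section
# (edges at the inflection points), width/2 for a rectangle.
truth_half_width <- function(v) {
  if (v$profile == "gaussian") v$sigma else v$width / 2
}

#' Render a phantom image with ground truth
#'
#' Pixel intensities are `background + gradient bowl + sum of vessel
#' contributions + reflex ridges + noise`, where each vessel contributes
#' `sign * amplitude * profile(distance to centreline)`. Rendering is
#' deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (numeric matrix) and `truth`, a list holding
#'   `mask` (pixels within the true half-width of any centreline),
#'   `centrelines` (list of dense coordinate matrices), `widths`
#'   (true full widths per vessel) and `expected_diameter` (the
#'   analytic noise-free measured diameter: `2 * sigma` for a Gaussian
#'   section, `width` for a rectangle; before perpendicular smoothing).
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  nr <- spec$size[1]; nc <- spec$size[2]
  rows <- seq_len(nr); cols <- seq_len(nc)
  img <- matrix(spec$background, nr, nc)
  if (spec$gradient != 0) {
    cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
    rad2 <- outer((rows - cr)^2, rep(1, nc)) +
      outer(rep(1, nr), (cols - cc)^2)
    img <- img - spec$gradient * rad2 / max(rad2)
  }
  mask <- matrix(FALSE, nr, nc)
  centrelines <- list()
  widths <- numeric(0)
  expected <- numeric(0)
  overlap <- matrix(0L, nr, nc)
  for (v in spec$vessels) {
    vd <- vessel_distance(v, rows, cols)
    img <- img + v$sign * v$amplitude * profile_value(v, vd$dist)
    if (!is.null(v$reflex)) {
      img <- img - v$sign * v$reflex$amplitude *
        exp(-vd$dist^2 / (2 * v$reflex$sigma^2))
    }
    vmask <- vd$dist <= truth_half_width(v)
    overlap <- overlap + (vmask & mask)
    mask <- mask | vmask
    centrelines[[length(centrelines) + 1L]] <- vd$centreline
    widths <- c(widths, 2 * truth_half_width(v))
    expected <- c(expected,
                  if (v$profile == "gaussian") 2 * v$sigma else v$width)
  }
  if (any(overlap > 0)) {
    warning(sprintf("%d pixel(s) belong to more than one vessel",
                    sum(overlap > 0)), call. = FALSE)
  }
  if (spec$noise_sd > 0) {
    img <- img + withr::with_seed(
      spec$seed, matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
    )
  }
  list(
    image = img,
    truth = list(mask = mask, centrelines = centrelines, widths = widths,
                 expected_diameter = expected)
  )
}

#' Standard phantom fixtures
#'
#' The fixed set of phantom specifications used across the test suite.
#' All are 256 x 256 images with dark vessels of amplitude 100 on a
#' bright background of 200 (0--255 scale). Vessels are drawn in small
#' parallel families tilted slightly off the pixel grid, with enough
#' vessels per image that the true vessel fraction of the field of view
#' sits in the regime reported for real fundus photographs (roughly
#' 10--15\%), which is the operating point the default 20\% coefficient
#' threshold assumes. Fixtures:
#'
#' * `gauss4` — six Gaussian-section vessels of scale 4 px.
#' * `arc_sweep` — six concentric circular-arc vessels with rectangle
#'   sections of widths 5--13 px (blur 1 px).
#' * `rect_w5` ... `rect_w13` — families of identical rectangle-section
#'   vessels (blur 1 px), one fixture per width in 5, 7, 9, 11, 13.
#' * `reflex_off` / `reflex_on` — the `gauss4` family without and with a
#'   central light reflex (ridge amplitude 40, scale 0.8 px) added to
#'   every vessel; the pair differs only in the ridge term.
#' * `parallel_pair` — two Gaussian vessels 20 px apart, for testing
#'   that a neighbouring vessel lands in the exclusion stack.
#' * `noisy_snr10` / `noisy_snr5` — the `gauss4` family plus a gentle
#'   radial background bowl and additive white noise at
#'   contrast-to-noise ratios 10 and 5.
#'
#' @return Named list of [phantom_spec()] objects.
#' @export
phantom_suite <- function() {
  sz <- 256
  lines_at <- function(rows, ...) {
    lapply(seq_along(rows), function(i) {
      dr <- if (i %% 2L == 0L) -4 else 4  # ~1 degree tilt, alternating
      # vessels end in round caps inside the image, clear of the border
      phantom_vessel(kind = "line", p0 = c(rows[i] - dr / 2, 12),
                     p1 = c(rows[i] + dr / 2, sz - 12), ...)
    })
  }
  base <- function(vessels, noise_sd = 0, gradient = 0, seed = 1L) {
    phantom_spec(size = sz, background = 200, gradient = gradient,
                 vessels = vessels, noise_sd = noise_sd, seed = seed)
  }
  gauss_rows <- seq(20, 236, by = 36)
  gauss_fam <- lines_at(gauss_rows, profile = "gaussian", sigma = 4)
  reflex_fam <- lines_at(gauss_rows, profile = "gaussian", sigma = 4,
                         reflex = list(amplitude = 40, sigma = 0.8))
  # concentric circles: curved vessels without end caps or border exits
  arc_widths <- c(5, 9, 13)
  arc_radii <- c(45, 80, 115)
  arcs <- lapply(seq_along(arc_widths), function(i) {
    phantom_vessel(kind = "arc", centre = c(128.5, 128.5),
                   radius = arc_radii[i], theta = c(0, 2 * pi),
                   profile = "rect", width = arc_widths[i], blur = 1)
  })
  # vessel counts keep the true vessel fraction near the regime the 20%
  # threshold assumes, for every section width
  sweep_rows <- list(
    `5` = seq(14, 238, by = 28), `7` = seq(18, 235, by = 31),
    `9` = gauss_rows, `11` = seq(24, 224, by = 40),
    `13` = seq(32, 224, by = 48)
  )
  suite <- list(
    gauss4 = base(gauss_fam),
    arc_sweep = base(arcs),
    reflex_off = base(gauss_fam),
    reflex_on = base(reflex_fam),
    parallel_pair = base(list(
      phantom_vessel(kind = "line", p0 = c(108, 16), p1 = c(118, 240),
                     profile = "gaussian", sigma = 4),
      phantom_vessel(kind = "line", p0 = c(128, 16), p1 = c(138, 240),
                     profile = "gaussian", sigma = 4)
    )),
    noisy_snr10 = base(gauss_fam, noise_sd = 10, gradient = 15, seed = 7L),
    noisy_snr5 = base(gauss_fam, noise_sd = 20, gradient = 15, seed = 7L)
  )
  for (w in c(5, 7, 9, 11, 13)) {
    suite[[sprintf("rect_w%d", w)]] <-
      base(lines_at(sweep_rows[[as.character(w)]],
                    profile = "rect", width = w, blur = 1))
  }
  suite
}

#' Match measured chains to phantom ground-truth vessels
#'
#' Assigns each detected centreline chain to the phantom vessel whose
#' true centreline it follows: a chain matches vessel `i` when at least
#' `min_fraction` of its points lie within `tol` pixels of that
#' vessel's centreline. This is the standard protocol for evaluating
#' measurements against ground truth — detected segments are compared
#' only where a reference vessel exists.
#'
#' @param chains List of `centreline_chain` objects.
#' @param truth The `truth` component of a [render_phantom()] result.
#' @param tol Distance tolerance in pixels (default 2).
#' @param min_fraction Minimum fraction of chain points within `tol`
#'   (default 0.8).
#' @return Integer vector, one element per chain: the matched vessel
#'   index, or `NA` for unmatched (spurious) chains.
#' @export
match_chains <- function(chains, truth, tol = 2, min_fraction = 0.8) {
  vapply(chains, function(ch) {
    pts <- ch$points
    best <- NA_integer_
    best_frac <- 0
    for (i in seq_along(truth$centrelines)) {
      tc <- truth$centrelines[[i]]
      dmin <- vapply(seq_len(nrow(pts)), function(k) {
        min(sqrt((tc[, 1] - pts[k, 1])^2 + (tc[, 2] - pts[k, 2])^2))
      }, numeric(1))
      frac <- mean(dmin <= tol)
      if (frac >= min_fraction && frac > best_frac) {
        best <- i
        best_frac <- frac
      }
    }
    best
  }, integer(1))
}
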