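# Internal pixel-level helpers shared across modules.
#
# Images are plain numeric matrices indexed [row, col] (1-based, pixel
# centres at integer coordinates); masks are logical matrices of the same
# shape.

#' @importFrom stats median approx rnorm pnorm
NULL

# Reflect indices into 1..n with half-sample symmetric ("mirror") boundary:
# ... 2 1 | 1 2 3 ... n | n n-1 ...
reflect_index <- function(i, n) {
  if (n == 1L) return(rep.int(1L, length(i)))
  j <- (i - 1L) %% (2L * n)
  j <- ifelse(j < 0L, j + 2L * n, j)
  ifelse(j >= n, 2L * n - 1L - j, j) + 1L
}

# 1-D convolution of a matrix along rows (margin = 1, i.e. down columns) or
# columns (margin = 2) with a sparse tap list; mirror boundary extension.
# `offsets` are integer tap positions relative to the output pixel and
# `weights` the corresponding coefficients.  Zero-weight taps may be
# omitted, which is what makes the a trous scheme cheap.
conv1d_mirror <- function(mat, offsets, weights, margin) {
  out <- matrix(0, nrow(mat), ncol(mat))
  n <- if (margin == 1L) nrow(mat) else ncol(mat)
  base <- seq_len(n)
  for (k in seq_along(offsets)) {
    idx <- reflect_index(base + offsets[k], n)
    if (margin == 1L) {
      out <- out + weights[k] * mat[idx, , drop = FALSE]
    } else {
      out <- out + weights[k] * mat[, idx, drop = FALSE]
    }
  }
  out
}

# Separable 2-D convolution (rows then columns) with the same 1-D kernel.
conv_sep_mirror <- function(mat, offsets, weights) {
  conv1d_mirror(conv1d_mirror(mat, offsets, weights, 1L), offsets, weights, 2L)
}

# Dense symmetric Gaussian tap list with radius ceil(3*sigma) (>= 1).
gaussian_taps <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  off <- seq.int(-r, r)
  w <- exp(-off^2 / (2 * sigma^2))
  list(offsets = off, weights = w / sum(w))
}

# Normalised (mask-weighted) separable Gaussian smoothing.  `values` may
# contain NA where `weight` is 0; those samples do not contribute.
smooth_weighted <- function(values, weight, sigma_row, sigma_col) {
  v <- values
  v[weight == 0] <- 0
  num <- v * weight
  den <- weight
  if (sigma_row > 0) {
    g <- gaussian_taps(sigma_row)
    num <- conv1d_mirror(num, g$offsets, g$weights, 1L)
    den <- conv1d_mirror(den, g$offsets, g$weights, 1L)
  }
  if (sigma_col > 0) {
    g <- gaussian_taps(sigma_col)
    num <- conv1d_mirror(num, g$offsets, g$weights, 2L)
    den <- conv1d_mirror(den, g$offsets, g$weights, 2L)
  }
  out <- num / den
  out[den <= .Machine$double.eps] <- NA_real_
  out
}

# Count of 'on' 8-neighbours for every pixel of a logical matrix.
neighbour_count <- function(mask) {
  m <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.numeric(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  acc <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    acc <- acc + m[(2L + dr):(nr + 1L + dr), (2L + dc):(nc + 1L + dc)]
  }
  acc
}

# Label 8-connected foreground components.  Returns an integer matrix with
# 0 for background and labels 1..k renumbered in first-pixel order.
label_components8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  on <- which(mask)
  if (length(on) == 0L) return(lab)
  nr <- nrow(mask)
  r <- ((on - 1L) %% nr) + 1L
  c <- ((on - 1L) %/% nr) + 1L
  vid <- match(on, on)  # 1..m
  edges <- integer(0)
  # forward neighbours: E, S, SE, SW
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + d[1L]; c2 <- c + d[2L]
    ok <- r2 >= 1L & r2 <= nr & c2 <= ncol(mask)
    nb <- (c2[ok] - 1L) * nr + r2[ok]
    hit <- match(nb, on)
    keep <- !is.na(hit)
    edges <- c(edges, rbind(vid[ok][keep], hit[keep]))
  }
  g <- igraph::make_graph(edges = edges, n = length(on), directed = FALSE)
  comp <- igraph::components(g)$membership
  comp <- match(comp, unique(comp))  # renumber deterministically
  lab[on] <- comp
  lab
}

# Bilinear interpolation of `img` at real-valued (row, col) positions.
# Positions outside [1, nrow] x [1, ncol] give NA.
bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  out <- rep(NA_real_, length(r))
  ok <- is.finite(r) & is.finite(c) & r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); r0 <- pmax(r0, 1L)
  c0 <- pmin(floor(c), nc - 1L); c0 <- pmax(c0, 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * nr + r0
  v <- (1 - fr) * (1 - fc) * img[i00] +
    fr * (1 - fc) * img[i00 + 1] +
    (1 - fr) * fc * img[i00 + nr] +
    fr * fc * img[i00 + nr + 1]
  out[ok] <- v
  out
}

# Nearest-neighbour lookup in a logical matrix; outside positions -> NA.
nearest_lookup <- function(mask, r, c) {
  nr <- nrow(mask); nc <- ncol(mask)
  ri <- round(r); ci <- round(c)
  out <- rep(NA, length(r))
  ok <- is.finite(ri) & is.finite(ci) & ri >= 1 & ri <= nr & ci >= 1 & ci <= nc
  out[ok] <- mask[(ci[ok] - 1) * nr + ri[ok]]
  out
}

stopifnot_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop("`image` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(image))) stop("`image` must be finite", call. = FALSE)
  invisible(image)
}
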