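#' Cubic B-spline lowpass filter for the isotropic undecimated wavelet
#' transform
#'
#' The base 1-D kernel of the a trous / starlet scheme, derived from the
#' cubic B-spline: `c(1, 4, 6, 4, 1) / 16`. Its taps sum to exactly 1, so
#' repeated filtering preserves the image mean, and it is symmetric about
#' its centre.
#'
#' @return Numeric vector of length 5.
#' @seealso [iuwt_decompose()]
#' @export
iuwt_base_filter <- function() {
  c(1, 4, 6, 4, 1) / 16
}

#' Upsample a filter for a given wavelet iteration
#'
#' Builds the a trous filter used at iteration `j` by inserting
#' `2^(j-1) - 1` zeros between each pair of adjacent taps of the base
#' kernel. `j = 1` returns the kernel unchanged. The tap sum is unchanged,
#' so the filter remains mean-preserving at every scale.
#'
#' @param kernel Numeric vector, the base 1-D filter.
#' @param j Integer level index, `>= 1`.
#' @return Numeric vector of length `(length(kernel) - 1) * 2^(j-1) + 1`.
#' @export
iuwt_upsample_filter <- function(kernel, j) {
  if (length(j) != 1L || !is.finite(j) || j < 1 || j != round(j)) {
    stop("`j` must be a single integer >= 1", call. = FALSE)
  }
  gap <- 2^(j - 1) - 1
  if (gap == 0) return(kernel)
  n <- (length(kernel) - 1L) * 2^(j - 1) + 1L
  out <- numeric(n)
  out[seq.int(1L, n, by = 2^(j - 1))] <- kernel
  out
}

# Sparse tap list (offsets/weights of nonzero taps) for iteration j; the
# zeros inserted by upsampling are never touched during convolution.
iuwt_taps <- function(j) {
  k <- iuwt_base_filter()
  half <- (length(k) - 1L) / 2L
  list(offsets = as.integer(seq.int(-half, half) * 2^(j - 1)), weights = k)
}

#' Isotropic undecimated wavelet transform of an image
#'
#' Decomposes a 2-D image with the a trous scheme: starting from
#' `c_0 = image`, each scaling plane `c_j` is the separable (rows then
#' columns) convolution of `c_{j-1}` with the level-`j` upsampled cubic
#' B-spline filter, and each wavelet plane is the difference
#' `w_j = c_{j-1} - c_j`. Boundaries are handled by mirror (symmetric)
#' extension. The transform is redundant: every plane has the shape of the
#' input and the input is recovered exactly by adding the residual to all
#' wavelet planes.
#'
#' Vessels and other image features of increasing spatial scale appear
#' with best contrast on increasing wavelet levels, which is what the
#' segmentation stage exploits.
#'
#' @param image Numeric matrix of intensities.
#' @param n_levels Number of wavelet iterations `J >= 1`. If the upsampled
#'   filter footprint at some level would exceed twice the smaller image
#'   extent, deeper levels are dropped with a warning: they carry no
#'   meaningful scale information for such an image.
#' @return An object of class `iuwt_decomposition`: a list with `levels`
#'   (list of wavelet planes `w_1..w_J`), `residual` (final scaling plane
#'   `c_J`) and `n_levels`.
#' @examples
#' img <- matrix(rnorm(32 * 32), 32)
#' d <- iuwt_decompose(img, 4)
#' max(abs(iuwt_reconstruct(d) - img)) # ~1e-16: addition recovers the input
#' @export
iuwt_decompose <- function(image, n_levels) {
  stopifnot_image(image)
  if (length(n_levels) != 1L || n_levels < 1 || n_levels != round(n_levels)) {
    stop("`n_levels` must be a single integer >= 1", call. = FALSE)
  }
  n_levels <- as.integer(n_levels)
  ext <- min(dim(image))
  levels <- vector("list", n_levels)
  c_prev <- image * 1.0
  J <- 0L
  for (j in seq_len(n_levels)) {
    footprint <- (length(iuwt_base_filter()) - 1L) * 2^(j - 1) + 1L
    if (footprint > 2L * ext) {
      warning(sprintf(
        "level %d filter (length %d) exceeds twice the image extent; stopping at %d level(s)",
        j, footprint, J
      ), call. = FALSE)
      break
    }
    taps <- iuwt_taps(j)
    c_next <- conv_sep_mirror(c_prev, taps$offsets, taps$weights)
    levels[[j]] <- c_prev - c_next
    c_prev <- c_next
    J <- j
  }
  if (J == 0L) stop("image too small for even one wavelet level", call. = FALSE)
  structure(
    list(levels = levels[seq_len(J)], residual = c_prev, n_levels = J),
    class = "iuwt_decomposition"
  )
}

#' @export
print.iuwt_decomposition <- function(x, ...) {
  cat(sprintf(
    "IUWT decomposition: %d wavelet level(s) of a %d x %d image\n",
    x$n_levels, nrow(x$residual), ncol(x$residual)
  ))
  invisible(x)
}

#' Sum selected wavelet levels
#'
#' Pixelwise sum of the chosen wavelet planes, the image that the
#' segmentation stage thresholds ("adding the levels with the best
#' vessel contrast").
#'
#' @param decomp An [iuwt_decompose()] result.
#' @param level_indices Integer vector of level indices within `1..J`.
#' @return Numeric matrix of summed wavelet coefficients.
#' @export
iuwt_sum_levels <- function(decomp, level_indices) {
  stopifnot(inherits(decomp, "iuwt_decomposition"))
  level_indices <- as.integer(level_indices)
  if (length(level_indices) == 0L) {
    stop("`level_indices` must not be empty", call. = FALSE)
  }
  if (any(level_indices < 1L | level_indices > decomp$n_levels)) {
    stop(sprintf("level indices must lie in 1..%d", decomp$n_levels),
      call. = FALSE
    )
  }
  Reduce(`+`, decomp$levels[level_indices])
}

#' Reconstruct the original image from a decomposition
#'
#' Addition of the residual scaling plane and all wavelet planes; exact up
#' to floating-point rounding.
#'
#' @param decomp An [iuwt_decompose()] result.
#' @return Numeric matrix.
#' @export
iuwt_reconstruct <- function(decomp) {
  stopifnot(inherits(decomp, "iuwt_decomposition"))
  decomp$residual + Reduce(`+`, decomp$levels)
}
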