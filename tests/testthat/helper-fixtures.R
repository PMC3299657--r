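# Shared fixtures.  Rendering a phantom and running the full pipeline are
# the expensive steps, so both are memoised per (fixture, config) within a
# test run.

.fixture_cache <- new.env(parent = emptyenv())

get_phantom <- function(name, noise_sd = NULL, seed = NULL) {
  key <- paste0("ph_", name, "_", noise_sd %||% "", "_", seed %||% "")
  if (is.null(.fixture_cache[[key]])) {
    spec <- phantom_suite()[[name]]
    if (!is.null(noise_sd)) spec$noise_sd <- noise_sd
    if (!is.null(seed)) spec$seed <- as.integer(seed)
    .fixture_cache[[key]] <- render_phantom(spec)
  }
  .fixture_cache[[key]]
}

# Full pipeline run with chain-to-truth matching; `...` overrides
# vessel_config() fields.
get_measured <- function(name, noise_sd = NULL, seed = NULL, ...) {
  ov <- list(...)
  key <- paste0(
    "run_", name, "_", noise_sd %||% "", "_", seed %||% "_",
    paste(names(ov), unlist(ov), collapse = "_")
  )
  if (is.null(.fixture_cache[[key]])) {
    ph <- get_phantom(name, noise_sd, seed)
    cfg <- do.call(vessel_config, ov)
    res <- suppressWarnings(measure_image(ph$image, cfg))
    res$matched <- match_chains(res$chains, ph$truth)
    res$truth <- ph$truth
    .fixture_cache[[key]] <- res
  }
  .fixture_cache[[key]]
}

# Valid measurements belonging to chains matched to a ground-truth vessel.
matched_measurements <- function(res) {
  m <- res$measurements
  m[m$segment_id %in% which(!is.na(res$matched)) & m$valid, ]
}

# Max distance from matched chain points to their true centrelines.
max_centreline_deviation <- function(res) {
  worst <- 0
  for (i in which(!is.na(res$matched))) {
    pts <- res$chains[[i]]$points
    tc <- res$truth$centrelines[[res$matched[i]]]
    for (k in seq_len(nrow(pts))) {
      d <- min(sqrt((tc[, 1] - pts[k, 1])^2 + (tc[, 2] - pts[k, 2])^2))
      worst <- max(worst, d)
    }
  }
  worst
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a minimal profile_stack by hand for edge-module unit tests.
make_stack <- function(intensities, own = NULL, excluded = NULL,
                       centre = (ncol(intensities) + 1L) %/% 2L) {
  P <- nrow(intensities); L <- ncol(intensities)
  samples <- list(
    position = cbind(seq_len(P), rep(0, P)),
    tangent = cbind(rep(1, P), rep(0, P)),
    normal = cbind(rep(0, P), rep(1, P)),
    arc = seq_len(P) - 1
  )
  structure(
    list(
      intensities = intensities,
      own_vessel = own %||% matrix(FALSE, P, L),
      excluded = excluded %||% matrix(FALSE, P, L),
      row_coords = matrix(rep(seq_len(P), L), P, L),
      col_coords = matrix(rep(seq_len(L) - centre, each = P), P, L),
      centre_index = centre,
      samples = samples
    ),
    class = "profile_stack"
  )
}
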