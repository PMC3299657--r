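# The four-step sub-pixel edge identification.

test_that("provisional width is the median of binary row sums", {
  mk <- function(sums, L = 15) {
    own <- matrix(FALSE, length(sums), L)
    ctr <- (L + 1L) %/% 2L
    for (i in seq_along(sums)) {
      if (sums[i] > 0) {
        half <- (sums[i] - 1) %/% 2
        own[i, (ctr - half):(ctr - half + sums[i] - 1)] <- TRUE
      }
    }
    make_stack(matrix(0, length(sums), L), own = own)
  }
  expect_equal(provisional_width(mk(c(5, 5, 7, 5, 6)))$provisional_width, 5)
  expect_equal(provisional_width(mk(rep(8, 4)))$provisional_width, 8)
  expect_equal(provisional_width(mk(c(4, 6)))$provisional_width, 5)
  expect_error(provisional_width(mk(c(0, 0))), "no vessel overlap")
})

test_that("mean-profile gradient extrema sit at the Gaussian flanks", {
  L <- 41; ctr <- 21
  x <- seq_len(L) - ctr
  prof <- 100 - 60 * exp(-x^2 / (2 * 16))       # dark vessel, sigma 4
  st <- make_stack(matrix(rep(prof, each = 10), 10, L))
  est <- mean_profile_extrema(st, 8, "dark")
  expect_equal(est$left_column, ctr - 4)
  expect_equal(est$right_column, ctr + 4)
  expect_equal(est$refined_width, 8)
  # symmetric profile: extrema equidistant from the centre
  expect_equal(ctr - est$left_column, est$right_column - ctr)
  # bright polarity on the inverted profile finds the same columns
  stb <- make_stack(matrix(rep(200 - prof, each = 10), 10, L))
  estb <- mean_profile_extrema(stb, 8, "bright")
  expect_equal(estb$left_column, est$left_column)
  expect_equal(estb$right_column, est$right_column)
})

test_that("a narrow central light reflex does not shift the extrema", {
  L <- 41; ctr <- 21
  x <- seq_len(L) - ctr
  base <- 100 - 60 * exp(-x^2 / (2 * 16))
  reflex <- base + 25 * exp(-x^2 / (2 * 0.8^2))  # bump width << vessel/3
  st <- make_stack(matrix(rep(reflex, each = 10), 10, L))
  est <- mean_profile_extrema(st, 8, "dark")
  # oracle: exhaustive argmax over the search windows on the clean profile
  g <- c(NA, diff(base, lag = 2) / 2, NA)
  expect_equal(est$left_column, which.min(replace(g, (ctr):L, NA)))
  expect_equal(est$right_column, which.max(replace(g, 1:(ctr), NA)))
})

test_that("second derivative of a constant stack is zero", {
  st <- make_stack(matrix(5, 8, 21))
  d2 <- smooth_second_derivative(st, 8)
  expect_true(all(abs(d2[, 2:20]) < 1e-12))
})

test_that("parallel smoothing leaves a stack of identical rows unchanged", {
  L <- 31
  prof <- sin(seq_len(L) / 3)
  st <- make_stack(matrix(rep(prof, each = 12), 12, L))
  d2a <- smooth_second_derivative(st, 9, parallel_scale = 2,
                                  perpendicular_scale = 1e-6)
  ref <- prof[1:(L - 2)] - 2 * prof[2:(L - 1)] + prof[3:L]
  for (i in 1:12) expect_lt(max(abs(d2a[i, 2:(L - 1)] - ref)), 1e-6)
})

test_that("smoothed Gaussian dip has its inflection at one effective sigma", {
  # Gaussian convolved with Gaussian is Gaussian with summed variances:
  # the smoothed second derivative changes sign at sqrt(sigma^2 + sp^2)
  L <- 61; ctr <- 31; sigma <- 4
  x <- seq_len(L) - ctr
  prof <- 150 - 80 * exp(-x^2 / (2 * sigma^2))
  st <- make_stack(matrix(rep(prof, each = 20), 20, L))
  w <- 2 * sigma
  sp <- 0.5 * sqrt(w)                      # exaggerated to make it visible
  d2 <- smooth_second_derivative(st, w, parallel_scale = 2,
                                 perpendicular_scale = 0.5)
  row <- d2[10, ]
  cross <- which(row[-L] > 0 & row[-1] <= 0)
  cross <- cross[cross > ctr][1]
  sub <- cross + row[cross] / (row[cross] - row[cross + 1])
  expect_lt(abs((sub - ctr) - sqrt(sigma^2 + sp^2)), 0.15)
})

test_that("zero-crossing trails measure a noiseless Gaussian vessel", {
  L <- 61; ctr <- 31; sigma <- 4
  x <- seq_len(L) - ctr
  prof <- 150 - 80 * exp(-x^2 / (2 * sigma^2))
  st <- make_stack(matrix(rep(prof, each = 30), 30, L))
  est <- mean_profile_extrema(st, 2 * sigma, "dark")
  d2 <- smooth_second_derivative(st, est$refined_width)
  out <- link_zero_crossings(d2, st, est, "dark")
  expect_true(all(out$valid))
  expected <- 2 * sqrt(sigma^2 + (0.1 * sqrt(est$refined_width))^2)
  expect_lt(max(abs(out$diameter - expected)) / expected, 0.02)
  # sub-pixel columns sit strictly between opposite-signed samples
  lc <- out$left_col + ctr                  # world col -> stack column
  expect_true(all(lc > 1 & lc < L))
})

test_that("a stack with no vessel overlap cannot be measured", {
  # the no-vessel guard: step 1 refuses before any trail linking happens
  set.seed(99)
  st <- make_stack(matrix(rnorm(30 * 41), 30, 41))
  expect_error(provisional_width(st), "no vessel overlap")
})

test_that("sub-pixel crossings lie strictly between opposite-signed samples", {
  L <- 61; ctr <- 31
  x <- seq_len(L) - ctr
  prof <- 150 - 80 * exp(-x^2 / (2 * 16))
  st <- make_stack(matrix(rep(prof, each = 15), 15, L))
  est <- mean_profile_extrema(st, 8, "dark")
  d2 <- smooth_second_derivative(st, est$refined_width)
  out <- link_zero_crossings(d2, st, est, "dark")
  for (side in c("left_col", "right_col")) {
    cols <- out[[side]][out$valid] + ctr    # world -> stack column
    j <- floor(cols)
    for (k in seq_along(cols)) {
      a <- d2[k, j[k]]; b <- d2[k, j[k] + 1]
      expect_true((a >= 0) != (b >= 0))
      expect_gte(cols[k], j[k])
      expect_lt(cols[k], j[k] + 1)
    }
  }
})

test_that("crossings inside excluded regions are discarded", {
  L <- 41; ctr <- 21; sigma <- 3
  x <- seq_len(L) - ctr
  prof <- 150 - 80 * exp(-x^2 / (2 * sigma^2))
  excl <- matrix(FALSE, 20, L)
  excl[, 1:(ctr - 2)] <- TRUE               # blank out the whole left side
  st <- make_stack(matrix(rep(prof, each = 20), 20, L), excluded = excl)
  est <- mean_profile_extrema(st, 2 * sigma, "dark")
  d2 <- smooth_second_derivative(st, 6)
  out <- link_zero_crossings(d2, st, est, "dark")
  expect_true(all(!out$valid))              # left edge gone -> nothing valid
})

test_that("measure_segment returns sub-pixel diameters on a phantom", {
  res <- get_measured("arc_sweep")
  m <- matched_measurements(res)
  expect_gt(nrow(m), 500)
  for (i in which(!is.na(res$matched))) {
    mi <- m[m$segment_id == i, ]
    truth_w <- res$truth$expected_diameter[res$matched[i]]
    expect_lt(abs(mean(mi$diameter) - truth_w), 0.5)
    expect_lt(sd(mi$diameter), 0.3)
  }
})

test_that("diameters equal the Euclidean distance between edge points", {
  res <- get_measured("gauss4")
  m <- matched_measurements(res)
  d <- sqrt((m$left_row - m$right_row)^2 + (m$left_col - m$right_col)^2)
  expect_lt(max(abs(d - m$diameter)), 1e-12)
  expect_true(all(m$diameter > 0))
})
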