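# Spline fitting, arc-length sampling and profile extraction.

test_that("centripetal parameters take square roots of chord lengths", {
  p <- cbind(c(0, 0, 0), c(0, 1, 2))
  expect_equal(centripetal_parameters(p)$t, c(0, 1, 2))
  pd <- cbind(c(0, 1), c(0, 1))            # one diagonal step
  expect_equal(centripetal_parameters(pd)$t, c(0, 2^0.25))
  p2 <- cbind(c(0, 3), c(0, 4))            # two points, chord 5
  expect_equal(centripetal_parameters(p2)$t, c(0, sqrt(5)))
  # duplicate consecutive points collapse
  pdup <- cbind(c(0, 0, 1), c(0, 0, 0))
  cp <- centripetal_parameters(pdup)
  expect_equal(nrow(cp$points), 2)
  expect_error(centripetal_parameters(cbind(1, 1)), "2 distinct")
})

test_that("a line is reproduced exactly with a constant tangent", {
  pts <- cbind(5 + 0.5 * (0:49), 10 + (0:49))
  sp <- fit_centreline_spline(pts, 10)
  cp <- centripetal_parameters(pts)
  ev <- eval_spline(sp, cp$t)
  expect_lt(max(abs(ev - cp$points)), 1e-8)
  d <- eval_spline(sp, cp$t, deriv = 1)
  ang <- atan2(d[, 2], d[, 1])
  expect_lt(diff(range(ang)), 1e-8)
})

test_that("a circular arc fits within 0.25 px with accurate tangents", {
  th <- seq(0, 1.2, length.out = 200)
  pts <- cbind(100 + 50 * cos(th), 100 + 50 * sin(th))
  sp <- fit_centreline_spline(pts, 10)
  cp <- centripetal_parameters(pts)
  ev <- eval_spline(sp, cp$t)
  expect_lt(max(sqrt(rowSums((ev - cp$points)^2))), 0.25)
  d <- eval_spline(sp, cp$t, deriv = 1)
  radial <- cp$points - matrix(c(100, 100), nrow(cp$points), 2, byrow = TRUE)
  cosang <- abs(rowSums(d * radial)) /
    (sqrt(rowSums(d^2)) * sqrt(rowSums(radial^2)))
  ang_dev <- asin(pmin(1, cosang)) * 180 / pi
  expect_lt(max(ang_dev), 2)              # tangent perpendicular to radius
})

test_that("short chains fall back to a single low-order polynomial", {
  pts <- cbind(c(1, 2, 3, 4.2, 5), c(1, 2.1, 3, 4, 5.2))
  sp <- fit_centreline_spline(pts, 10)
  expect_equal(sp$ord, 4L)
  cp <- centripetal_parameters(pts)
  ev <- eval_spline(sp, cp$t)
  expect_lt(max(sqrt(rowSums((ev - cp$points)^2))), 0.5)
  sp3 <- fit_centreline_spline(pts[1:3, ], 10)
  expect_equal(sp3$ord, 3L)
  expect_error(fit_centreline_spline(pts[1, , drop = FALSE], 10), "2 distinct")
})

test_that("arc-length sampling is uniform with orthonormal frames", {
  pts <- cbind(rep(5, 21), 0:20)
  sp <- fit_centreline_spline(pts, 10)
  s <- sample_centreline(sp, 1)
  expect_equal(nrow(s$position), 21)
  expect_lt(max(abs(s$tangent[, 1])), 1e-8)     # all tangents along columns
  th <- seq(0, 1.2, length.out = 200)
  arc <- cbind(100 + 50 * cos(th), 100 + 50 * sin(th))
  s2 <- sample_centreline(fit_centreline_spline(arc, 10), 1)
  gaps <- sqrt(rowSums(diff(s2$position)^2))
  expect_true(all(gaps >= 0.8 & gaps <= 1.2))
  expect_lt(max(abs(rowSums(s2$tangent * s2$normal))), 1e-9)
  expect_lt(max(abs(sqrt(rowSums(s2$normal^2)) - 1)), 1e-9)
  # consecutive normals never flip sign
  expect_true(all(rowSums(s2$normal[-1, ] * s2$normal[-nrow(s2$normal), ]) > 0))
})

test_that("profiles of a constant image are constant rows", {
  img <- matrix(3.5, 40, 40)
  seg <- matrix(FALSE, 40, 40); seg[18:22, ] <- TRUE
  fov <- matrix(TRUE, 40, 40)
  pts <- cbind(rep(20, 20), 11:30)
  s <- sample_centreline(fit_centreline_spline(pts, 10), 1)
  st <- extract_profiles(img, seg, fov, s, 11)
  inside <- is.finite(st$intensities)
  expect_true(all(abs(st$intensities[inside] - 3.5) < 1e-12))
})

test_that("bilinear interpolation is exact on a linear ramp", {
  img <- matrix(rep(1:40, times = 40), 40, 40)   # I(r, c) = r
  seg <- matrix(FALSE, 40, 40); seg[18:22, ] <- TRUE
  fov <- matrix(TRUE, 40, 40)
  pts <- cbind(rep(20, 20), 11:30)
  s <- sample_centreline(fit_centreline_spline(pts, 10), 1)
  st <- extract_profiles(img, seg, fov, s, 11)
  # normals are vertical, so every profile is a ramp with unit slope
  # (sign depends on the normal orientation convention)
  for (i in seq_len(nrow(st$intensities))) {
    expect_lt(max(abs(abs(diff(st$intensities[i, ])) - 1)), 1e-9)
  }
  expect_lt(max(abs(st$intensities - st$row_coords)), 1e-9)
})

test_that("own-vessel runs are contiguous and contain the centre column", {
  res <- get_measured("gauss4")
  ph <- get_phantom("gauss4")
  fov <- res$fov
  ch <- res$chains[[which(!is.na(res$matched))[1]]]
  s <- sample_centreline(fit_centreline_spline(ch, 10), 1)
  st <- extract_profiles(ph$image, res$segmentation, fov, s, 17)
  expect_false(any(st$own_vessel & st$excluded))
  ctr <- st$centre_index
  for (i in seq_len(nrow(st$own_vessel))) {
    v <- st$own_vessel[i, ]
    if (!any(v)) next
    run <- range(which(v))
    expect_true(all(v[run[1]:run[2]]))
    expect_true(v[ctr])
  }
})

test_that("a neighbouring vessel is excluded and never own-vessel", {
  ph <- get_phantom("parallel_pair")
  fov <- fov_mask(ph$image, 20, 1)
  seg <- segment_vessels(ph$image, vessel_config(), fov)
  chains <- extract_centrelines(seg, 10)
  mt <- match_chains(chains, ph$truth)
  i <- which(mt == 1)[1]
  expect_false(is.na(i))
  s <- sample_centreline(fit_centreline_spline(chains[[i]], 10), 1)
  st <- extract_profiles(ph$image, seg, fov, s, 48)
  tc2 <- ph$truth$centrelines[[2]]
  near2 <- matrix(FALSE, nrow(st$intensities), ncol(st$intensities))
  for (k in seq_len(ncol(near2))) {
    d2 <- vapply(seq_len(nrow(near2)), function(p) {
      min(sqrt((tc2[, 1] - st$row_coords[p, k])^2 +
                 (tc2[, 2] - st$col_coords[p, k])^2))
    }, numeric(1))
    near2[, k] <- d2 <= 3
  }
  on_neighbour <- near2 & !is.na(st$intensities)
  expect_gt(sum(st$excluded & near2), 0)
  expect_equal(sum(st$own_vessel & near2), 0)
})
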