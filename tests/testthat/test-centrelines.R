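# Thinning, branch splitting, spur pruning and diameter estimation.

test_that("thinning a solid rectangle leaves a 1-px line along its middle", {
  rect <- matrix(FALSE, 20, 30)
  rect[8:12, 5:25] <- TRUE
  sk <- thin_mask(rect)
  expect_true(all(rect[sk]))                  # subset of the input
  pts <- which(sk, arr.ind = TRUE)
  expect_true(all(abs(pts[, 1] - 10) <= 1))   # along the middle row
  # 1-px wide: no 2x2 block fully on
  blocks <- sk[-nrow(sk), -ncol(sk)] & sk[-1, -ncol(sk)] &
    sk[-nrow(sk), -1] & sk[-1, -1]
  expect_false(any(blocks))
})

test_that("thinning trivial inputs is a no-op", {
  empty <- matrix(FALSE, 10, 10)
  expect_identical(thin_mask(empty), empty)
  line <- matrix(FALSE, 10, 10)
  line[5, 2:9] <- TRUE
  expect_identical(thin_mask(line), line)
})

test_that("thinning preserves topology (components and holes)", {
  m <- matrix(FALSE, 40, 40)
  m[5:15, 5:35] <- TRUE        # bar
  m[25:35, 5:15] <- TRUE       # separate blob ...
  m[28:32, 8:12] <- FALSE      # ... with a hole
  sk <- thin_mask(m)
  n_comp <- function(x) max(vesselcalibre:::label_components8(x))
  expect_equal(n_comp(sk), n_comp(m))
  # the hole survives: background of the skeleton blob stays disconnected
  # from the border within the blob's bounding box
  lab_bg <- EBImage::bwlabel(!sk)
  border_labels <- unique(c(lab_bg[1, ], lab_bg[40, ], lab_bg[, 1], lab_bg[, 40]))
  expect_gt(max(lab_bg), length(border_labels[border_labels > 0]))
})

test_that("branch pixels split a plus-sign skeleton into four chains", {
  pl <- matrix(FALSE, 15, 15)
  pl[8, 3:13] <- TRUE
  pl[3:13, 8] <- TRUE
  chains <- split_at_branches(pl)
  expect_length(chains, 4)
  # the crossing pixel and its four arm pixels all have >= 3 neighbours,
  # so each remaining arm is one pixel shorter than drawn
  lens <- sort(vapply(chains, function(ch) nrow(ch$points), integer(1)))
  expect_true(all(lens == 4))
})

test_that("an open curve traces into one ordered end-to-end chain", {
  m <- matrix(FALSE, 20, 20)
  path <- cbind(c(3:10, 11:16), c(rep(4, 8), 5:10))  # bend via diagonal steps
  m[path] <- TRUE
  chains <- split_at_branches(m)
  expect_length(chains, 1)
  pts <- chains[[1]]$points
  expect_equal(nrow(pts), nrow(path))
  expect_false(chains[[1]]$is_closed)
  steps <- abs(diff(pts))
  expect_true(all(pmax(steps[, 1], steps[, 2]) == 1))
  expect_equal(pts[1, ], c(3L, 4L))       # starts at the smallest end pixel
})

test_that("a closed ring traces into a single closed chain", {
  # diamond ring: diagonal steps only, so no pixel has > 2 neighbours
  m <- matrix(FALSE, 15, 15)
  for (r in 1:15) for (c in 1:15) {
    if (abs(r - 8) + abs(c - 8) == 5) m[r, c] <- TRUE
  }
  chains <- split_at_branches(m)
  expect_length(chains, 1)
  expect_true(chains[[1]]$is_closed)
  expect_equal(nrow(chains[[1]]$points), sum(m))
})

test_that("deleting a spur re-inserts branch pixels and merges the vessel", {
  sp <- matrix(FALSE, 20, 50)
  sp[10, 5:40] <- TRUE
  sp[7:9, 21] <- TRUE                      # 3-px spur off the line
  chains <- split_at_branches(sp)
  expect_length(chains, 3)
  merged <- remove_spurs(chains, sp, 10)
  expect_length(merged, 1)
  pts <- merged[[1]]$points
  steps <- abs(diff(pts))
  expect_true(all(pmax(steps[, 1], steps[, 2]) == 1))
  # spans the whole line again; spur pixels are gone
  expect_setequal(range(pts[, 2]), c(5, 40))
  expect_false(any(pts[, 1] < 9))
})

test_that("remove_spurs leaves long chains untouched", {
  sp <- matrix(FALSE, 10, 40)
  sp[5, 3:38] <- TRUE
  chains <- split_at_branches(sp)
  expect_identical(remove_spurs(chains, sp, 10), chains)
  # short isolated chain is deleted
  iso <- matrix(FALSE, 10, 10)
  iso[5, 3:7] <- TRUE
  expect_length(remove_spurs(split_at_branches(iso), iso, 10), 0)
})

test_that("diameter estimates double the max distance transform", {
  # width-5 strip: centre row is 3 px from background, estimate 6
  m <- matrix(FALSE, 11, 40)
  m[4:8, 1:40] <- TRUE
  ch <- list(vesselcalibre:::new_chain(cbind(rep(6L, 20), 11:30)))
  est <- estimate_diameters(m, ch)
  expect_equal(est[[1]]$diameter_estimate, 6)

  # single isolated pixel: distance 1 to any neighbour
  m1 <- matrix(FALSE, 9, 9)
  m1[5, 5] <- TRUE
  ch1 <- list(vesselcalibre:::new_chain(cbind(5L, 5L)))
  expect_equal(estimate_diameters(m1, ch1)[[1]]$diameter_estimate, 2)
})

test_that("diameter estimates track strip width to within 2 px", {
  # brute-force nearest-background oracle over axis-aligned strips
  for (w in seq(3, 15, by = 2)) {
    m <- matrix(FALSE, w + 10, 40)
    r0 <- 6; r1 <- 6 + w - 1
    m[r0:r1, 1:40] <- TRUE
    mid <- (r0 + r1) %/% 2
    ch <- list(vesselcalibre:::new_chain(cbind(rep(mid, 16), 13:28)))
    est <- estimate_diameters(m, ch)[[1]]$diameter_estimate
    bg <- which(!m, arr.ind = TRUE)
    oracle <- 2 * max(vapply(13:28, function(cc) {
      min(sqrt((bg[, 1] - mid)^2 + (bg[, 2] - cc)^2))
    }, numeric(1)))
    expect_equal(est, oracle)
    expect_lte(est - w, 2)
    expect_gte(est, w)
  }
})

test_that("chains shorter than their estimated diameter are dropped", {
  mk <- function(n, d) {
    ch <- vesselcalibre:::new_chain(cbind(rep(1L, n), seq_len(n)))
    ch$diameter_estimate <- d
    ch
  }
  out <- remove_short_chains(list(mk(5, 6), mk(50, 6), mk(6, 6)))
  expect_length(out, 2)
  expect_identical(remove_short_chains(list()), list())
})

test_that("centreline points stay within 1 px of the truth on phantoms", {
  res <- get_measured("rect_w9")
  expect_gt(sum(!is.na(res$matched)), 0)
  expect_lte(max_centreline_deviation(res), 1)
})
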