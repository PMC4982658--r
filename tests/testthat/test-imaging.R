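# Image-analysis chain: registration, high-pass filtering, segmentation,
# measurement, tracking and dynamics classification.

test_that("registration recovers integer and subpixel shifts", {
  set.seed(31)
  img <- matrix(rnorm(128 * 128), 128)
  expect_equal(as.numeric(register_translation(img, img)), c(0, 0))
  shifted <- shift_image(img, 3, -2)
  expect_equal(as.numeric(register_translation(img, shifted, upsample = 1)),
               c(3, -2))
  sub <- shift_image(img, 0.25, -0.75)
  est <- register_translation(img, sub, upsample = 100)
  expect_equal(as.numeric(est), c(0.25, -0.75), tolerance = 0.05)
  expect_error(register_translation(matrix(1, 8, 8), matrix(1, 8, 8)),
               "degenerate")
})

test_that("registration agrees with a dense-shift correlation oracle", {
  set.seed(32)
  img <- matrix(rnorm(64 * 64), 64)
  target <- shift_image(img, 0.35, -0.6)
  # oracle: exhaustive correlation over a dense grid of candidate shifts
  grid <- seq(-1, 1, by = 0.05)
  score <- outer(grid, grid, Vectorize(function(dy, dx) {
    cor(as.vector(shift_image(img, dy, dx)), as.vector(target))
  }))
  best <- arrayInd(which.max(score), dim(score))
  oracle <- c(grid[best[1]], grid[best[2]])
  est <- register_translation(img, target, upsample = 100)
  expect_equal(as.numeric(est), oracle, tolerance = 0.05)
})

test_that("high-pass filtration removes backgrounds and keeps spots", {
  const <- matrix(7, 64, 64)
  expect_true(all(highpass_subtract(const, 10) == 0))
  expect_true(all(highpass_subtract(const, 10, method = "median") == 0))
  spot <- const
  spot[32, 32] <- 107
  hp <- highpass_subtract(spot, 10)
  expect_equal(hp[32, 32], 100, tolerance = 10) # spot preserved within 10%
  # linear ramp: interior residual well below the ramp range
  ramp <- matrix(rep(seq(0, 100, length.out = 64), each = 64), 64, 64)
  hp <- highpass_subtract(ramp, 4)
  interior <- hp[17:48, 17:48]
  expect_lt(max(abs(interior)), 5)
})

test_that("watershed segmentation separates and counts synthetic spots", {
  blank <- matrix(0, 64, 64)
  expect_equal(max(segment_adhesions(blank, threshold = 0.5)), 0)
  # two well-separated flat ellipses
  img <- matrix(0, 96, 96)
  m1 <- facomp:::ellipse_mask(96, 25, 25, 6, 4, 0)
  m2 <- facomp:::ellipse_mask(96, 70, 65, 5, 3, pi / 4)
  img[m1] <- 50; img[m2] <- 80
  labs <- segment_adhesions(img, smooth_sigma = 0, threshold = 1,
                            tolerance = 10)
  expect_equal(max(labs), 2)
  cen <- facomp:::label_centroids(labs)
  expect_equal(unname(sort(cen[, 1])), c(25, 70), tolerance = 0.1)
  # touching Gaussian peaks are split by the watershed
  g <- function(cy, cx, s, amp) {
    amp * exp(-(outer((1:96 - cy)^2, (1:96 - cx)^2, "+")) / (2 * s^2))
  }
  two <- g(48, 40, 4, 100) + g(48, 58, 4, 100)
  labs2 <- segment_adhesions(two, smooth_sigma = 0, threshold = 5,
                             tolerance = 10)
  expect_equal(max(labs2), 2)
})

test_that("region measurement matches geometry and moment formulas", {
  labs <- matrix(0L, 16, 16)
  labs[3, 3:6] <- 1L
  ch <- matrix(0, 16, 16)
  ch[3, 3:6] <- c(2, 4, 6, 8)
  m <- measure_regions(labs, list(x = ch))
  expect_equal(m$x, 5)          # mean of {2,4,6,8}
  expect_equal(m$pixels, 4L)
  # circle: eccentricity near 0; ellipse a=5 b=3: ecc = c/a = 0.8
  size <- 64
  circ <- matrix(0L, size, size); circ[facomp:::ellipse_mask(size, 32, 32, 10, 10, 0)] <- 1L
  ell <- matrix(0L, size, size); ell[facomp:::ellipse_mask(size, 32, 32, 15, 9, 0)] <- 1L
  mc <- measure_regions(circ, list())
  me <- measure_regions(ell, list())
  expect_lt(mc$eccentricity, 0.15)
  expect_equal(me$eccentricity, 0.8, tolerance = 0.03)
  # area uses the pixel size
  m2 <- measure_regions(labs, list(), pixel_size = 0.5)
  expect_equal(m2$area, 4 * 0.25)
  expect_error(measure_regions(labs, list(bad = matrix(0, 4, 4))),
               "mismatch")
})

test_that("measurement is invariant to label renumbering and channel order", {
  set.seed(33)
  img <- matrix(0, 64, 64)
  ma <- facomp:::ellipse_mask(64, 20, 20, 5, 3, 0)
  mb <- facomp:::ellipse_mask(64, 45, 45, 6, 4, 1)
  labs <- matrix(0L, 64, 64); labs[ma] <- 1L; labs[mb] <- 2L
  relab <- matrix(0L, 64, 64); relab[ma] <- 7L; relab[mb] <- 3L
  chans <- list(c1 = matrix(runif(64 * 64), 64),
                c2 = matrix(runif(64 * 64), 64))
  a <- measure_regions(labs, chans)
  b <- measure_regions(relab, chans)
  expect_equal(a[order(a$cy), c("pixels", "c1", "c2")],
               b[order(b$cy), c("pixels", "c1", "c2")], ignore_attr = TRUE)
  d <- measure_regions(labs, rev(chans))
  expect_equal(a$c1, d$c1)
})

test_that("tracking applies overlap first, then the 10-px centroid rule", {
  # identity: every region tracked through all frames, age (>12')
  base <- matrix(0L, 32, 32); base[5:9, 5:9] <- 1L; base[20:25, 18:24] <- 2L
  seqs <- rep(list(base), 6)
  tr <- track_adhesions(seqs)
  expect_length(tr, 2)
  expect_true(all(vapply(tr, function(t) t$first_frame, 0L) == 1L))
  expect_equal(classify_dynamics(tr[[1]], 6)$age, "(>12')")
  # 8 px apart, no overlap: matched
  p8 <- shifted_pair(8)
  tr8 <- track_adhesions(p8)
  expect_equal(tr8[[1]]$first_frame, 1L)
  # 12 px apart: not matched; the earlier region is not in the output
  p12 <- shifted_pair(12)
  tr12 <- track_adhesions(p12)
  expect_length(tr12, 1)
  expect_equal(tr12[[1]]$first_frame, 2L)
  # determinism
  expect_identical(track_adhesions(p8), track_adhesions(p8))
})

fake_traj <- function(totals, first_frame = 1L, n_frames = 6L) {
  frames <- first_frame:n_frames
  structure(list(id = 1L, frames = frames, labels = frames * 0 + 1L,
                 areas = rep(10, length(frames)),
                 centroids = matrix(0, length(frames), 2),
                 totals = totals, first_frame = first_frame),
            class = "fa_trajectory")
}

test_that("dynamics classes follow the Pearson +/-0.7 rule", {
  up <- fake_traj(c(5, 10, 20, 30, 40, 45))
  down <- fake_traj(c(45, 40, 30, 20, 10, 5))
  wob <- fake_traj(c(10, 10, 11, 10, 11, 10))
  expect_equal(classify_dynamics(up, 6)$dynamics, "AS")
  expect_equal(classify_dynamics(down, 6)$dynamics, "DS")
  expect_equal(classify_dynamics(wob, 6)$dynamics, "ST")
  # |r| < 0.7 on {10, 11, 10, 11}: direct Pearson gives r ~ 0.45
  expect_lt(abs(cor(1:4, c(10, 11, 10, 11))), 0.7)
  # constant trace: undefined r treated as stationary
  flat <- fake_traj(rep(10, 6))
  expect_equal(classify_dynamics(flat, 6)$dynamics, "ST")
  # young adhesions get an age but no dynamics class
  young <- fake_traj(c(10, 20), first_frame = 5L)
  cls <- classify_dynamics(young, 6)
  expect_equal(cls$age, "3'")
  expect_true(is.na(cls$dynamics))
})
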