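cfg <- tm_config()

## ideal C-alpha helix along a given unit axis, centred at the origin
ideal_helix <- function(n = 20L, axis = c(0, 0, 1), rise = 1.5, r = 2.3,
                        twist = 100) {
  e <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- e - sum(e * axis) * axis; u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  j <- seq_len(n) - 1L
  t_j <- (j - (n - 1) / 2) * rise
  phi <- twist * pi / 180 * j
  outer(t_j, axis) + r * (outer(cos(phi), u) + outer(sin(phi), v))
}

angle_deg <- function(a, b) {
  acos(min(1, max(-1, sum(a * b) / sqrt(sum(a^2) * sum(b^2))))) * 180 / pi
}

test_that("helix axis fitting recovers the construction axis and equivaries under rotation", {
  h <- ideal_helix(20L)
  fit <- fit_helix_axis(h)
  expect_lt(angle_deg(fit$axis, c(0, 0, 1)), 1e-6 * 180 / pi)
  expect_equal(fit$centroid, colMeans(h), tolerance = 1e-12)

  set.seed(4)
  for (rep in 1:5) {
    R <- random_rotation()
    fitR <- fit_helix_axis(h %*% t(R))
    expect_lt(angle_deg(fitR$axis, as.numeric(R %*% c(0, 0, 1))), 1e-6 * 180 / pi)
  }
})

test_that("axis fit tolerates coordinate noise to within 5 degrees", {
  set.seed(12)
  h <- ideal_helix(22L)
  noisy <- h + matrix(rnorm(length(h), 0, 0.3), ncol = 3)
  fit <- fit_helix_axis(noisy)
  expect_lt(angle_deg(fit$axis, c(0, 0, 1)), 5)
})

test_that("axis fit rejects degenerate input", {
  expect_error(fit_helix_axis(ideal_helix(4L)), "at least 5")
  expect_error(fit_helix_axis(matrix(1, 6, 3)), "coincident")
})

test_that("segment orientation classifies up, down and in-plane axes", {
  fr <- membrane_frame(c(0, 0, 1))
  expect_identical(segment_orientation(c(0, 0, 1), fr), "UP")
  expect_identical(segment_orientation(c(0, 0, -1), fr), "DOWN")
  expect_identical(segment_orientation(c(1, 0, 0), fr), "UNDEFINED")
  ## threshold: default cos 0.5 is a 60-degree tilt limit
  tilted <- c(sin(65 * pi / 180), 0, cos(65 * pi / 180))
  expect_identical(segment_orientation(tilted, fr), "UNDEFINED")
})

test_that("triplet handedness matches construction and flips under mirror", {
  fr <- membrane_frame(c(0, 0, 1))
  circ <- function(deg) c(10 * cos(deg * pi / 180), 10 * sin(deg * pi / 180), 0)
  ## counterclockwise progression seen from +z is left-handed (default
  ## convention: clockwise = R)
  expect_identical(triplet_handedness(circ(0), circ(120), circ(240), fr, cfg), "L")
  neg <- function(p) c(-p[1], p[2], p[3])
  expect_identical(
    triplet_handedness(neg(circ(0)), neg(circ(120)), neg(circ(240)), fr, cfg), "R")
  ## the convention switch flips every label
  cfg_flip <- tm_config(handedness_convention = "clockwise_L")
  expect_identical(triplet_handedness(circ(0), circ(120), circ(240), fr, cfg_flip), "R")
  ## coincident projected centroids are an error
  expect_error(
    triplet_handedness(c(0, 0, 0), c(0, 0, 5), c(1, 1, 0), fr, cfg), "coincide")
})

test_that("handedness agrees with the signed-area oracle on random triplets", {
  set.seed(101)
  fr <- membrane_frame(c(0, 0, 1))
  n_ok <- 0L
  for (rep in 1:200) {
    pts <- matrix(runif(9, -20, 20), 3, 3)
    lab_o <- oracle_turn_label(pts[1, ], pts[2, ], pts[3, ])
    lab <- triplet_handedness(pts[1, ], pts[2, ], pts[3, ], fr, cfg)
    n_ok <- n_ok + (lab == lab_o)
  }
  expect_identical(n_ok, 200L)
})

test_that("handedness labels are invariant under joint rigid motion", {
  set.seed(33)
  for (rep in 1:20) {
    pts <- matrix(runif(9, -20, 20), 3, 3)
    fr <- membrane_frame(c(0, 0, 1), c(0, 0, 0))
    lab <- triplet_handedness(pts[1, ], pts[2, ], pts[3, ], fr, cfg)
    R <- random_rotation(); tr <- runif(3, -50, 50)
    mv <- function(p) as.numeric(R %*% p + tr)
    fr2 <- membrane_frame(as.numeric(R %*% fr$normal), mv(fr$origin))
    lab2 <- triplet_handedness(mv(pts[1, ]), mv(pts[2, ]), mv(pts[3, ]), fr2, cfg)
    expect_identical(lab2, lab)
  }
})

test_that("negating the normal or reversing the walk flips the label", {
  set.seed(44)
  for (rep in 1:20) {
    pts <- matrix(runif(9, -20, 20), 3, 3)
    fr <- membrane_frame(c(0, 0, 1))
    lab <- triplet_handedness(pts[1, ], pts[2, ], pts[3, ], fr, cfg)
    if (lab == "X") next
    fr_neg <- membrane_frame(c(0, 0, -1))
    expect_identical(triplet_handedness(pts[1, ], pts[2, ], pts[3, ], fr_neg, cfg),
                     chartr("RL", "LR", lab))
    expect_identical(triplet_handedness(pts[3, ], pts[2, ], pts[1, ], fr, cfg),
                     chartr("RL", "LR", lab))
  }
})

test_that("handedness strings concatenate consecutive core triplets", {
  b <- do.call(make_helix_bundle, bundle_preset("rrll"))
  p <- profile_of_bundle(b)
  expect_identical(handedness_string(p), "RRLL")
  b4 <- do.call(make_helix_bundle, bundle_preset("rr"))
  expect_identical(handedness_string(profile_of_bundle(b4)), "RR")
  b3 <- do.call(make_helix_bundle, bundle_preset("l3"))
  expect_identical(handedness_string(profile_of_bundle(b3)), "L")
  ## fewer than three qualifying segments is an error
  p2 <- mk_profile(c(20L, 20L), c("UP", "DOWN"))
  expect_error(handedness_string(p2), "at least 3")
})

test_that("profile building assigns orientations, sorts ranges, and validates coverage", {
  b <- do.call(make_helix_bundle, list(n_segments = 4L, ring_radius = 12,
                                       angular_order = c(0, 90, 180, 270),
                                       orientation_pattern = "UDUD"))
  p <- build_profile(b$coords, b$tm_ranges, b$frame)
  expect_identical(segment_orientations(p), c("UP", "DOWN", "UP", "DOWN"))

  ## shuffled input ranges come back in chain order
  shuffled <- b$tm_ranges[c(3, 1, 4, 2), ]
  p2 <- build_profile(b$coords, shuffled, b$frame)
  expect_identical(as.data.frame(p), as.data.frame(p2))

  ## a 3-residue range cannot be fitted
  bad <- b$tm_ranges
  bad$end[1] <- bad$start[1] + 2L
  expect_error(build_profile(b$coords, bad, b$frame), "fewer than 5|coverage")

  ## missing C-alpha below 80% coverage of a range
  thin <- b$coords[-(2:8), ]
  expect_error(build_profile(thin, b$tm_ranges, b$frame), "coverage")
})
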