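# Trajectory statistics: distance series, binning, occupancy, ring
# distances, RMSD.

test_that("hbond_series reproduces hand-computed distances", {
  traj <- tiny_hbond_traj(c(1.8, 2.2, 3.0))
  s <- hbond_series(traj, bond_id = "toy")
  expect_equal(s$distances, c(1.8, 2.2, 3.0), tolerance = 1e-12)
  one <- tiny_hbond_traj(2.0)
  expect_equal(hbond_series(one, bond_id = "toy")$distances, 2.0)
  expect_error(hbond_series(traj, hydrogen = 99, acceptor = 1),
               "out of range")
})

test_that("binning follows the half-open edge rule", {
  h <- bin_hbond_series(c(1.625, 1.626, 1.874))
  expect_equal(h$frequencies[1], 200 / 3, tolerance = 1e-9)  # 66.67 %
  expect_equal(h$frequencies[2], 100 / 3, tolerance = 1e-9)  # 33.33 %
  expect_equal(sum(h$counts), 3)
  # a value exactly on an edge goes to the upper bin
  h2 <- bin_hbond_series(c(1.75))
  expect_equal(h2$counts, c(0, 1, 0, 0, 0, 0, 0, 0))
})

test_that("out-of-range frames count in the denominator but no bin", {
  h <- bin_hbond_series(rep(5.0, 100))
  expect_equal(h$frequencies, rep(0, 8))
  expect_equal(h$n_frames_total, 100)
  expect_equal(h$n_out_of_range, 100)
})

test_that("zero-variance series fills a single bin completely", {
  traj <- tiny_hbond_traj(rep(2.125, 50))
  h <- bin_hbond_series(hbond_series(traj, bond_id = "toy"))
  expect_equal(h$frequencies[h$bin_centers == 2.125], 100)
  expect_equal(sum(h$frequencies), 100)
})

test_that("histogram conserves counts exactly", {
  set.seed(42)
  for (i in 1:5) {
    x <- runif(200, 0.5, 6)
    h <- bin_hbond_series(x)
    expect_identical(sum(h$counts) + h$n_out_of_range, 200L)
  }
})

test_that("occupancy counts frames at or below the cutoff", {
  expect_equal(occupancy(c(1.8, 2.2, 4.0), 3.5), 200 / 3, tolerance = 1e-9)
  expect_equal(occupancy(c(1.8, 2.2, 4.0), Inf), 100)
  expect_equal(occupancy(c(4.0, 5.0), 3.5), 0)
})

test_that("occupancy is non-decreasing in the cutoff", {
  set.seed(7)
  x <- runif(300, 1, 6)
  cuts <- seq(0.5, 7, by = 0.25)
  occ <- vapply(cuts, function(ct) occupancy(x, ct), numeric(1))
  expect_true(all(diff(occ) >= 0))
})

test_that("ring centroid distances are plain centroid arithmetic", {
  tri <- function(c0) rbind(c0 + c(1, 0, 0), c0 + c(-0.5, 0.866, 0),
                            c0 + c(-0.5, -0.866, 0))
  coords <- array(rbind(tri(c(0, 0, 0)), tri(c(4, 0, 0))), c(6, 3, 1))
  traj <- structure(list(coords = coords, elements = rep("C", 6),
                         monitored = data.frame(), ring_pairs = list(),
                         n_frames = 1L), class = "toy_trajectory")
  expect_equal(ring_centroid_series(traj, 1:3, 4:6), 4.0, tolerance = 1e-12)
  coords2 <- array(rbind(tri(c(0, 0, 0)), tri(c(0, 0, 0))), c(6, 3, 1))
  traj2 <- structure(list(coords = coords2, elements = rep("C", 6),
                          monitored = data.frame(), ring_pairs = list(),
                          n_frames = 1L), class = "toy_trajectory")
  expect_equal(ring_centroid_series(traj2, 1:3, 4:6), 0.0)
  expect_error(ring_centroid_series(traj, 1:2, 4:6), "at least 3")
  expect_error(ring_centroid_series(traj, 1:3, 3:6), "disjoint")
})

test_that("fraction_below counts a direct threshold", {
  expect_equal(fraction_below(c(4.9, 5.1), 5.0), 0.5)
  expect_equal(fraction_below(c(1, 2), 5.0), 1)
})

test_that("RMSD removes rigid motion only under superposition", {
  spec <- hbond_spec("r", 1, 2.0, 0.1, 4)
  traj <- make_hbond_trajectory(list(spec), seed = 2)
  # all frames identical
  traj$coords[3, 1, ] <- 2.5
  expect_equal(rmsd_series(traj), rep(0, 4), tolerance = 1e-9)
  # frame 2 rigidly translated
  traj$coords[, , 2] <- traj$coords[, , 2] + rep(c(1, 0, 0), each = 3)
  r_fit <- rmsd_series(traj, superpose = TRUE)
  r_raw <- rmsd_series(traj, superpose = FALSE)
  expect_equal(r_fit[2], 0, tolerance = 1e-6)
  expect_equal(r_raw[2], 1.0, tolerance = 1e-9)
  expect_true(all(r_fit <= r_raw + 1e-9))
  expect_error(rmsd_series(traj, atom_selection = 1:2, superpose = TRUE),
               "at least 3")
})

test_that("binding-power labels follow the configurable thresholds", {
  expect_equal(hbond_strength_label(c(1.9, 2.0, 2.3, 2.6, 3.0)),
               c("strong", "medium", "medium", "weak", "weak"))
  expect_equal(hbond_strength_label(2.3, strong_below = 2.4,
                                    medium_below = 2.8), "strong")
  expect_error(hbond_strength_label(2, 2.6, 2.0))
})

test_that("binned frequencies converge to the mixture bin probabilities", {
  spec <- hbond_spec("cv", c(0.4, 0.6), c(2.0, 2.9), c(0.12, 0.2), 10000)
  traj <- make_hbond_trajectory(list(spec), seed = 13)
  h <- bin_hbond_series(traj$distances[, 1])
  for (k in seq_along(h$bin_centers)) {
    p <- mixture_bin_probability(spec, h$bin_centers[k] - 0.125,
                                 h$bin_centers[k] + 0.125)
    expect_lt(abs(h$frequencies[k] - 100 * p), 2)
  }
})
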