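# Synthetic trajectory generator: statistical and geometric contracts.

test_that("zero-variance spec realizes the exact distance in every frame", {
  spec <- hbond_spec("const", 1, 2.0, 0, 10)
  traj <- make_hbond_trajectory(list(spec), seed = 3)
  s <- hbond_series(traj, bond_id = "const")
  expect_equal(s$distances, rep(2.0, 10), tolerance = 1e-12)
})

test_that("monitored-pair distances equal the drawn series to 1e-9", {
  specs <- list(hbond_spec("a", c(0.5, 0.5), c(1.9, 2.9), c(0.1, 0.2), 500),
                hbond_spec("b", 1, 2.2, 0.15, 500))
  traj <- make_hbond_trajectory(specs, seed = 11,
                                ring_specs = list(
                                  ring_spec("r1", 1, 5.0, 0.4, 500)))
  for (id in c("a", "b")) {
    s <- hbond_series(traj, bond_id = id)
    expect_lt(max(abs(s$distances - traj$distances[, id])), 1e-9)
  }
  r <- ring_centroid_series(traj, pair_id = "r1")
  expect_lt(max(abs(r - traj$ring_distances[, "r1"])), 1e-9)
})

test_that("sample moments recover the generating mixture", {
  spec <- hbond_spec("m", 1, 2.0, 0.1, 10000)
  traj <- make_hbond_trajectory(list(spec), seed = 7)
  d <- traj$distances[, 1]
  expect_lt(abs(mean(d) - 2.0), 0.01)
  expect_lt(abs(sd(d) - 0.1), 0.01)
})

test_that("bimodal mixture splits mass per the closed-form CDF", {
  spec <- hbond_spec("bi", c(0.6, 0.4), c(1.9, 2.9), c(0.15, 0.15), 20000)
  traj <- make_hbond_trajectory(list(spec), seed = 21)
  frac <- mean(traj$distances[, 1] < 2.4)
  expect_lt(abs(frac - 0.6), 0.02)
  expect_lt(abs(frac - mixture_cdf(spec, 2.4)), 0.02)
})

test_that("empirical distribution matches the truncated mixture CDF (KS)", {
  spec <- hbond_spec("ks", c(0.3, 0.7), c(1.8, 2.6), c(0.1, 0.3), 10000)
  traj <- make_hbond_trajectory(list(spec), seed = 5)
  d <- sort(traj$distances[, 1])
  emp <- seq_along(d) / length(d)
  ks <- max(abs(emp - mixture_cdf(spec, d)))
  expect_lt(ks, 0.02)
})

test_that("same seed gives bit-identical output; substreams ignore order", {
  specs <- list(hbond_spec("x", 1, 2.0, 0.2, 200),
                hbond_spec("y", 1, 2.8, 0.1, 200))
  t1 <- make_hbond_trajectory(specs, seed = 9)
  t2 <- make_hbond_trajectory(specs, seed = 9)
  expect_identical(t1$coords, t2$coords)
  t3 <- make_hbond_trajectory(rev(specs), seed = 9)
  expect_identical(t1$distances[, "x"], t3$distances[, "x"])
  expect_identical(t1$distances[, "y"], t3$distances[, "y"])
  t4 <- make_hbond_trajectory(specs, seed = 10)
  expect_false(identical(t1$distances, t4$distances))
})

test_that("spec validation rejects malformed mixtures", {
  expect_error(hbond_spec("w", c(0.5, 0.6), c(2, 3), c(0.1, 0.1), 10),
               "sum to 1")
  expect_error(hbond_spec("w", 1, 4.0, 0.1, 10), "1.5, 3.5")
  expect_error(hbond_spec("w", 1, 2.0, -0.1, 10), ">= 0")
  expect_error(hbond_spec("w", 1, 2.0, 0.1, 0), "n_frames")
  expect_error(
    make_hbond_trajectory(list(hbond_spec("a", 1, 2, 0.1, 10),
                               hbond_spec("b", 1, 2, 0.1, 20)), seed = 1),
    "same n_frames")
})

test_that("water-water scan places O-O separations exactly", {
  spec <- dimer_scan_spec(water_molecule(), water_molecule(),
                          separations = c(3, 5, 10), axis = c(1, 0, 0),
                          anchor_a = 1, anchor_b = 1)
  dimers <- make_dimer_scan(spec)
  expect_length(dimers, 3)
  for (i in seq_along(dimers)) {
    d <- sqrt(sum((dimers[[i]]$fragment_a$xyz[1, ] -
                     dimers[[i]]$fragment_b$xyz[1, ])^2))
    expect_equal(d, c(3, 5, 10)[i], tolerance = 1e-12)
  }
})

test_that("overlapping separations are refused with a clear message", {
  spec <- dimer_scan_spec(helium_atom(), helium_atom("He2"),
                          separations = 0.3)
  expect_error(make_dimer_scan(spec), "refusing")
})

test_that("formamide N-H...O=C fixture hits the requested H...O distance", {
  fa <- formamide_molecule()
  # anchor A: carbonyl O (atom 2); anchor B: syn amide H (atom 5)
  spec <- dimer_scan_spec(fa, fa, separations = 1.9, axis = c(1, 0, 0),
                          anchor_a = 2, anchor_b = 5)
  d <- make_dimer_scan(spec)[[1]]
  r <- sqrt(sum((d$fragment_a$xyz[2, ] - d$fragment_b$xyz[5, ])^2))
  expect_equal(r, 1.9, tolerance = 1e-9)
})

test_that("demo specs load from the packaged frequency table", {
  specs <- demo_hbond_specs(100)
  expect_true("ASP118_O1" %in% names(specs))
  expect_length(specs, 10)
  for (s in specs) expect_equal(sum(s$weights), 1, tolerance = 1e-12)
  rings <- demo_ring_specs(100)
  # PHE44-like pair spends about half the time under 5 angstrom
  expect_lt(abs(mixture_cdf(rings$PHE44, 5.0) - 0.5), 0.05)
})
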