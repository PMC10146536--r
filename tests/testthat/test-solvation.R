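# Radial profiles, RDFs and hydration numbers.

test_that("a delta shell lands in one bin and every profile integrates
           to one", {
  # 40 atoms at exactly 2.0 nm from a central heavy reference atom
  set.seed(14)
  v <- matrix(rnorm(120), ncol = 3)
  dirs <- v / sqrt(rowSums(v^2))
  atoms <- cloud_atoms(41, mass = c(1000, rep(1, 40)))
  x <- rbind(c(0, 0, 0), 1.99 * dirs) + 10   # mid-bin radius
  frames <- list(new_frame(x, rep(20, 3), 0), new_frame(x, rep(20, 3), 10))
  tr <- new_trajectory(atoms, frames, dt_store = 10)
  pr <- radial_profile(tr, list(shell = 2:41), reference = 1,
                       bin_width = 0.02, window_last = span_ns(tr))
  occupied <- which(pr$counts[, "shell"] > 0)
  expect_length(occupied, 1)
  expect_equal(pr$r[occupied], 1.99, tolerance = 0.011)
  expect_equal(sum(pr$P[, "shell"]) * pr$bin_width, 1, tolerance = 1e-9)
})

test_that("a radius-uniform shell sample gives a flat occupied band and a
           surface shell collapses onto its radius", {
  # radius drawn uniformly on [1.2, 1.8]: flat count profile inside
  set.seed(23)
  n <- 20000
  v <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- v / sqrt(rowSums(v^2))
  rad <- runif(n, 1.2, 1.8)
  atoms <- cloud_atoms(n + 1, mass = c(1e6, rep(1, n)))
  x <- rbind(c(0, 0, 0), rad * dirs) + 5
  tr <- new_trajectory(atoms, list(new_frame(x, rep(10, 3), 0)),
                       dt_store = 10)
  pr <- suppressWarnings(radial_profile(tr, list(s = 1 + seq_len(n)),
                                        reference = 1, bin_width = 0.05))
  inside <- pr$counts[, "s"][pr$r > 1.25 & pr$r < 1.75]
  outside <- pr$counts[, "s"][pr$r < 1.15 | pr$r > 1.85]
  expect_true(all(outside == 0))
  expect_lt(max(abs(inside - mean(inside))) / mean(inside), 0.15)
  # a zero-thickness surface shell occupies only the bins at its radius
  fx <- analytic_fixture("shell", R = 1.5, n = 5000, seed = 3)
  tr2 <- new_trajectory(fx$atoms, list(fx$frame), dt_store = 10)
  pr2 <- suppressWarnings(radial_profile(tr2, list(s = seq_len(5000)),
                                         reference = seq_len(5000),
                                         bin_width = 0.05))
  expect_true(all(abs(pr2$r[pr2$counts[, "s"] > 0] - 1.5) <= 0.05))
})

test_that("an ideal-gas configuration has g(r) = 1 and a single pair puts
           its only mass at the pair distance", {
  fx <- analytic_fixture("ideal_gas_bath", n = 4000, box = c(4, 4, 4),
                         seed = 6)
  tr <- new_trajectory(fx$atoms, list(fx$frame), dt_store = 10)
  g <- suppressWarnings(rdf(tr, center_group = 1:200,
                            around_group = 201:4000,
                            r_max = 1.9, bin_width = 0.05))
  band <- g$g[g$r >= 0.5 & g$r <= 1.9]
  expect_lt(max(abs(band - 1)), 0.05)
  expect_error(suppressWarnings(rdf(tr, 1:10, 11:20, r_max = 2.5)),
               "half")
  # single centre with one neighbour at 0.31 nm (mid-bin)
  a2 <- cloud_atoms(2)
  f2 <- new_frame(rbind(c(1, 1, 1), c(1.31, 1, 1)), c(5, 5, 5))
  t2 <- new_trajectory(a2, list(f2), dt_store = 10)
  g2 <- suppressWarnings(rdf(t2, 1, 2, r_max = 1, bin_width = 0.02))
  expect_equal(g2$r[which(g2$counts > 0)], 0.31, tolerance = 0.011)
  expect_equal(sum(g2$counts > 0), 1)
  # around-group entirely beyond r_max: g identically zero
  f3 <- new_frame(rbind(c(1, 1, 1), c(3.5, 1, 1)), c(8, 8, 8))
  t3 <- new_trajectory(a2, list(f3), dt_store = 10)
  g3 <- suppressWarnings(rdf(t3, 1, 2, r_max = 1, bin_width = 0.02))
  expect_true(all(g3$g == 0))
})

test_that("hydration counting is exact on a constructed shell and
           half-open at the cutoff", {
  # one labelled solute with exactly 4 water O at 0.30 nm, one at the
  # cutoff + 1e-6 (excluded), one far away
  sol <- cloud_atoms(1, mass = 12); sol$label <- "X"
  wat <- cloud_atoms(6, role = "WATER_O"); wat$molid <- 1 + 1:6
  atoms <- rbind(sol, wat)
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  x <- rbind(c(0, 0, 0), 0.30 * dirs, c(0.35 + 1e-6, 0, 0), c(2, 2, 2)) + 4
  tr <- new_trajectory(atoms, list(new_frame(x, rep(8, 3), 0),
                                   new_frame(x, rep(8, 3), 10)),
                       dt_store = 10)
  h <- suppressWarnings(hydration_number(tr, "X", cutoff = 0.35,
                                         window_last = span_ns(tr)))
  expect_equal(h$mean, 4.0)
})

test_that("a uniform bath recovers the ideal-gas hydration closed form
           and the RDF-integral route matches direct counting", {
  tr <- bath_trajectory(n_centers = 8, rho = 33, box = 3.2, n_frames = 40,
                        seed = 5)
  w <- span_ns(tr)
  h <- hydration_number(tr, "X", cutoff = 0.35, window_last = w)
  expected <- 4 / 3 * pi * 0.35^3 * 33
  expect_lt(abs(h$mean - expected) / expected, 0.03)
  h_rdf <- hydration_number(tr, "X", cutoff = 0.35, method = "rdf",
                            window_last = w)
  expect_lt(abs(h$mean - h_rdf$mean) / h$mean, 0.01)
})

test_that("tail-end carbons are multimodal with exterior tails and the
           hydroxyl is better hydrated than the buried link oxygen", {
  traj <- cached_micelle(9)
  w <- span_ns(traj)
  pr <- radial_profile(traj, list(C2 = select_atoms(traj$atoms, "C2")),
                       bin_width = 0.05, window_last = w)
  expect_gte(count_modes(pr$P[, "C2"]), 2)
  hyd <- hydration_profile(traj, labels = c("O1", "OH"), window_last = w)
  expect_gt(hyd$hydration[hyd$label == "OH"],
            hyd$hydration[hyd$label == "O1"])
  # interior-only tails are unimodal
  traj0 <- cached_micelle(5, n_agg = 15, n_waters = 300, n_frames = 4,
                          f_out = 0)
  pr0 <- radial_profile(traj0, list(C2 = select_atoms(traj0$atoms, "C2")),
                        bin_width = 0.05, window_last = span_ns(traj0))
  expect_equal(count_modes(pr0$P[, "C2"]), 1)
})
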