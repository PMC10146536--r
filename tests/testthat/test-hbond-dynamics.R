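# Geometric hydrogen-bond detection, per-position counts, and the
# intermittent correlation function.

# Minimal donor/acceptor frame: a donor at distance `d_da` from the
# acceptor with its hydrogen placed (0.1 nm from the donor) so the
# D-H...A angle at the hydrogen equals `dha_deg` exactly.
hb_frame <- function(d_da, dha_deg) {
  box <- rep(6, 3)
  A <- c(3, 3, 3)
  D <- A + c(d_da, 0, 0)
  angle_at_h <- function(beta) {
    H <- D + 0.1 * c(-cos(beta), sin(beta), 0)
    v1 <- D - H; v2 <- A - H
    acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  }
  beta <- if (dha_deg >= 180) 0 else
    uniroot(function(b) angle_at_h(b) - dha_deg, c(1e-9, pi - 1e-9))$root
  H <- D + 0.1 * c(-cos(beta), sin(beta), 0)
  new_frame(rbind(A, D, H), box)
}

test_that("the distance and angle criteria gate bonding as specified", {
  crit <- hbond_criterion()
  don <- cbind(D = 2L, H = 3L)
  expect_equal(nrow(detect_hbonds(hb_frame(0.34, 180), don, 1L, crit)), 1)
  expect_equal(nrow(detect_hbonds(hb_frame(0.36, 180), don, 1L, crit)), 0)
  expect_equal(nrow(detect_hbonds(hb_frame(0.30, 90), don, 1L, crit)), 0)
  expect_equal(nrow(detect_hbonds(hb_frame(0.30, 125), don, 1L, crit)), 1)
  expect_equal(nrow(detect_hbonds(hb_frame(0.3499, 180), don, 1L, crit)), 1)
  # GROMACS-style convention: angle at the donor, maximum 30 degrees
  g <- hbond_criterion(angle = 30, convention = "hda_max")
  expect_equal(nrow(detect_hbonds(hb_frame(0.34, 180), don, 1L, g)), 1)
  expect_equal(nrow(detect_hbonds(hb_frame(0.30, 90), don, 1L, g)), 0)
  expect_error(hbond_criterion(angle = 200), "angle")
})

test_that("the bonded set is invariant under donor-row reordering", {
  traj <- cached_micelle(5, n_agg = 12, n_waters = 200, n_frames = 2)
  topo <- micellar:::hbond_topology(traj$atoms, traj$bonds)
  f <- traj$frames[[1]]
  a <- detect_hbonds(f, topo$water_donors, topo$sur_acceptors)
  perm <- sample(nrow(topo$water_donors))
  b <- detect_hbonds(f, topo$water_donors[perm, ], topo$sur_acceptors)
  expect_equal(a, b)
})

test_that("per-position counts: a constructed permanently-bonded water
           gives exactly one bond at the hydroxyl", {
  rec <- micelle_recipe(n_agg = 4, n_eo = 5, n_waters = 0, n_frames = 3,
                        seed = 2)
  traj <- unwrap_trajectory(build_micelle(rec))
  na <- nrow(traj$atoms)
  oh <- select_atoms(traj$atoms, "OH")
  # append one donating water per hydroxyl O, H on the O-A axis
  props <- atom_properties()
  watoms <- do.call(rbind, lapply(seq_along(oh), function(i)
    data.frame(name = c("OW", "HW1", "HW2"), type = c("OW", "HW", "HW"),
               element = c("O", "H", "H"),
               mass = props$mass[match(c("OW", "HW", "HW"), props$type)],
               vdw = props$vdw[match(c("OW", "HW", "HW"), props$type)],
               role = c("WATER_O", "WATER_H", "WATER_H"),
               class = "SOLVENT", label = NA_character_,
               molid = 4 + i, resname = "SOL", resid = 4 + i,
               stringsAsFactors = FALSE)))
  atoms2 <- rbind(traj$atoms, watoms)
  ho <- select_atoms(traj$atoms, "HO")
  frames2 <- lapply(traj$frames, function(f) {
    wx <- do.call(rbind, lapply(seq_along(oh), function(i) {
      # direction perpendicular to the hydroxyl O-H bond: the planted
      # water accepts nothing (H-D...A angle stays < 90 degrees) and its
      # first hydrogen donates along the axis (D-H...A = 180 degrees)
      d <- f$xyz[ho[i], ] - f$xyz[oh[i], ]
      e <- if (abs(d[1]) / sqrt(sum(d^2)) < 0.9) c(1, 0, 0) else c(0, 1, 0)
      v <- c(d[2] * e[3] - d[3] * e[2], d[3] * e[1] - d[1] * e[3],
             d[1] * e[2] - d[2] * e[1])
      v <- v / sqrt(sum(v^2))
      O <- f$xyz[oh[i], ] + 0.30 * v
      H1 <- f$xyz[oh[i], ] + 0.20 * v    # on the O_w -> OH axis
      H2 <- O + 0.10 * v                 # pointing away from the micelle
      rbind(O, H1, H2)
    }))
    new_frame(rbind(f$xyz, wx), f$box, f$time)
  })
  wbO <- na + 3 * (seq_along(oh) - 1) + 1
  bonds2 <- rbind(traj$bonds, cbind(wbO, wbO + 1), cbind(wbO, wbO + 2))
  storage.mode(bonds2) <- "integer"
  tr2 <- new_trajectory(atoms2, frames2, dt_store = 10, bonds = bonds2)
  counts <- suppressWarnings(
    hbond_counts_per_position(tr2, labels = c("O1", "OH"),
                              window_last = span_ns(tr2)))
  expect_equal(counts$hbonds[counts$label == "OH"], 1.0)
  expect_equal(counts$hbonds[counts$label == "O1"], 0.0)
  # a water-free system has zero everywhere
  c0 <- suppressWarnings(
    hbond_counts_per_position(traj, labels = c("O1", "OH"),
                              window_last = span_ns(traj)))
  expect_equal(c0$hbonds, c(0, 0))
})

test_that("per-position counts sum to the total bond count and trend
           upward toward the micelle surface", {
  traj <- cached_micelle(9)
  w <- span_ns(traj)
  counts <- hbond_counts_per_position(traj, window_last = w)
  topo <- micellar:::hbond_topology(traj$atoms, traj$bonds)
  wf <- window_frames(traj, w)
  total <- 0
  for (i in wf) {
    f <- traj$frames[[i]]
    total <- total +
      nrow(detect_hbonds(f, topo$water_donors, topo$sur_acceptors)) +
      nrow(detect_hbonds(f, topo$sur_donors, topo$water_acceptors))
  }
  # oxygen positions partition every surfactant-water bond (the HO row is
  # the hydrogen's view of the bonds its hydroxyl oxygen donates)
  n_mol <- length(select_atoms(traj$atoms, "OH"))
  o_rows <- grepl("^O", counts$label)
  expect_equal(sum(counts$hbonds[o_rows]) * n_mol * length(wf), total)
  # exchange-surface trend: hydroxyl O accepts more than the link O, and
  # position rank correlates with the count over the ether ladder
  o_idx <- o_rows
  expect_gt(counts$hbonds[counts$label == "OH"],
            counts$hbonds[counts$label == "O1"])
  expect_gt(cor(seq_len(sum(o_idx)), counts$hbonds[o_idx],
                method = "kendall"), 0.3)
})

test_that("C_HB is exactly one at zero lag and flat for permanent bonds", {
  h <- matrix(1, 5, 40)
  cv <- chb_correlation(h, max_lag = 10, dt = 1)
  expect_equal(cv$chb, rep(1, 11))
  expect_error(chb_correlation(matrix(0, 3, 10), dt = 1), "<h>")
})

test_that("independent Bernoulli indicators decay to p immediately", {
  set.seed(19)
  p <- 0.3
  h <- matrix(rbinom(800 * 600, 1, p), 800, 600)
  cv <- chb_correlation(h, max_lag = 5, dt = 1)
  expect_equal(cv$chb[1], 1)
  se <- sqrt(p * (1 - p) / (800 * 590))
  expect_lt(max(abs(cv$chb[-1] - p)), 3 * se / p + 0.01)
})

test_that("two-state Markov kinetics reproduce the master-equation
           correlation curve", {
  rec <- kinetic_recipe(n_pairs = 600, k_off = 2, k_on = 1, dt = 0.1,
                        n_frames = 1500, seed = 11)
  sim <- simulate_hbond_kinetics(rec)
  cv <- chb_correlation(sim$h, max_lag = 3, dt = rec$dt)
  expect_lt(max(abs(cv$chb - sim$analytic(cv$t))), 0.05)
  # monotone non-increasing toward the equilibrium occupancy
  expect_true(all(diff(cv$chb) < 0.02))
  expect_equal(cv$chb[length(cv$chb)], sim$analytic(3), tolerance = 0.1)
})

test_that("decay ordering ranks by area under the curve with stable ties", {
  t <- seq(0, 5, by = 0.1)
  mk <- function(k) structure(list(t = t, chb = exp(-k * t), n_pairs = 1,
                                   mean_h = 0.5), class = "chb_curve")
  r <- decay_ordering(list(slow = mk(1), fast = mk(2)))
  expect_equal(r$label, c("fast", "slow"))
  r3 <- decay_ordering(list(b = mk(4), a = mk(2), c = mk(1)))
  expect_equal(r3$label, c("b", "a", "c"))
  tie <- decay_ordering(list(u = mk(1), v = mk(1)))
  expect_equal(tie$label, c("u", "v"))   # input order breaks the tie
  bad <- mk(1); bad$t <- bad$t + 0.05
  expect_error(decay_ordering(list(x = mk(1), y = bad)), "grid")
})
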