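# Independent oracles and small fixture builders shared across the suite.

# Brute-force O(N^2) accessible-area implementation, independent of the
# package's cell-grid code path: random (seeded) point set instead of the
# Fibonacci lattice, plain R loops for neighbour culling.
brute_sasa <- function(pos, radii, probe, n_points = 960, seed = 42) {
  set.seed(seed)
  v <- matrix(rnorm(3 * n_points), ncol = 3)
  pts <- v / sqrt(rowSums(v^2))
  n <- nrow(pos)
  area <- numeric(n)
  for (i in seq_len(n)) {
    Ri <- radii[i] + probe
    p <- sweep(pts * Ri, 2, pos[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in seq_len(n)) {
      if (j == i) next
      Rj <- radii[j] + probe
      d2 <- rowSums(sweep(p, 2, pos[j, ])^2)
      free <- free & (d2 >= Rj^2)
    }
    area[i] <- 4 * pi * Ri^2 * mean(free)
  }
  area
}

# Brute-force minimum image: nearest periodic copy by exhaustive shift
# enumeration (wide enough to cover deltas spanning several boxes).
brute_min_image <- function(delta, box) {
  shifts <- as.matrix(expand.grid(-4:4, -4:4, -4:4))
  cand <- sweep(shifts %*% diag(box), 2, delta, "+")
  cand[which.min(rowSums(cand^2)), ]
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# Plain point-cloud atom table (unit masses unless given).
cloud_atoms <- function(n, mass = 1, vdw = 0.15, role = "TAIL_C") {
  data.frame(name = paste0("X", seq_len(n)), type = "C", element = "C",
             mass = mass, vdw = vdw, role = role,
             class = role_polarity(role), label = NA_character_,
             molid = seq_len(n), resname = "FIX",
             stringsAsFactors = FALSE)
}

# Single-solute-in-water-bath trajectory: `n_centers` labelled atoms well
# separated on a lattice, plus an ideal-gas water-oxygen bath redrawn per
# frame at the requested density.
bath_trajectory <- function(n_centers = 8, rho = 33, box = 3.2,
                            n_frames = 40, seed = 5) {
  set.seed(seed)
  n_w <- round(rho * box^3)
  grid <- as.matrix(expand.grid(x = c(0.8, 2.4), y = c(0.8, 2.4),
                                z = c(0.8, 2.4)))[seq_len(n_centers), ,
                                                  drop = FALSE]
  sol <- cloud_atoms(n_centers, mass = 12, vdw = 0.17)
  sol$label <- "X"
  wat <- cloud_atoms(n_w, mass = 15.999, vdw = 0.152, role = "WATER_O")
  wat$molid <- n_centers + seq_len(n_w)
  atoms <- rbind(sol, wat)
  frames <- lapply(seq_len(n_frames), function(i)
    new_frame(rbind(grid, matrix(runif(3 * n_w, 0, box), ncol = 3)),
              rep(box, 3), time = (i - 1) * 10))
  new_trajectory(atoms, frames, dt_store = 10)
}

# Full-span window (avoids the short-trajectory fallback warning).
span_ns <- function(traj) {
  times <- vapply(traj$frames, function(f) f$time, 0)
  (times[length(times)] - times[1]) / 1000
}

# One shared desk-scale micelle per template size, built lazily and cached
# for the whole test session (building is the expensive step).
micelle_cache <- new.env()
cached_micelle <- function(n_eo, n_agg = 30, n_waters = 3000,
                           n_frames = 40, f_out = 0.3, seed = 11) {
  key <- paste("m", n_eo, n_agg, n_waters, n_frames, f_out, seed, sep = "_")
  if (is.null(micelle_cache[[key]])) {
    rec <- micelle_recipe(n_agg = n_agg, n_eo = n_eo, f_out = f_out,
                          n_waters = n_waters, n_frames = n_frames,
                          seed = seed)
    micelle_cache[[key]] <- unwrap_trajectory(build_micelle(rec))
  }
  micelle_cache[[key]]
}
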