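# Templates, coordinate I/O, periodic geometry, selection.

test_that("TX templates satisfy their structural invariants", {
  for (n_eo in c(5, 7, 9)) {
    tpl <- tx_template(n_eo)
    a <- tpl$atoms
    expect_equal(nrow(a), 16 + 3 * n_eo)
    expect_equal(sum(a$role == "EO_O"), n_eo)
    expect_equal(sum(a$role == "HYDROXYL_O"), 1)
    expect_equal(sum(a$role == "HYDROXYL_H"), 1)
    # inner->outer position labels: link oxygen first, hydroxyl last
    olab <- a$label[a$role %in% c("EO_O", "HYDROXYL_O")]
    expect_equal(olab, c(paste0("O", seq_len(n_eo)), "OH"))
    # every hydrophilic/hydrophobic assignment follows the role map
    expect_identical(a$class, role_polarity(a$role))
    expect_silent(validate_template(tpl))
  }
  expect_error(role_polarity("NOT_A_ROLE"), "unknown atom role")
})

test_that("shipped template files round-trip to the built-in templates", {
  sizes <- c(tx5 = 5, tx114 = 7, tx100 = 9)
  for (nm in names(sizes)) {
    path <- system.file("extdata", paste0(nm, ".template"),
                        package = "micellar")
    tpl <- read_template(path)
    ref <- tx_template(sizes[[nm]])
    expect_equal(tpl$n_eo, ref$n_eo)
    expect_equal(tpl$atoms$role, ref$atoms$role)
    expect_equal(tpl$atoms$mass, ref$atoms$mass, tolerance = 1e-4)
    expect_equal(tpl$bonds, ref$bonds)
  }
  # write -> read is the identity on the atom table
  tmp <- tempfile(fileext = ".template")
  write_template(tx_template(6), tmp)
  back <- read_template(tmp)
  expect_equal(back$atoms$label, tx_template(6)$atoms$label)
})

test_that("GRO reader echoes a hand-written file and converts PDB to nm", {
  gro <- c("three atoms", "    3",
           sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "SOL",
                   c("OW", "HW1", "HW2"), 1:3,
                   c(1, 1.1, 0.9), 2, 3),
           "   5.00000   5.00000   5.00000")
  tmp <- tempfile(fileext = ".gro")
  writeLines(gro, tmp)
  r <- read_coordinates(tmp, "GRO")
  expect_equal(nrow(r$frame$xyz), 3)
  expect_equal(r$frame$box, c(5, 5, 5))
  expect_equal(r$frame$xyz[1, ], c(1, 2, 3))
  expect_equal(r$atoms$name, c("OW", "HW1", "HW2"))

  # PDB positions are Angstrom on disk, nm in memory
  f <- new_frame(matrix(c(1, 0.5, 0.25), 1), c(5, 5, 5))
  pdb <- tempfile(fileext = ".pdb")
  write_pdb_frame(f, cloud_atoms(1), pdb)
  back <- read_coordinates(pdb, "PDB")
  expect_equal(as.numeric(back$frame$xyz[1, ]), c(1, 0.5, 0.25),
               tolerance = 1e-3)
})

test_that("GRO round trip preserves a 1000-atom frame to format precision", {
  set.seed(2)
  x <- matrix(runif(3000, 0, 6), ncol = 3)
  f <- new_frame(x, c(6, 6, 6), time = 120)
  tmp <- tempfile(fileext = ".gro")
  write_gro(f, cloud_atoms(1000), tmp)
  back <- read_coordinates(tmp, "GRO")
  expect_lt(max(abs(back$frame$xyz - x)), 5e-4)
  expect_equal(back$frame$time, 120)
  # writer emits exactly 3 decimals for positions
  line <- readLines(tmp)[3]
  expect_match(substr(line, 21, 28), "^ *-?[0-9]+\\.[0-9]{3}$")
})

test_that("malformed GRO input fails with the offending line named", {
  ok_line <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1, "SOL", "OW", 1,
                     1, 2, 3)
  bad_line <- sub("   2.000", "     bad", ok_line, fixed = TRUE)
  tmp <- tempfile(fileext = ".gro")
  writeLines(c("t", "    2", ok_line, bad_line, "   5.0 5.0 5.0"), tmp)
  expect_error(read_coordinates(tmp, "GRO"), "line 4")
  writeLines(c("t", "    1", ok_line), tmp)
  expect_error(read_coordinates(tmp, "GRO"), "box")
  writeLines(c("t", "    1", ok_line,
               "  5.0 5.0 5.0 0.0 0.0 0.0 2.0 0.0 0.0"), tmp)
  expect_error(read_coordinates(tmp, "GRO"), "triclinic")
})

test_that("multi-frame GRO trajectories round-trip", {
  atoms <- cloud_atoms(10)
  frames <- lapply(1:4, function(i)
    new_frame(matrix(runif(30, 0, 5), ncol = 3), c(5, 5, 5),
              time = (i - 1) * 10))
  tr <- new_trajectory(atoms, frames, dt_store = 10)
  tmp <- tempfile(fileext = ".gro")
  write_gro_trajectory(tr, tmp)
  back <- read_gro_trajectory(tmp)
  expect_equal(length(back$frames), 4)
  expect_equal(back$dt_store, 10)
  expect_lt(max(abs(back$frames[[3]]$xyz - frames[[3]]$xyz)), 5e-4)
})

test_that("minimum image wraps into [-box/2, box/2) and matches the
           27-image search", {
  expect_equal(minimum_image(c(4.9, 0, 0), c(5, 5, 5)), c(-0.1, 0, 0))
  expect_equal(minimum_image(c(0, 0, 0), c(5, 5, 5)), c(0, 0, 0))
  # half-open convention at the +L/2 edge
  expect_equal(minimum_image(c(2.5, -2.5, 0), c(5, 5, 5)), c(-2.5, -2.5, 0))
  set.seed(9)
  box <- c(4, 5.5, 3)
  for (i in 1:50) {
    d <- runif(3, -12, 12)
    expect_equal(minimum_image(d, box), brute_min_image(d, box),
                 tolerance = 1e-12)
  }
  # minimum-image distance never exceeds the raw distance
  d <- matrix(runif(300, -8, 8), ncol = 3)
  w <- minimum_image(d, box)
  expect_true(all(rowSums(w^2) <= rowSums(d^2) + 1e-12))
})

test_that("centre of mass is the mass-weighted mean", {
  a <- cloud_atoms(2)
  f <- new_frame(rbind(c(0, 0, 0), c(2, 0, 0)), c(10, 10, 10))
  expect_equal(center_of_mass(f, a), c(1, 0, 0))
  a$mass <- c(1, 3)
  f2 <- new_frame(rbind(c(0, 0, 0), c(4, 0, 0)), c(10, 10, 10))
  expect_equal(center_of_mass(f2, a), c(3, 0, 0))
  # high-precision summation oracle on a random configuration
  set.seed(4)
  n <- 500
  a3 <- cloud_atoms(n, mass = runif(n, 1, 20))
  x <- matrix(runif(3 * n, 0, 8), ncol = 3)
  f3 <- new_frame(x, c(20, 20, 20))
  ref <- sapply(1:3, function(k) sum(a3$mass * x[, k]) / sum(a3$mass))
  expect_equal(center_of_mass(f3, a3), ref, tolerance = 1e-12)
  a3$mass <- 0
  expect_error(center_of_mass(f3, a3), "mass")
})

test_that("unwrapping restores a wrapped micelle exactly and is idempotent", {
  traj <- cached_micelle(5, n_agg = 12, n_waters = 200, n_frames = 2)
  f <- traj$frames[[1]]
  mic <- which(traj$atoms$class != "SOLVENT")
  ref <- f$xyz[mic, ]
  # translate so the micelle straddles a corner, then wrap into the box
  g <- f
  g$xyz <- sweep(g$xyz, 2, g$box / 2 + 0.3, "+") %% g$box
  uw <- unwrap_micelle(g, mic, traj$bonds)
  dref <- as.matrix(dist(ref))
  dnew <- as.matrix(dist(uw$xyz[mic, ]))
  expect_lt(max(abs(dref - dnew)), 1e-9)
  # waters untouched, second application exact no-op
  wat <- setdiff(seq_len(nrow(g$xyz)), mic)
  expect_identical(uw$xyz[wat, ], g$xyz[wat, ])
  uw2 <- unwrap_micelle(uw, mic, traj$bonds)
  expect_identical(uw2$xyz, uw$xyz)
  # all micelle bonded pairs whole (waters keep their wrapped positions)
  mb <- traj$bonds[traj$bonds[, 1] %in% mic & traj$bonds[, 2] %in% mic, ]
  bl <- uw$xyz[mb[, 1], ] - uw$xyz[mb[, 2], ]
  expect_lt(max(sqrt(rowSums(bl^2))), min(f$box) / 2)
})

test_that("a two-atom molecule bonded across the boundary is made whole", {
  a <- cloud_atoms(2)
  f <- new_frame(rbind(c(0.1, 1, 1), c(4.9, 1, 1)), c(5, 5, 5))
  uw <- unwrap_micelle(f, 1:2, rbind(c(1L, 2L)))
  expect_lt(sqrt(sum((uw$xyz[1, ] - uw$xyz[2, ])^2)), 2.5)
  # fully interior micelle: unwrap is the identity
  f2 <- new_frame(rbind(c(2, 2, 2), c(2.3, 2, 2)), c(5, 5, 5))
  expect_identical(unwrap_micelle(f2, 1:2, rbind(c(1L, 2L)))$xyz, f2$xyz)
})

test_that("selection is deterministic and partitions non-solvent atoms", {
  traj <- cached_micelle(5, n_agg = 12, n_waters = 200, n_frames = 2)
  atoms <- traj$atoms
  q <- select_atoms(atoms, "QUATERNARY_C")
  expect_length(q, 12)
  hh <- select_atoms(atoms, "HO")
  expect_length(hh, 12)
  expect_true(all(atoms$class[hh] == "HYDROPHILIC"))
  phob <- select_atoms(atoms, "HYDROPHOBIC")
  phil <- select_atoms(atoms, "HYDROPHILIC")
  expect_equal(sort(c(phob, phil)), which(atoms$class != "SOLVENT"))
  expect_equal(length(phob) + length(phil), 12 * nrow(tx_template(5)$atoms))
  expect_error(select_atoms(atoms, "O99"), "valid queries")
})
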