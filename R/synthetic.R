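# Deterministic synthetic inputs: pseudo-TX micelle configurations with
# controllable structure, analytic fixtures with closed-form observables,
# and two-state Markov hydrogen-bond kinetics with a known C_HB(t).
#
# The generator is a structural emulator, not a thermodynamic model: it
# places template-conformant surfactants on jittered radial spokes with a
# controllable exterior-tail fraction, and fills the box with water outside
# a contact envelope. Everything is reproducible bit-for-bit from the seed.

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Micelle construction recipe
#'
#' Study-condition parameters of the synthetic micelle generator. The
#' desk-scale defaults (n_agg 30, 3000 waters, 200 stored frames at 10 ps)
#' exercise every estimator at laptop cost; the reference systems use
#' n_agg 100 in a 10 nm box with ~30,000 waters (set those fields for a
#' full-scale build).
#'
#' @param n_agg aggregation number (surfactants per micelle).
#' @param n_eo oxyethylene units (5/7/9 for the TX-5/TX-114/TX-100
#'   molecules).
#' @param core_radius hydrophobic core radius in nm.
#' @param f_out fraction of surfactants whose tail sits outside the core
#'   (exterior tails), in [0, 1].
#' @param head_disorder per-atom placement jitter scale (nm).
#' @param box cubic box edge (nm); the built micelle must fit in half the
#'   box.
#' @param n_waters number of water molecules.
#' @param n_frames stored frames.
#' @param dt_store frame spacing (ps).
#' @param seed mandatory integer seed; all generation is reproducible.
#' @return object of class \code{micelle_recipe}.
#' @export
micelle_recipe <- function(n_agg = 30, n_eo = 9, core_radius = 0.8,
                           f_out = 0.3, head_disorder = 0.05, box = 9,
                           n_waters = 3000, n_frames = 200, dt_store = 10,
                           seed) {
  if (missing(seed)) stop("a seed is mandatory (reproducible generation)")
  stopifnot(n_agg >= 1, n_eo >= 1, core_radius > 0,
            f_out >= 0, f_out <= 1, box > 0, n_waters >= 0, n_frames >= 1)
  tpl <- tx_template(n_eo)
  r_est <- core_radius + 0.3 + max(tpl$stations) + 0.3
  if (r_est >= min(box) / 2)
    stop(sprintf(paste0("estimated micelle radius %.2f nm does not fit in ",
                        "half the %.1f nm box; use a larger box"),
                 r_est, min(box)))
  structure(list(n_agg = as.integer(n_agg), n_eo = as.integer(n_eo),
                 core_radius = core_radius, f_out = f_out,
                 head_disorder = head_disorder, box = rep(box, 3)[1:3],
                 n_waters = as.integer(n_waters),
                 n_frames = as.integer(n_frames), dt_store = dt_store,
                 seed = as.integer(seed), template = tpl),
            class = "micelle_recipe")
}

rand_unit <- function(n) {
  v <- matrix(rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

# One surfactant along direction u: chain atoms at radial stations r0 + s_i
# with a fixed-magnitude perpendicular offset at per-atom phase angles phi
# (keeps bond lengths near 0.15 nm while advancing ~0.08 nm radially per
# chain atom, without biasing any chain position toward exposure), branch
# methyls splayed off their parent, jitter on every atom.
place_molecule <- function(tpl, u, r0, jitter, phi) {
  st <- tpl$stations
  n <- length(st)
  # perpendicular basis
  p1 <- c(-u[2], u[1], 0)
  if (sum(p1^2) < 1e-12) p1 <- c(1, 0, 0)
  p1 <- p1 / sqrt(sum(p1^2))
  p2 <- c(u[2] * p1[3] - u[3] * p1[2],
          u[3] * p1[1] - u[1] * p1[3],
          u[1] * p1[2] - u[2] * p1[1])
  chain <- tpl$atoms$role %in% c("EO_C", "EO_O", "HYDROXYL_O", "HYDROXYL_H")
  off <- 0.10 * ifelse(chain, 1, 0)
  x <- outer(r0 + st, u) + off * (cos(phi) %o% p1 + sin(phi) %o% p2)
  # splay the five methyls and ring off-axis so atoms do not stack
  meth <- which(tpl$atoms$type == "CH3")
  x[meth, ] <- x[meth, ] + 0.11 * rand_unit(length(meth))
  ring <- which(tpl$atoms$role == "RING_C")
  hex <- 0.12 * c(0, 1, 1, 0, -1, -1)
  x[ring, ] <- x[ring, ] + outer(hex, p2)
  x + jitter * matrix(rnorm(3 * n), ncol = 3)
}

#' Build a synthetic micelle trajectory
#'
#' Places \code{n_agg} template-conformant surfactants on jittered radial
#' spokes around the box centre: a fraction 1 - f_out with the quaternary
#' tail-end carbon inside the core (radius < core_radius), a fraction
#' f_out with the tail in the head-group shell; ethoxylate chains extend
#' outward. Inter-molecular contacts below 0.15 nm are relaxed by random
#' perturbation retries. Waters are placed uniformly in the box outside
#' the micelle contact envelope (0.11 nm surface clearance from every
#' atom's vdW sphere), with hydrogens at the SPC geometry in random
#' orientations. Additional frames add small positional
#' jitter and re-place a few percent of the waters each frame so
#' micelle-water hydrogen bonds exchange.
#'
#' @param recipe a \code{\link{micelle_recipe}}.
#' @return a \code{mic_trajectory} with an annotated atom table and global
#'   bond list; deterministic given the recipe's seed.
#' @export
build_micelle <- function(recipe) {
  stopifnot(inherits(recipe, "micelle_recipe"))
  tpl <- recipe$template
  with_seed(recipe$seed, {
    na <- nrow(tpl$atoms)
    n_mic <- recipe$n_agg * na
    center <- recipe$box / 2
    u <- rand_unit(recipe$n_agg)
    n_out <- round(recipe$f_out * recipe$n_agg)
    is_out <- seq_len(recipe$n_agg) <= n_out
    # spoke directions and tail-end radii are fixed per molecule; the
    # chain conformation phases evolve as a random walk across frames
    # (smooth conformational sampling with a few-frame correlation time)
    r0 <- ifelse(is_out, recipe$core_radius + 0.3,
                 runif(recipe$n_agg, 0.25, 0.65) * recipe$core_radius)
    bonds <- do.call(rbind, lapply(seq_len(recipe$n_agg),
                                   function(m) tpl$bonds + (m - 1) * na))
    molid <- rep(seq_len(recipe$n_agg), each = na)
    phi <- matrix(runif(recipe$n_agg * na, 0, 2 * pi), recipe$n_agg, na)
    mk_micelle <- function() {
      xs <- lapply(seq_len(recipe$n_agg), function(m)
        sweep(place_molecule(tpl, u[m, ], r0[m], recipe$head_disorder,
                             phi[m, ]),
              2, center, "+"))
      do.call(rbind, xs)
    }
    # relax inter-molecular overlaps (< 0.15 nm): push each clashing pair
    # apart along its axis with a small random perturbation on top
    relax <- function(x) {
      for (it in 1:500) {
        pr <- cpp_pairs_within(x, x, recipe$box, 0.15, TRUE)
        inter <- molid[pr$i] != molid[pr$j]
        if (!any(inter)) break
        if (it == 500)
          stop("could not relax atom overlaps; use a larger box or core")
        ii <- pr$i[inter]; jj <- pr$j[inter]; dd <- pr$d[inter]
        dvec <- x[ii, , drop = FALSE] - x[jj, , drop = FALSE]
        nrm <- sqrt(rowSums(dvec^2))
        zero <- nrm < 1e-9
        if (any(zero)) {
          dvec[zero, ] <- rand_unit(sum(zero))
          nrm[zero] <- 1
        }
        push <- dvec / nrm * (0.16 - dd) / 2 +
          0.005 * matrix(rnorm(3 * length(ii)), ncol = 3)
        for (k in seq_along(ii)) {
          x[ii[k], ] <- x[ii[k], ] + push[k, ]
          x[jj[k], ] <- x[jj[k], ] - push[k, ]
        }
      }
      x
    }
    x <- relax(mk_micelle())
    # water placement: uniform outside the micelle contact envelope (a
    # water oxygen keeps a surface clearance of 0.11 nm from every atom's
    # vdW sphere, so polar oxygens are approached closer than CHn),
    # thinned so no two water oxygens sit closer than 0.25 nm
    vdw_mic <- rep(tpl$atoms$vdw, recipe$n_agg)
    wO <- matrix(numeric(0), ncol = 3)
    while (nrow(wO) < recipe$n_waters) {
      cand <- matrix(runif(3 * 2 * (recipe$n_waters - nrow(wO) + 50)),
                     ncol = 3) %*% diag(recipe$box)
      ok <- cpp_min_clearance(cand, x, recipe$box, vdw_mic) >= 0.11
      cand <- cand[ok, , drop = FALSE]
      if (nrow(wO)) {
        ok2 <- cpp_min_dist(cand, wO, recipe$box) >= 0.25
        cand <- cand[ok2, , drop = FALSE]
      }
      for (r in 1:5) {  # thin within the candidate batch itself
        pr <- cpp_pairs_within(cand, cand, recipe$box, 0.25, TRUE)
        if (!length(pr$i)) break
        cand <- cand[-unique(pr$j), , drop = FALSE]
      }
      wO <- rbind(wO, cand)
    }
    wO <- wO[seq_len(recipe$n_waters), , drop = FALSE]
    # SPC geometry: O-H 0.1 nm, H-O-H 109.47 degrees, random orientation
    hoh <- 109.47 * pi / 180
    a1 <- rand_unit(recipe$n_waters)
    perp <- rand_unit(recipe$n_waters)
    perp <- perp - a1 * rowSums(perp * a1)
    perp <- perp / sqrt(rowSums(perp^2))
    a2 <- a1 * cos(hoh) + perp * sin(hoh)
    h1 <- wO + 0.1 * a1
    h2 <- wO + 0.1 * a2
    wxyz <- matrix(0, nrow = 3 * recipe$n_waters, ncol = 3)
    wxyz[seq(1, by = 3, length.out = recipe$n_waters), ] <- wO
    wxyz[seq(2, by = 3, length.out = recipe$n_waters), ] <- h1
    wxyz[seq(3, by = 3, length.out = recipe$n_waters), ] <- h2
    props <- atom_properties()
    wat <- if (recipe$n_waters == 0) {
      w0 <- tpl$atoms[0, ]
      w0$molid <- integer(0)
      w0
    } else data.frame(
      name = rep(c("OW", "HW1", "HW2"), recipe$n_waters),
      type = rep(c("OW", "HW", "HW"), recipe$n_waters),
      element = rep(c("O", "H", "H"), recipe$n_waters),
      mass = rep(props$mass[match(c("OW", "HW", "HW"), props$type)],
                 recipe$n_waters),
      vdw = rep(props$vdw[match(c("OW", "HW", "HW"), props$type)],
                recipe$n_waters),
      role = rep(c("WATER_O", "WATER_H", "WATER_H"), recipe$n_waters),
      class = "SOLVENT", label = NA_character_,
      stringsAsFactors = FALSE)
    wat$molid <- recipe$n_agg + rep(seq_len(recipe$n_waters), each = 3)
    sur <- tpl$atoms[rep(seq_len(na), recipe$n_agg), ]
    sur$molid <- molid
    sur$resname <- tpl$resname
    wat$resname <- rep("SOL", nrow(wat))
    atoms <- rbind(sur, wat)
    atoms$resid <- atoms$molid
    rownames(atoms) <- NULL
    wbO <- n_mic + 3 * (seq_len(recipe$n_waters) - 1) + 1
    wbonds <- rbind(cbind(wbO, wbO + 1), cbind(wbO, wbO + 2))
    allb <- rbind(bonds, wbonds)
    storage.mode(allb) <- "integer"
    frames <- vector("list", recipe$n_frames)
    wprev <- wxyz
    for (fi in seq_len(recipe$n_frames)) {
      if (fi > 1)
        phi <- phi + 0.8 * matrix(rnorm(recipe$n_agg * na),
                                  recipe$n_agg, na)
      xmic <- if (fi == 1) x else relax(mk_micelle())
      wf <- wprev
      if (recipe$n_waters > 0 && fi > 1) {
        # diffusive rigid step per water + exchange a few percent to
        # fresh positions outside the contact envelope
        wj <- 0.08 * matrix(rnorm(3 * recipe$n_waters), ncol = 3)
        wf <- wf + wj[rep(seq_len(recipe$n_waters), each = 3), ]
        orows <- seq(1, by = 3, length.out = recipe$n_waters)
        sunk <- which(cpp_min_clearance(wf[orows, , drop = FALSE], xmic,
                                        recipe$box, vdw_mic) < 0.06)
        swap <- union(sunk,
                      sample.int(recipe$n_waters,
                                 max(1L, round(0.03 * recipe$n_waters))))
        nswap <- length(swap)
        repeat {
          newO <- matrix(runif(3 * nswap), ncol = 3) %*% diag(recipe$box)
          bad <- cpp_min_clearance(newO, xmic, recipe$box, vdw_mic) < 0.11
          if (!any(bad)) break
          newO[bad, ] <- matrix(runif(3 * sum(bad)), ncol = 3) %*%
            diag(recipe$box)
        }
        for (s in seq_along(swap)) {
          rowsw <- 3 * (swap[s] - 1) + 1:3
          shift <- newO[s, ] - wf[rowsw[1], ]
          wf[rowsw, ] <- sweep(wf[rowsw, ], 2, shift, "+")
        }
        wprev <- wf
      }
      frames[[fi]] <- new_frame(rbind(xmic, wf), recipe$box,
                                time = (fi - 1) * recipe$dt_store)
    }
    traj <- new_trajectory(atoms, frames, dt_store = recipe$dt_store,
                           bonds = allb)
    traj$recipe <- recipe
    traj
  })
}

#' Analytic fixtures with closed-form observables
#'
#' Small configurations whose target observable is known exactly, for
#' self-checking tests:
#' \describe{
#'   \item{sphere_cloud}{\code{n} unit-mass points uniform in a solid
#'     sphere of radius \code{R}; expected Rg = sqrt(3/5) R.}
#'   \item{shell}{points uniform on a sphere of radius \code{R}.}
#'   \item{octahedron}{six unit masses at +/- \code{a} on the axes;
#'     expected coordinate moments (4a^2, 4a^2, 4a^2), e = 0, ratio = 1.}
#'   \item{two_atom_sasa}{two atoms of radius \code{r} at distance
#'     \code{d}; expected area from the spherical-cap closed form.}
#'   \item{ideal_gas_bath}{\code{n} water oxygens uniform in the box
#'     (ideal gas); expected in-range count within a cutoff rc is
#'     (4/3) pi rc^3 rho.}
#' }
#'
#' @param kind one of "sphere_cloud", "shell", "octahedron",
#'   "two_atom_sasa", "ideal_gas_bath".
#' @param R,a,r,d,probe,n,box,seed kind-specific parameters (lengths nm).
#' @return list with \code{frame}, \code{atoms} and \code{expected} (named
#'   list of closed-form values).
#' @export
analytic_fixture <- function(kind = c("sphere_cloud", "shell", "octahedron",
                                      "two_atom_sasa", "ideal_gas_bath"),
                             R = 2, a = 1, r = 0.15, d = 0.29,
                             probe = 0.14, n = 1000, box = NULL, seed = 1) {
  kind <- match.arg(kind)
  mk_atoms <- function(k, type = "C", role = "TAIL_C") {
    props <- atom_properties()
    pi_ <- match(type, props$type)
    data.frame(name = paste0("X", seq_len(k)), type = type,
               element = props$element[pi_], mass = 1,
               vdw = props$vdw[pi_], role = role,
               class = role_polarity(role), label = NA_character_,
               molid = seq_len(k), resname = "FIX",
               stringsAsFactors = FALSE)
  }
  if (kind == "sphere_cloud" || kind == "shell") {
    x <- with_seed(seed, {
      v <- rand_unit(n)
      rad <- if (kind == "shell") R else R * runif(n)^(1 / 3)
      v * rad
    })
    if (is.null(box)) box <- rep(4 * R + 1, 3)
    return(list(frame = new_frame(sweep(x, 2, box / 2, "+"), box),
                atoms = mk_atoms(n),
                expected = list(rg = if (kind == "shell") R else
                  sqrt(3 / 5) * R)))
  }
  if (kind == "octahedron") {
    x <- rbind(c(a, 0, 0), c(-a, 0, 0), c(0, a, 0), c(0, -a, 0),
               c(0, 0, a), c(0, 0, -a))
    if (is.null(box)) box <- rep(8 * a, 3)
    return(list(frame = new_frame(sweep(x, 2, box / 2, "+"), box),
                atoms = mk_atoms(6),
                expected = list(moments = rep(4 * a^2, 3), ratio = 1,
                                e = 0)))
  }
  if (kind == "two_atom_sasa") {
    Rp <- r + probe
    iso <- 4 * pi * Rp^2
    expected <- if (d >= 2 * Rp) 2 * iso else {
      h <- Rp - d / 2
      2 * (iso - 2 * pi * Rp * h)
    }
    if (is.null(box)) box <- rep(10 * Rp, 3)
    x <- rbind(c(-d / 2, 0, 0), c(d / 2, 0, 0))
    atoms <- mk_atoms(2)
    atoms$vdw <- r
    return(list(frame = new_frame(sweep(x, 2, box / 2, "+"), box),
                atoms = atoms,
                expected = list(area = expected, isolated = iso,
                                probe = probe)))
  }
  # ideal_gas_bath
  if (is.null(box)) box <- rep(3, 3)
  x <- with_seed(seed, matrix(runif(3 * n), ncol = 3) %*% diag(box))
  atoms <- mk_atoms(n, type = "OW", role = "WATER_O")
  atoms$mass <- 15.999
  list(frame = new_frame(x, box), atoms = atoms,
       expected = list(rho = n / prod(box),
                       count_within = function(rc)
                         4 / 3 * pi * rc^3 * n / prod(box)))
}

#' Two-state hydrogen-bond kinetics recipe
#'
#' @param n_pairs number of independent donor-acceptor pairs.
#' @param k_off bond-breaking rate (1/ps).
#' @param k_on bond-reforming rate (1/ps).
#' @param dt frame spacing (ps).
#' @param n_frames stored frames.
#' @param seed mandatory seed.
#' @return object of class \code{kinetic_recipe}.
#' @export
kinetic_recipe <- function(n_pairs = 2000, k_off = 1, k_on = 1, dt = 0.25,
                           n_frames = 5000, seed) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(k_off >= 0, k_on >= 0, dt > 0, n_pairs >= 1, n_frames >= 2)
  if (k_on == 0 && k_off == 0)
    stop("k_on and k_off cannot both be zero")
  structure(list(n_pairs = as.integer(n_pairs), k_off = k_off, k_on = k_on,
                 dt = dt, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)), class = "kinetic_recipe")
}

#' Simulate two-state hydrogen-bond indicator kinetics
#'
#' Independent two-state Markov chains per pair, sampled at the exact
#' discrete-time transition probabilities of the continuous-time process
#' (rates k_off, k_on) and initialised at the equilibrium occupancy
#' k_on / (k_on + k_off). The analytic intermittent correlation is
#' C(t) = (k_on + k_off exp(-(k_on + k_off) t)) / (k_on + k_off).
#'
#' @param recipe a \code{\link{kinetic_recipe}}.
#' @return list with \code{h} (pairs x frames 0/1 matrix), \code{times},
#'   \code{analytic} (function of t in ps), \code{p_eq}.
#' @export
simulate_hbond_kinetics <- function(recipe) {
  stopifnot(inherits(recipe, "kinetic_recipe"))
  ktot <- recipe$k_on + recipe$k_off
  p_eq <- if (ktot > 0) recipe$k_on / ktot else 1
  decay <- exp(-ktot * recipe$dt)
  p10 <- (recipe$k_off / ktot) * (1 - decay)   # bonded -> broken per step
  p01 <- (recipe$k_on / ktot) * (1 - decay)    # broken -> bonded per step
  with_seed(recipe$seed, {
    h <- matrix(0, recipe$n_pairs, recipe$n_frames)
    h[, 1] <- as.numeric(runif(recipe$n_pairs) < p_eq)
    for (t in 2:recipe$n_frames) {
      u <- runif(recipe$n_pairs)
      h[, t] <- ifelse(h[, t - 1] == 1, as.numeric(u >= p10),
                       as.numeric(u < p01))
    }
    list(h = h, times = (seq_len(recipe$n_frames) - 1) * recipe$dt,
         analytic = function(t)
           (recipe$k_on + recipe$k_off * exp(-ktot * t)) / ktot,
         p_eq = p_eq)
  })
}
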