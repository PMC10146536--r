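# Hydrogen-bond detection (geometric criterion), per-position counts, and
# the intermittent hydrogen-bond time correlation function C_HB(t).

#' Geometric hydrogen-bond criterion
#'
#' A donor-hydrogen-acceptor triple is bonded when the donor-acceptor
#' distance is within \code{distance} (default 0.35 nm, i.e. 3.5 Angstrom)
#' and the angle condition holds. The default convention, \code{dha_min},
#' accepts triples whose D-H...A angle (at the hydrogen) is at least
#' \code{angle} degrees (default 120: straighter bonds are stronger). The
#' alternative \code{hda_max} convention accepts triples whose H-D-A angle
#' (at the donor) is at most \code{angle} degrees (set e.g. 30 for the
#' GROMACS-style criterion).
#'
#' @param distance donor-acceptor cutoff in nm.
#' @param angle angle threshold in degrees.
#' @param convention "dha_min" (default) or "hda_max".
#' @return object of class \code{hbond_criterion}.
#' @export
hbond_criterion <- function(distance = 0.35, angle = 120,
                            convention = c("dha_min", "hda_max")) {
  convention <- match.arg(convention)
  if (distance <= 0) stop("distance cutoff must be positive")
  if (angle <= 0 || angle > 180) stop("angle must lie in (0, 180]")
  structure(list(distance = distance, angle = angle,
                 convention = convention), class = "hbond_criterion")
}

# Donor/acceptor bookkeeping from a template-annotated atom table + bonds:
# surfactant ether oxygens are acceptor-only, the terminal hydroxyl is both
# donor and acceptor, waters donate through both hydrogens and accept
# through the oxygen. Water-water bonds are never formed here.
hbond_topology <- function(atoms, bonds) {
  h_of <- function(o_idx) {
    vapply(o_idx, function(o) {
      nb <- c(bonds[bonds[, 1] == o, 2], bonds[bonds[, 2] == o, 1])
      h <- nb[atoms$role[nb] %in% c("HYDROXYL_H", "WATER_H")]
      if (!length(h))
        stop("donor atom ", o, " (", atoms$name[o],
             ") has no bonded hydrogen in the template")
      as.integer(h[1])
    }, integer(1))
  }
  ho <- which(atoms$role == "HYDROXYL_O")
  wo <- which(atoms$role == "WATER_O")
  sur_donors <- if (length(ho)) cbind(D = ho, H = h_of(ho)) else
    cbind(D = integer(0), H = integer(0))
  water_donors <- NULL
  if (length(wo)) {
    dh <- lapply(wo, function(o) {
      nb <- c(bonds[bonds[, 1] == o, 2], bonds[bonds[, 2] == o, 1])
      h <- nb[atoms$role[nb] == "WATER_H"]
      cbind(D = rep(o, length(h)), H = h)
    })
    water_donors <- do.call(rbind, dh)
  } else water_donors <- cbind(D = integer(0), H = integer(0))
  list(sur_acceptors = which(atoms$role %in% c("EO_O", "HYDROXYL_O")),
       sur_donors = sur_donors,
       water_acceptors = wo,
       water_donors = water_donors)
}

hbond_angle_ok <- function(xyz, box, D, H, A, criterion) {
  if (criterion$convention == "dha_min") {
    v1 <- minimum_image(xyz[D, , drop = FALSE] - xyz[H, , drop = FALSE], box)
    v2 <- minimum_image(xyz[A, , drop = FALSE] - xyz[H, , drop = FALSE], box)
    thr <- function(a) a >= criterion$angle
  } else {
    v1 <- minimum_image(xyz[H, , drop = FALSE] - xyz[D, , drop = FALSE], box)
    v2 <- minimum_image(xyz[A, , drop = FALSE] - xyz[D, , drop = FALSE], box)
    thr <- function(a) a <= criterion$angle
  }
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  thr(ang)
}

#' Detect hydrogen bonds in one frame
#'
#' Applies the geometric criterion to every donor-hydrogen pair against
#' every acceptor under minimum-image geometry and returns the bonded
#' (donor, hydrogen, acceptor) triples. The bonded set is invariant under
#' reordering of the input pairs.
#'
#' @param frame a \code{mic_frame}.
#' @param donors 2-column matrix of (donor heavy atom, bonded hydrogen)
#'   index pairs.
#' @param acceptors acceptor atom indices.
#' @param criterion an \code{\link{hbond_criterion}}.
#' @return data.frame with columns donor, hydrogen, acceptor.
#' @export
detect_hbonds <- function(frame, donors, acceptors,
                          criterion = hbond_criterion()) {
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0))
  if (!nrow(donors) || !length(acceptors)) return(empty)
  du <- unique(donors[, 1])
  pr <- cpp_pairs_within(frame$xyz[du, , drop = FALSE],
                         frame$xyz[acceptors, , drop = FALSE],
                         frame$box, criterion$distance, FALSE)
  if (!length(pr$i)) return(empty)
  Dc <- du[pr$i]; Ac <- acceptors[pr$j]
  # expand over the hydrogens of each candidate donor
  hmap <- split(donors[, 2], donors[, 1])
  nh <- lengths(hmap[as.character(Dc)])
  D <- rep(Dc, nh); A <- rep(Ac, nh)
  H <- unlist(hmap[as.character(Dc)], use.names = FALSE)
  keep <- D != A
  D <- D[keep]; H <- H[keep]; A <- A[keep]
  if (!length(D)) return(empty)
  ok <- hbond_angle_ok(frame$xyz, frame$box, D, H, A, criterion)
  out <- data.frame(donor = D[ok], hydrogen = H[ok], acceptor = A[ok])
  out[order(out$donor, out$hydrogen, out$acceptor), , drop = FALSE]
}

#' Mean hydrogen-bond count per surfactant position
#'
#' For oxygen position labels, counts water-donated bonds accepted at that
#' position (plus, for the hydroxyl oxygen, bonds it donates to water);
#' for the hydroxyl hydrogen label, bonds donated through that hydrogen.
#' Averaged over window frames and surfactant molecules.
#'
#' @param traj an unwrapped \code{mic_trajectory} with bonds.
#' @param labels position labels (default: all ether oxygens, the hydroxyl
#'   oxygen and hydrogen, in template order).
#' @param criterion an \code{\link{hbond_criterion}}.
#' @param window_last analysis window in ns.
#' @return data.frame with label and mean bonds per molecule per frame.
#' @export
hbond_counts_per_position <- function(traj, labels = NULL,
                                      criterion = hbond_criterion(),
                                      window_last = 30) {
  atoms <- traj$atoms
  if (is.null(labels)) {
    lab <- atoms$label[atoms$role %in% c("EO_O", "HYDROXYL_O", "HYDROXYL_H")]
    labels <- unique(lab[!is.na(lab)])
  }
  topo <- hbond_topology(atoms, traj$bonds)
  wf <- window_frames(traj, window_last)
  tot <- setNames(numeric(length(labels)), labels)
  n_mol <- vapply(labels, function(l) length(select_atoms(atoms, l)), 0)
  for (i in wf) {
    f <- traj$frames[[i]]
    acc <- detect_hbonds(f, topo$water_donors, topo$sur_acceptors, criterion)
    don <- detect_hbonds(f, topo$sur_donors, topo$water_acceptors, criterion)
    for (l in labels) {
      sel <- select_atoms(atoms, l)
      role <- atoms$role[sel[1]]
      cnt <- if (role == "HYDROXYL_H")
        sum(don$hydrogen %in% sel)
      else
        sum(acc$acceptor %in% sel) +
          (if (role == "HYDROXYL_O") sum(don$donor %in% sel) else 0)
      tot[l] <- tot[l] + cnt
    }
  }
  data.frame(label = labels,
             hbonds = as.numeric(tot) / (n_mol * length(wf)),
             row.names = NULL)
}

#' Hydrogen-bond indicator records over a window
#'
#' Detects surfactant-water hydrogen bonds (both donation directions) in
#' every window frame and assembles the binary indicator series h(t) for
#' every (donor, hydrogen, acceptor) triple bonded in at least one frame.
#'
#' @inheritParams hbond_counts_per_position
#' @param acceptor_subset optional surfactant acceptor indices to restrict
#'   to (e.g. one oxygen position); \code{donor_subset} likewise restricts
#'   surfactant donor hydrogens.
#' @param donor_subset see above.
#' @return object of class \code{hbond_records}: list with \code{h}
#'   (pairs x frames 0/1 matrix), \code{triples}, \code{times} (ps).
#' @export
hbond_records <- function(traj, criterion = hbond_criterion(),
                          window_last = 30, acceptor_subset = NULL,
                          donor_subset = NULL) {
  atoms <- traj$atoms
  topo <- hbond_topology(atoms, traj$bonds)
  if (!is.null(acceptor_subset))
    topo$sur_acceptors <- intersect(topo$sur_acceptors, acceptor_subset)
  if (!is.null(donor_subset)) {
    keep <- topo$sur_donors[, "H"] %in% donor_subset
    topo$sur_donors <- topo$sur_donors[keep, , drop = FALSE]
  }
  wf <- window_frames(traj, window_last)
  keysets <- vector("list", length(wf))
  for (k in seq_along(wf)) {
    f <- traj$frames[[wf[k]]]
    acc <- detect_hbonds(f, topo$water_donors, topo$sur_acceptors, criterion)
    don <- detect_hbonds(f, topo$sur_donors, topo$water_acceptors, criterion)
    all <- rbind(acc, don)
    keysets[[k]] <- paste(all$donor, all$hydrogen, all$acceptor)
  }
  keys <- sort(unique(unlist(keysets)))
  if (!length(keys)) stop("no hydrogen bonds found in the analysis window")
  h <- matrix(0, nrow = length(keys), ncol = length(wf),
              dimnames = list(keys, NULL))
  for (k in seq_along(wf))
    h[match(keysets[[k]], keys), k] <- 1
  tr <- do.call(rbind, strsplit(keys, " "))
  structure(list(h = h,
                 triples = data.frame(donor = as.integer(tr[, 1]),
                                      hydrogen = as.integer(tr[, 2]),
                                      acceptor = as.integer(tr[, 3])),
                 times = vapply(wf, function(i) traj$frames[[i]]$time, 0)),
            class = "hbond_records")
}

#' Intermittent hydrogen-bond time correlation function
#'
#' C_HB(t) = <h(t0 + t) h(t0)> / <h>, averaged over (strided) time origins
#' t0 and over the pair population (all triples bonded at least once in the
#' window). Bonds may break and reform within the lag; for binary
#' indicators C_HB(0) = 1 exactly and the long-time limit of an
#' equilibrated population is the mean occupancy <h>.
#'
#' @param records an \code{hbond_records}, or a plain 0/1 matrix
#'   (pairs x frames).
#' @param max_lag maximum lag in ps (default: half the window).
#' @param origin_stride origin spacing in frames (default 1: every frame).
#' @param dt frame spacing in ps (taken from the records when present).
#' @return object of class \code{chb_curve}: data.frame-like list with
#'   \code{t} (ps), \code{chb}, \code{n_pairs}, \code{mean_h}.
#' @export
chb_correlation <- function(records, max_lag = NULL, origin_stride = 1,
                            dt = NULL) {
  if (inherits(records, "hbond_records")) {
    h <- records$h
    if (is.null(dt)) dt <- diff(records$times[1:2])
  } else {
    h <- records
    if (is.null(dt)) dt <- 1
  }
  storage.mode(h) <- "double"
  mh <- mean(h)
  if (mh == 0) stop("no bonds in window: <h> = 0")
  nt <- ncol(h)
  if (is.null(max_lag)) max_lag <- floor((nt - 1) / 2) * dt
  lags <- 0:min(nt - 1, floor(max_lag / dt))
  raw <- cpp_lag_corr(h, as.integer(lags), as.integer(origin_stride))
  structure(list(t = lags * dt, chb = raw / mh,
                 n_pairs = nrow(h), mean_h = mh), class = "chb_curve")
}

#' @export
print.chb_curve <- function(x, ...) {
  cat(sprintf("C_HB(t): %d pairs, <h> = %.3f, t = 0..%g ps, C(end) = %.3f\n",
              x$n_pairs, x$mean_h, max(x$t), x$chb[length(x$chb)]))
  invisible(x)
}

#' Rank hydrogen-bond correlation curves by decay speed
#'
#' Ranks curves by the trapezoidal area under C_HB(t) up to \code{t_max};
#' a smaller area means faster decay. Curves must share the lag grid; ties
#' are broken deterministically by input (label) order.
#'
#' @param curves named list of \code{chb_curve}s.
#' @param t_max integration limit in ps (default: full shared grid).
#' @return data.frame with label, area and rank (1 = fastest), ordered
#'   fastest first.
#' @export
decay_ordering <- function(curves, t_max = NULL) {
  stopifnot(length(curves) >= 1)
  t0 <- curves[[1]]$t
  for (cv in curves)
    if (!isTRUE(all.equal(cv$t, t0)))
      stop("curves do not share a common lag grid")
  if (is.null(t_max)) t_max <- max(t0)
  keep <- t0 <= t_max
  area <- vapply(curves, function(cv) {
    tt <- cv$t[keep]; y <- cv$chb[keep]
    sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
  }, 0)
  ord <- order(area, seq_along(area))
  data.frame(label = names(curves)[ord], area = as.numeric(area[ord]),
             rank = seq_along(ord), row.names = NULL)
}
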