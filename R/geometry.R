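# Periodic-boundary geometry: minimum image, micelle unwrapping, centre of
# mass, and atom-group selection.

#' Minimum-image displacement
#'
#' Wraps each displacement component into [-box/2, box/2); distances built
#' from the result are minimum-image distances over all periodic copies.
#'
#' @param delta length-3 vector or N x 3 matrix of displacements (nm).
#' @param box length-3 positive orthorhombic box (nm).
#' @return object of the same shape as \code{delta}.
#' @export
minimum_image <- function(delta, box) {
  box <- as.numeric(box)
  if (any(box <= 0)) stop("box components must be positive")
  if (is.matrix(delta)) {
    for (k in 1:3) delta[, k] <- delta[, k] -
        box[k] * floor(delta[, k] / box[k] + 0.5)
    delta
  } else {
    delta - box * floor(delta / box + 0.5)
  }
}

#' Centre of mass of an atom group
#'
#' Mass-weighted mean position. The group is assumed unwrapped (no periodic
#' splits); see \code{\link{unwrap_micelle}}.
#'
#' @param frame a \code{mic_frame}.
#' @param atoms atom table carrying a \code{mass} column.
#' @param group integer vector of atom indices (default: all atoms).
#' @return length-3 position (nm).
#' @export
center_of_mass <- function(frame, atoms, group = seq_len(nrow(atoms))) {
  if (!length(group)) stop("empty atom group")
  m <- atoms$mass[group]
  M <- sum(m)
  if (!is.finite(M) || M <= 0) stop("zero or invalid total mass")
  colSums(frame$xyz[group, , drop = FALSE] * m) / M
}

#' Select atoms by role, polarity class, or position label
#'
#' Deterministic sorted selection on a template-annotated atom table. A
#' query naming a role (e.g. \code{QUATERNARY_C}), a polarity class
#' (\code{HYDROPHOBIC}, \code{HYDROPHILIC}, \code{SOLVENT}) or a template
#' position label (e.g. \code{O1}, \code{OH}) is accepted; per-position
#' queries return one atom per surfactant molecule.
#'
#' @param atoms annotated atom table.
#' @param query single character query.
#' @return sorted integer vector of atom indices.
#' @export
select_atoms <- function(atoms, query) {
  stopifnot(is.character(query), length(query) == 1)
  if (query %in% atom_roles()) {
    idx <- which(atoms$role == query)
  } else if (query %in% c("HYDROPHOBIC", "HYDROPHILIC", "SOLVENT")) {
    idx <- which(atoms$class == query)
  } else if (!is.null(atoms$label) && query %in% atoms$label) {
    idx <- which(!is.na(atoms$label) & atoms$label == query)
  } else {
    valid <- c(atom_roles(), "HYDROPHOBIC", "HYDROPHILIC", "SOLVENT",
               sort(unique(atoms$label[!is.na(atoms$label)])))
    stop("unknown selection '", query, "'; valid queries: ",
         paste(valid, collapse = ", "))
  }
  if (!length(idx)) stop("selection '", query, "' matched no atoms")
  sort(idx)
}

micelle_indices <- function(atoms) which(atoms$class != "SOLVENT")

#' Unwrap a micelle across periodic boundaries
#'
#' Makes every bonded pair whole under the minimum-image convention
#' (molecule-wise graph walk), then gathers whole molecules so the micelle
#' is a single compact cluster. Water positions are untouched. Idempotent:
#' applying it to an already-whole micelle returns identical coordinates.
#'
#' @param frame a \code{mic_frame}.
#' @param micelle_atoms indices of the micelle (non-solvent) atoms.
#' @param bonds 2-column matrix of global bonded index pairs (micelle only).
#' @return a \code{mic_frame} with unwrapped micelle coordinates.
#' @export
unwrap_micelle <- function(frame, micelle_atoms, bonds) {
  x <- frame$xyz; box <- frame$box
  mset <- sort(micelle_atoms)
  keep <- bonds[, 1] %in% mset & bonds[, 2] %in% mset
  bonds <- bonds[keep, , drop = FALSE]
  # adjacency lists over micelle atoms
  adj <- vector("list", nrow(x))
  for (r in seq_len(nrow(bonds))) {
    a <- bonds[r, 1]; b <- bonds[r, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  visited <- rep(TRUE, nrow(x)); visited[mset] <- FALSE
  comps <- list()
  for (root in mset) {
    if (visited[root]) next
    comp <- integer(0); queue <- root; visited[root] <- TRUE
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]; comp <- c(comp, a)
      for (b in adj[[a]]) if (!visited[b]) {
        x[b, ] <- x[a, ] + minimum_image(x[b, ] - x[a, ], box)
        visited[b] <- TRUE; queue <- c(queue, b)
      }
    }
    comps[[length(comps) + 1]] <- comp
  }
  # gather molecules about the toroidal (circular-mean) cluster centre:
  # valid whenever the micelle radius is below half the box edge
  cms <- t(vapply(comps, function(comp)
    colMeans(x[comp, , drop = FALSE]), numeric(3)))
  theta <- sweep(cms, 2, box / (2 * pi), "/")
  ctr <- atan2(colMeans(sin(theta)), colMeans(cos(theta))) * box / (2 * pi)
  for (k in seq_along(comps)) {
    shift <- minimum_image(cms[k, ] - ctr, box) - (cms[k, ] - ctr)
    if (any(shift != 0))
      x[comps[[k]], ] <- sweep(x[comps[[k]], , drop = FALSE], 2, shift, "+")
  }
  rad <- apply(abs(sweep(x[mset, , drop = FALSE], 2,
                         colMeans(x[mset, , drop = FALSE]))), 2, max)
  if (any(rad >= box / 2))
    stop("micelle radius (", paste(signif(rad, 3), collapse = ", "),
         " nm per axis) reaches half the box; use a larger box")
  out <- frame; out$xyz <- x
  out
}

#' Unwrap every frame of a trajectory
#'
#' @param traj a \code{mic_trajectory} carrying \code{bonds}.
#' @return the trajectory with each frame's micelle unwrapped.
#' @export
unwrap_trajectory <- function(traj) {
  if (is.null(traj$bonds)) stop("trajectory carries no bond list")
  mic <- micelle_indices(traj$atoms)
  traj$frames <- lapply(traj$frames, unwrap_micelle,
                        micelle_atoms = mic, bonds = traj$bonds)
  traj
}

#' Analysis-window frame indices
#'
#' Selects the trailing portion of a trajectory for equilibrium averaging:
#' the last \code{window_last} ns by default. When the trajectory is
#' shorter than the requested window, the last 15 percent of frames is
#' used and a warning is issued.
#'
#' @param traj a \code{mic_trajectory}.
#' @param window_last window length in ns (default 30).
#' @return integer vector of frame indices.
#' @export
window_frames <- function(traj, window_last = 30) {
  times <- vapply(traj$frames, function(f) f$time, 0)
  span <- times[length(times)] - times[1]
  w_ps <- window_last * 1000
  if (span < w_ps) {
    # short trajectory: fall back to the last 15 percent, but keep at
    # least 5 frames so block averaging stays defined
    n <- min(length(times), max(5L, as.integer(ceiling(0.15 * length(times)))))
    warning(sprintf(paste0("trajectory span (%.3g ns) shorter than the ",
                           "%g ns window; using the last %d frames"),
                    span / 1000, window_last, n))
    return(seq.int(length(times) - n + 1L, length(times)))
  }
  which(times >= times[length(times)] - w_ps)
}
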