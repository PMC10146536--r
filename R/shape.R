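# Micelle size and shape: radius of gyration, moments of inertia,
# Imax/Imin, eccentricity, average micelle radius, block-averaged windows.

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance from the group centre of mass:
#' Rg^2 = sum(m_i |r_i - r_com|^2) / sum(m_i). The group must be unwrapped.
#'
#' @param frame a \code{mic_frame}.
#' @param atoms atom table with masses.
#' @param group atom indices (default all).
#' @param mass_weighted use masses (default) or unit weights.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(frame, atoms, group = seq_len(nrow(atoms)),
                               mass_weighted = TRUE) {
  if (!length(group)) stop("empty atom group")
  m <- if (mass_weighted) atoms$mass[group] else rep(1, length(group))
  com <- colSums(frame$xyz[group, , drop = FALSE] * m) / sum(m)
  d2 <- rowSums(sweep(frame$xyz[group, , drop = FALSE], 2, com)^2)
  sqrt(sum(m * d2) / sum(m))
}

#' Moments of inertia about the centre of mass
#'
#' COORDINATE mode returns the moments about the COM-centred x, y, z axes
#' (I_x = sum m_i (dy^2 + dz^2) etc.), the convention used to form
#' Imax/Imin and the eccentricity; PRINCIPAL mode returns the inertia
#' tensor eigenvalues. Values are labelled, not sorted.
#'
#' @inheritParams radius_of_gyration
#' @param axes "coordinate" (default) or "principal".
#' @return named length-3 numeric (amu nm^2).
#' @export
inertia_moments <- function(frame, atoms, group = seq_len(nrow(atoms)),
                            axes = c("coordinate", "principal")) {
  axes <- match.arg(axes)
  if (!length(group)) stop("empty atom group")
  m <- atoms$mass[group]
  x <- frame$xyz[group, , drop = FALSE]
  com <- colSums(x * m) / sum(m)
  d <- sweep(x, 2, com)
  if (axes == "coordinate") {
    return(c(Ix = sum(m * (d[, 2]^2 + d[, 3]^2)),
             Iy = sum(m * (d[, 1]^2 + d[, 3]^2)),
             Iz = sum(m * (d[, 1]^2 + d[, 2]^2))))
  }
  r2 <- rowSums(d^2)
  I <- diag(sum(m * r2), 3) - t(d) %*% (d * m)
  ev <- eigen(I, symmetric = TRUE, only.values = TRUE)$values
  c(I1 = ev[1], I2 = ev[2], I3 = ev[3])
}

#' Shape ratio and eccentricity from three moments
#'
#' Imax/Imin = max/min of the three moments; eccentricity
#' e = 1 - Imin/Iavg. Both are 1 resp. 0 for a perfectly spherical mass
#' distribution.
#'
#' @param moments length-3 positive numeric.
#' @return list with \code{ratio} and \code{e}.
#' @export
shape_descriptors <- function(moments) {
  moments <- as.numeric(moments)
  if (length(moments) != 3 || any(!is.finite(moments)) || any(moments <= 0))
    stop("need three positive moments (degenerate collinear configuration?)")
  list(ratio = max(moments) / min(moments),
       e = 1 - min(moments) / mean(moments))
}

#' Average micelle radius from Rg
#'
#' Rs = sqrt(5/3) Rg, the radius of the uniform-density sphere with the
#' same radius of gyration.
#'
#' @param rg radius of gyration (nm), non-negative.
#' @return Rs in nm.
#' @export
average_radius <- function(rg) {
  if (any(rg < 0)) stop("Rg must be non-negative")
  sqrt(5 / 3) * rg
}

#' Block-averaged mean and standard error
#'
#' Mean of a (correlated) per-frame series with an uncertainty from block
#' averaging: the series is cut into \code{n_blocks} contiguous blocks and
#' the uncertainty is the standard error of the block means.
#'
#' @param x numeric series.
#' @param n_blocks number of blocks (default 5); requires
#'   \code{length(x) >= n_blocks >= 2}.
#' @return list with \code{mean}, \code{se}, \code{n_blocks},
#'   \code{block_means}.
#' @export
window_statistics <- function(x, n_blocks = 5) {
  n <- length(x)
  if (n_blocks < 2 || n < n_blocks)
    stop("need length(x) >= n_blocks >= 2")
  cuts <- floor(seq(0, n, length.out = n_blocks + 1))
  bm <- vapply(seq_len(n_blocks),
               function(b) mean(x[(cuts[b] + 1):cuts[b + 1]]), 0)
  list(mean = mean(x), se = sd(bm) / sqrt(n_blocks),
       n_blocks = n_blocks, block_means = bm)
}

#' Per-frame and window-averaged shape metrics
#'
#' Computes Rg, the three coordinate-axis (or principal) moments,
#' Imax/Imin, eccentricity and Rs for every window frame, then block
#' averages each series.
#'
#' @param traj an unwrapped \code{mic_trajectory}.
#' @param group atom indices (default: all non-solvent atoms).
#' @param window_last analysis window in ns (see
#'   \code{\link{window_frames}}).
#' @param axes moment convention, "coordinate" (default) or "principal".
#' @param n_blocks blocks for the uncertainty estimate.
#' @return object of class \code{shape_result}: list with \code{series}
#'   (data.frame per frame: time, rg, rs, I1..I3, ratio, e) and
#'   \code{summary} (data.frame of mean/se per metric), plus the axes mode.
#' @export
shape_series <- function(traj, group = NULL, window_last = 30,
                         axes = "coordinate", n_blocks = 5) {
  if (is.null(group)) group <- micelle_indices(traj$atoms)
  wf <- window_frames(traj, window_last)
  rows <- lapply(wf, function(i) {
    f <- traj$frames[[i]]
    rg <- radius_of_gyration(f, traj$atoms, group)
    mom <- inertia_moments(f, traj$atoms, group, axes = axes)
    sh <- shape_descriptors(mom)
    data.frame(time = f$time, rg = rg, rs = average_radius(rg),
               I1 = mom[1], I2 = mom[2], I3 = mom[3],
               ratio = sh$ratio, e = sh$e)
  })
  series <- do.call(rbind, rows)
  rownames(series) <- NULL
  met <- c("rg", "rs", "ratio", "e", "I1", "I2", "I3")
  summ <- do.call(rbind, lapply(met, function(mn) {
    ws <- window_statistics(series[[mn]], n_blocks)
    data.frame(metric = mn, mean = ws$mean, se = ws$se)
  }))
  structure(list(series = series, summary = summ, axes = axes,
                 n_blocks = n_blocks), class = "shape_result")
}

#' @export
print.shape_result <- function(x, ...) {
  cat(sprintf("shape metrics (%s axes, %d frames, %d blocks):\n",
              x$axes, nrow(x$series), x$n_blocks))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-6s %10.4f +/- %.4f\n", s$metric[i], s$mean[i], s$se[i]))
  invisible(x)
}
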