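# Solvation structure: radial probability profiles about the micelle COM,
# radial distribution functions, and cutoff hydration numbers.

#' Radial probability profiles relative to the micelle centre of mass
#'
#' Histograms the COM distances of each named atom group, pooled over the
#' window frames and group members, and normalises each profile to unit
#' integral (P(r) in 1/nm, sum(P) * bin_width = 1). The micelle COM is
#' recomputed per frame from \code{reference}; the trajectory must be
#' unwrapped.
#'
#' @param traj an unwrapped \code{mic_trajectory}.
#' @param groups named list of atom-index vectors.
#' @param reference atom indices defining the COM (default: all
#'   non-solvent atoms).
#' @param bin_width histogram bin width in nm (default 0.02).
#' @param r_max histogram range (default: data-driven).
#' @param window_last analysis window in ns.
#' @return object of class \code{radial_profile}: list with \code{r} (bin
#'   midpoints), \code{edges}, \code{P} (matrix, one column per group) and
#'   \code{counts}.
#' @export
radial_profile <- function(traj, groups, reference = NULL, bin_width = 0.02,
                           r_max = NULL, window_last = 30) {
  if (bin_width <= 0) stop("bin width must be positive")
  if (is.null(reference)) reference <- micelle_indices(traj$atoms)
  wf <- window_frames(traj, window_last)
  dists <- lapply(groups, function(g) numeric(0))
  for (i in wf) {
    f <- traj$frames[[i]]
    com <- center_of_mass(f, traj$atoms, reference)
    for (gn in names(groups)) {
      d <- sqrt(rowSums(sweep(f$xyz[groups[[gn]], , drop = FALSE],
                              2, com)^2))
      dists[[gn]] <- c(dists[[gn]], d)
    }
  }
  if (is.null(r_max))
    r_max <- bin_width * ceiling(max(unlist(dists), 1e-9) / bin_width + 1)
  edges <- seq(0, r_max, by = bin_width)
  nb <- length(edges) - 1
  counts <- sapply(names(groups), function(gn) {
    k <- pmin(nb, floor(dists[[gn]] / bin_width) + 1)
    tabulate(k, nbins = nb)
  })
  P <- sweep(counts, 2, colSums(counts) * bin_width, "/")
  structure(list(r = edges[-1] - bin_width / 2, edges = edges,
                 P = P, counts = counts, bin_width = bin_width),
            class = "radial_profile")
}

#' Count the modes of a radial profile
#'
#' Discrete peak count on a smoothed profile: local maxima above a height
#' floor (fraction of the global maximum) after a centred moving-average
#' smooth. Used to assert multimodality of, e.g., the tail-carbon profile.
#'
#' @param p numeric profile values (one group's P(r)).
#' @param floor_frac minimum peak height relative to the maximum.
#' @param smooth half-width (bins) of the moving average.
#' @return number of modes.
#' @export
count_modes <- function(p, floor_frac = 0.1, smooth = 2) {
  k <- 2 * smooth + 1
  ps <- stats::filter(c(rep(p[1], smooth), p, rep(p[length(p)], smooth)),
                      rep(1 / k, k))
  ps <- as.numeric(ps)[smooth + seq_along(p)]
  n <- length(ps); thr <- floor_frac * max(ps)
  peaks <- 0
  for (i in seq_len(n)) {
    l <- if (i == 1) -Inf else ps[i - 1]
    r <- if (i == n) -Inf else ps[i + 1]
    if (ps[i] > thr && ps[i] > l && ps[i] >= r) peaks <- peaks + 1
  }
  peaks
}

#' Radial distribution function g(r)
#'
#' Standard pair-distribution normalisation with minimum-image distances:
#' shell counts divided by (n_centers x n_frames) and by the ideal-gas
#' shell expectation rho * V_shell, with rho the box density of the
#' around-group. Self pairs (zero distance) are excluded.
#'
#' @param traj a \code{mic_trajectory}.
#' @param center_group,around_group atom index vectors.
#' @param r_max maximum distance (nm); must not exceed half the smallest
#'   box edge.
#' @param bin_width bin width in nm (default 0.02).
#' @param window_last analysis window in ns.
#' @return object of class \code{rdf_curve}: list with \code{r}, \code{g},
#'   \code{counts}, \code{rho}, \code{n_centers}, \code{n_frames}.
#' @export
rdf <- function(traj, center_group, around_group, r_max, bin_width = 0.02,
                window_last = 30) {
  box <- traj$frames[[1]]$box
  if (r_max > min(box) / 2)
    stop("r_max exceeds half the smallest box edge")
  wf <- window_frames(traj, window_last)
  nb <- ceiling(r_max / bin_width)
  counts <- numeric(nb)
  for (i in wf) {
    f <- traj$frames[[i]]
    counts <- counts + cpp_dist_hist(
      f$xyz[center_group, , drop = FALSE],
      f$xyz[around_group, , drop = FALSE],
      f$box, nb * bin_width, nb)
  }
  edges <- seq(0, nb * bin_width, by = bin_width)
  vshell <- 4 / 3 * pi * diff(edges^3)
  rho <- length(around_group) / prod(box)
  g <- counts / (length(center_group) * length(wf)) / (vshell * rho)
  structure(list(r = edges[-1] - bin_width / 2, g = g, counts = counts,
                 rho = rho, n_centers = length(center_group),
                 n_frames = length(wf), bin_width = bin_width),
            class = "rdf_curve")
}

#' Hydration number of a labelled atom position
#'
#' Mean number of water oxygens within \code{cutoff} (default 0.35 nm) of
#' the atom at a template position label, averaged over window frames and
#' surfactant molecules. The cutoff interval is half-open [0, cutoff):
#' a water exactly at the cutoff is excluded. The "rdf" method evaluates
#' the same quantity as the discretised RDF integral
#' n(rc) = 4 pi rho int g(r) r^2 dr with shell-volume discretisation.
#'
#' @param traj a \code{mic_trajectory} (unwrapped; water oxygens are the
#'   water reference sites).
#' @param position_label template position label (e.g. "O1", "OH") or any
#'   selection accepted by \code{\link{select_atoms}}.
#' @param cutoff counting radius in nm.
#' @param method "count" (direct, default) or "rdf" (integral route).
#' @param window_last analysis window in ns.
#' @param n_blocks blocks for the uncertainty (over per-frame means).
#' @return list with \code{mean}, \code{se}, \code{cutoff}, \code{method}.
#' @export
hydration_number <- function(traj, position_label, cutoff = 0.35,
                             method = c("count", "rdf"), window_last = 30,
                             n_blocks = 5) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("cutoff must be positive")
  centers <- select_atoms(traj$atoms, position_label)
  waters <- select_atoms(traj$atoms, "WATER_O")
  wf <- window_frames(traj, window_last)
  if (method == "rdf") {
    nb <- 70L
    bw <- cutoff / nb
    g <- rdf(traj, centers, waters, r_max = cutoff, bin_width = bw,
             window_last = window_last)
    edges <- seq(0, cutoff, by = bw)
    n_rc <- g$rho * sum(g$g * 4 / 3 * pi * diff(edges^3))
    return(list(mean = n_rc, se = NA_real_, cutoff = cutoff,
                method = "rdf"))
  }
  per_frame <- vapply(wf, function(i) {
    f <- traj$frames[[i]]
    mean(cpp_count_within(f$xyz[centers, , drop = FALSE],
                          f$xyz[waters, , drop = FALSE],
                          f$box, cutoff, FALSE))
  }, 0)
  ws <- if (length(per_frame) >= n_blocks)
    window_statistics(per_frame, n_blocks)
  else list(mean = mean(per_frame), se = NA_real_)
  list(mean = ws$mean, se = ws$se, cutoff = cutoff, method = "count")
}

#' Hydration numbers for a set of position labels
#'
#' Applies \code{\link{hydration_number}} to each label (inner to outer as
#' given) and returns a table, the per-position hydration analysis of a
#' TX-n surfactant.
#'
#' @inheritParams hydration_number
#' @param labels character vector of position labels; default: the tail
#'   carbons, ring carbon, every ether oxygen, the hydroxyl O and H of the
#'   bound template (taken from the atom table's labels, file order).
#' @return data.frame with label, hydration mean and se.
#' @export
hydration_profile <- function(traj, labels = NULL, cutoff = 0.35,
                              window_last = 30, n_blocks = 5) {
  if (is.null(labels)) {
    lab <- traj$atoms$label
    labels <- unique(lab[!is.na(lab)])
  }
  rows <- lapply(labels, function(l) {
    h <- hydration_number(traj, l, cutoff, "count", window_last, n_blocks)
    data.frame(label = l, hydration = h$mean, se = h$se)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
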