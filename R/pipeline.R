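# End-to-end orchestration: generate/ingest -> unwrap -> window -> shape +
# SASA + profiles + hydration + hydrogen bonds -> report files.

fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(deparse(x), collapse = "")))
  h <- 2166136261
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline: the input (a trajectory file or
#' a synthetic recipe), the equilibrium window, block count, SASA
#' settings, profile binning, hydration cutoff and hydrogen-bond
#' criterion.
#'
#' @param recipe a \code{\link{micelle_recipe}} (generated input), or NULL.
#' @param input path to a concatenated-GRO trajectory (ingested input), or
#'   NULL. Exactly one of recipe/input must be given.
#' @param template template used to annotate ingested input.
#' @param window_last equilibrium window in ns (default 30; short
#'   trajectories fall back to the last 15 percent with a warning).
#' @param n_blocks blocks for uncertainties (default 5).
#' @param sasa_probe SASA probe radius in nm (default 0.14).
#' @param sasa_n_points SASA points per atom (default 960).
#' @param bin_width radial profile/RDF bin width in nm (default 0.02).
#' @param hydration_cutoff hydration counting radius in nm (default 0.35).
#' @param criterion an \code{\link{hbond_criterion}}.
#' @param max_lag C_HB lag range in ps (default: half the window).
#' @param outdir output directory (NULL: no files written).
#' @param seed seed recorded in the provenance block.
#' @return object of class \code{analysis_config}.
#' @export
analysis_config <- function(recipe = NULL, input = NULL, template = NULL,
                            window_last = 30, n_blocks = 5,
                            sasa_probe = 0.14, sasa_n_points = 960,
                            bin_width = 0.02, hydration_cutoff = 0.35,
                            criterion = hbond_criterion(), max_lag = NULL,
                            outdir = NULL, seed = 1) {
  if (is.null(recipe) == is.null(input))
    stop("exactly one of recipe / input must be given")
  stopifnot(window_last > 0, n_blocks >= 2, sasa_probe > 0,
            bin_width > 0, hydration_cutoff > 0)
  structure(list(recipe = recipe, input = input, template = template,
                 window_last = window_last, n_blocks = n_blocks,
                 sasa_probe = sasa_probe, sasa_n_points = sasa_n_points,
                 bin_width = bin_width,
                 hydration_cutoff = hydration_cutoff,
                 criterion = criterion, max_lag = max_lag,
                 outdir = outdir, seed = seed),
            class = "analysis_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full micelle analysis pipeline
#'
#' Generates (or reads) the trajectory, unwraps the micelle in every
#' frame, selects the equilibrium window, and computes: shape metrics
#' (Rg, Rs, Imax/Imin, eccentricity), total/hydrophilic/hydrophobic SASA,
#' radial probability profiles of the tail-end carbon and oxygen
#' positions, per-position hydration numbers, per-position hydrogen-bond
#' counts, and intermittent hydrogen-bond correlation curves for the
#' innermost ether oxygen, the terminal hydroxyl oxygen and the hydroxyl
#' hydrogen, ranked by decay speed. Every summary mean carries a
#' block-averaging uncertainty; the report embeds a provenance block
#' (config hash, seed, package version).
#'
#' @param config an \code{\link{analysis_config}}.
#' @return object of class \code{micelle_report}: list with
#'   \code{summary} (Rg/Rs/ratio/e/SASA rows, mean and se),
#'   \code{hydration}, \code{hbonds}, \code{profiles}, \code{chb}
#'   (named list of curves), \code{decay}, \code{provenance}. When
#'   \code{config$outdir} is set, delimited-text tables and a structured
#'   JSON summary are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  traj <- pipeline_stage("input", {
    if (!is.null(config$recipe)) build_micelle(config$recipe) else {
      tr <- read_gro_trajectory(config$input)
      tr$atoms <- annotate_system(tr$atoms, config$template)
      tr
    }
  })
  traj <- pipeline_stage("unwrap", unwrap_trajectory(traj))
  atoms <- traj$atoms
  wl <- config$window_last

  shape <- pipeline_stage("shape",
    suppressWarnings(shape_series(traj, window_last = wl,
                                  n_blocks = config$n_blocks)))
  sasa <- pipeline_stage("sasa",
    suppressWarnings(sasa_series(traj, probe_radius = config$sasa_probe,
                                 n_points = config$sasa_n_points,
                                 window_last = wl,
                                 n_blocks = config$n_blocks)))

  olabels <- atoms$label[atoms$role %in% c("EO_O", "HYDROXYL_O")]
  olabels <- unique(olabels[!is.na(olabels)])
  pgroups <- c(list(C2 = select_atoms(atoms, "C2")),
               lapply(setNames(olabels, olabels),
                      function(l) select_atoms(atoms, l)))
  profiles <- pipeline_stage("profiles",
    suppressWarnings(radial_profile(traj, pgroups,
                                    bin_width = config$bin_width,
                                    window_last = wl)))
  hydration <- pipeline_stage("hydration",
    suppressWarnings(hydration_profile(traj,
                                       cutoff = config$hydration_cutoff,
                                       window_last = wl,
                                       n_blocks = config$n_blocks)))
  hbonds <- pipeline_stage("hbonds",
    suppressWarnings(hbond_counts_per_position(traj,
                                               criterion = config$criterion,
                                               window_last = wl)))
  chb <- pipeline_stage("chb", {
    inner <- select_atoms(atoms, "O1")
    oh <- select_atoms(atoms, "OH")
    hoh <- select_atoms(atoms, "HO")
    curves <- list()
    mk <- function(acc = NULL, don = NULL)
      tryCatch(chb_correlation(
        suppressWarnings(hbond_records(traj, config$criterion, wl,
                                       acceptor_subset = acc,
                                       donor_subset = don)),
        max_lag = config$max_lag),
        error = function(e) NULL)
    curves$O1 <- mk(acc = inner)
    curves$OH <- mk(acc = oh)
    curves$HO <- mk(don = hoh)
    curves[!vapply(curves, is.null, TRUE)]
  })
  decay <- if (length(chb) >= 2) decay_ordering(chb) else NULL

  summary <- rbind(
    shape$summary[shape$summary$metric %in% c("ratio", "e", "rg", "rs"), ],
    within(sasa$summary, metric <- paste0("sasa_", metric)))
  rownames(summary) <- NULL
  provenance <- list(config_hash = fnv1a(config[setdiff(names(config),
                                                        "outdir")]),
                     seed = config$seed,
                     package = as.character(utils::packageVersion("micellar")),
                     n_frames = n_frames(traj),
                     n_atoms = nrow(atoms))
  report <- structure(list(summary = summary, hydration = hydration,
                           hbonds = hbonds, profiles = profiles, chb = chb,
                           decay = decay, provenance = provenance),
                      class = "micelle_report")
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

#' @export
print.micelle_report <- function(x, ...) {
  cat("micelle structure report (config", x$provenance$config_hash, ")\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-16s %10.4f +/- %.4f\n", s$metric[i], s$mean[i],
                s$se[i]))
  cat("  hydration:", paste(sprintf("%s=%.2f", x$hydration$label,
                                    x$hydration$hydration),
                            collapse = " "), "\n")
  if (!is.null(x$decay))
    cat("  C_HB decay (fastest first):",
        paste(x$decay$label, collapse = " > "), "\n")
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(report$summary, "summary.tsv")
  wt(report$hydration, "hydration.tsv")
  wt(report$hbonds, "hbonds.tsv")
  prof <- data.frame(r = report$profiles$r, report$profiles$P,
                     check.names = FALSE)
  wt(prof, "profiles.tsv")
  if (length(report$chb)) {
    cc <- data.frame(t = report$chb[[1]]$t,
                     sapply(report$chb, function(cv) cv$chb))
    wt(cc, "chb.tsv")
  }
  json <- list(summary = report$summary, hydration = report$hydration,
               hbonds = report$hbonds, provenance = report$provenance)
  jsonlite::write_json(json, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' Equilibration traces of Rg and SASA
#'
#' Per-frame radius of gyration and total SASA over the whole trajectory
#' (not only the analysis window), for equilibration inspection.
#'
#' @param traj an unwrapped \code{mic_trajectory}.
#' @param group micelle atom indices (default non-solvent).
#' @param sasa_n_points SASA point count (default 240; traces favour
#'   speed over area precision).
#' @param sasa_probe probe radius (nm).
#' @return data.frame with time, rg, sasa (one row per frame).
#' @export
equilibration_trace <- function(traj, group = NULL, sasa_n_points = 240,
                                sasa_probe = 0.14) {
  if (is.null(group)) group <- micelle_indices(traj$atoms)
  rows <- lapply(seq_len(n_frames(traj)), function(i) {
    f <- traj$frames[[i]]
    data.frame(time = f$time,
               rg = radius_of_gyration(f, traj$atoms, group),
               sasa = compute_sasa(f, traj$atoms, group, sasa_probe,
                                   sasa_n_points)$total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export a coordinate file with highlighted atom classes
#'
#' Writes a GRO file in which atoms of the requested roles or labels carry
#' a distinct residue name (HL1, HL2, ...), so external viewers can pick
#' out e.g. the tail-end quaternary carbons and outermost hydroxyl
#' oxygens; an empty highlight set writes a plain copy. Highlighted groups
#' are recoverable from the file by residue-name selection.
#'
#' @param frame a \code{mic_frame}.
#' @param atoms annotated atom table.
#' @param highlight character vector of roles/labels to flag.
#' @param path output path.
#' @return the path, invisibly; the mapping highlight -> residue name as
#'   attribute \code{"tags"}.
#' @export
export_highlighted_structure <- function(frame, atoms,
                                         highlight = c("QUATERNARY_C",
                                                       "HYDROXYL_O"),
                                         path) {
  a <- atoms
  tags <- character(0)
  for (k in seq_along(highlight)) {
    idx <- select_atoms(atoms, highlight[k])
    tag <- sprintf("HL%d", k)
    a$resname[idx] <- tag
    tags[highlight[k]] <- tag
  }
  write_gro(frame, a, path)
  invisible(structure(path, tags = tags))
}
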