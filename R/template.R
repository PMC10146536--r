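# Molecular templates for TX-n surfactants and the atom-property tables.

#' Atom roles and polarity classes
#'
#' Role vocabulary for surfactant/water atoms and the fixed mapping from
#' role to polarity class: ether and hydroxyl oxygens (and the hydroxyl
#' hydrogen) are hydrophilic, all carbons and aliphatic hydrogens are
#' hydrophobic, water atoms are solvent.
#'
#' @return \code{atom_roles()} returns the character vector of valid roles;
#'   \code{role_polarity(role)} returns the polarity class for each role.
#' @export
atom_roles <- function() {
  c("TAIL_C", "QUATERNARY_C", "RING_C", "EO_C", "EO_O",
    "HYDROXYL_O", "HYDROXYL_H", "ALIPHATIC_H", "WATER_O", "WATER_H")
}

#' @rdname atom_roles
#' @param role character vector of roles.
#' @export
role_polarity <- function(role) {
  map <- c(TAIL_C = "HYDROPHOBIC", QUATERNARY_C = "HYDROPHOBIC",
           RING_C = "HYDROPHOBIC", EO_C = "HYDROPHOBIC",
           ALIPHATIC_H = "HYDROPHOBIC",
           EO_O = "HYDROPHILIC", HYDROXYL_O = "HYDROPHILIC",
           HYDROXYL_H = "HYDROPHILIC",
           WATER_O = "SOLVENT", WATER_H = "SOLVENT")
  bad <- setdiff(role, names(map))
  if (length(bad))
    stop("unknown atom role(s): ", paste(bad, collapse = ", "))
  unname(map[role])
}

#' Atom property table (masses and van der Waals radii)
#'
#' Standard atomic masses (amu) and Bondi van der Waals radii (nm) keyed by
#' atom type. United-atom CHn types carry inflated radii following the
#' GROMOS united-atom convention. The table carries a \code{version}
#' attribute; results are reproducible bit-for-bit against a stated version.
#'
#' @return data.frame with columns \code{type}, \code{element}, \code{mass},
#'   \code{vdw} (nm).
#' @export
atom_properties <- function() {
  tab <- data.frame(
    type    = c("CH3", "CH2", "CH1", "C", "CR1", "O", "OA", "H", "OW", "HW"),
    element = c("C",   "C",   "C",   "C", "C",   "O", "O",  "H", "O",  "H"),
    mass    = c(15.035, 14.027, 13.019, 12.011, 13.019,
                15.999, 15.999, 1.008, 15.999, 1.008),
    vdw     = c(0.200, 0.200, 0.200, 0.170, 0.190,
                0.152, 0.152, 0.120, 0.152, 0.120),
    stringsAsFactors = FALSE)
  attr(tab, "version") <- "micellar-atom-properties-1"
  tab
}

tx_resname <- function(n_eo) {
  switch(as.character(n_eo), "5" = "TX5", "7" = "TX114", "9" = "TX100",
         paste0("TX", n_eo))
}

#' Built-in TX-n surfactant template
#'
#' Declarative united-atom description of one Triton X molecule with
#' \code{n_eo} oxyethylene units: a tert-octyl tail (terminal quaternary
#' carbon used to track the tail end), a benzene ring, a
#' poly(ethylene oxide) chain and a terminal hydroxyl. Aliphatic hydrogens
#' are implicit (united-atom); the hydroxyl hydrogen and water hydrogens are
#' explicit.
#'
#' Position labels run inner to outer: tail carbons \code{C1}-\code{C4}
#' (\code{C2} is the quaternary tail-end carbon), ring carbon \code{CR},
#' ether oxygens \code{O1} (the phenol-linking oxygen, innermost) through
#' \code{O<n_eo>}, terminal hydroxyl oxygen \code{OH} and hydrogen
#' \code{HO}. Per-position selections resolve to exactly one atom per
#' molecule.
#'
#' @param n_eo number of oxyethylene units; 5, 7 and 9 give the TX-5,
#'   TX-114 and TX-100 molecules (any n_eo >= 1 is accepted).
#' @return object of class \code{tx_template}: list with \code{n_eo},
#'   \code{resname}, \code{atoms} (name, type, element, mass, vdw, role,
#'   class, label), \code{bonds} (2-column matrix of within-molecule
#'   1-based index pairs) and \code{stations} (radial build coordinates used
#'   by the synthetic generator, nm).
#' @export
tx_template <- function(n_eo = 9) {
  stopifnot(is.numeric(n_eo), length(n_eo) == 1, n_eo >= 1,
            n_eo == round(n_eo))
  n_eo <- as.integer(n_eo)

  nm <- character(0); ty <- character(0); rl <- character(0)
  lb <- character(0); st <- numeric(0)
  add <- function(name, type, role, label = NA_character_, station = 0) {
    nm <<- c(nm, name); ty <<- c(ty, type); rl <<- c(rl, role)
    lb <<- c(lb, label); st <<- c(st, station)
  }
  # tert-octyl tail, tail end (quaternary C) innermost
  add("CM1", "CH3", "TAIL_C", "C1", -0.12)
  add("CM2", "CH3", "TAIL_C", NA, -0.12)
  add("CM3", "CH3", "TAIL_C", NA, -0.12)
  add("CQ",  "C",   "QUATERNARY_C", "C2", 0.00)
  add("CB",  "CH2", "TAIL_C", "C3", 0.14)
  add("CG",  "C",   "TAIL_C", "C4", 0.28)
  add("CM4", "CH3", "TAIL_C", NA, 0.24)
  add("CM5", "CH3", "TAIL_C", NA, 0.24)
  # benzene ring, CR1 bonded to CG, CR4 (para) bonded to the linking oxygen
  ring_center <- 0.53
  ring_st <- ring_center + 0.14 * c(-1, -0.5, 0.5, 1, 0.5, -0.5)
  for (k in 1:6)
    add(paste0("CR", k), "CR1", "RING_C",
        if (k == 1) "CR" else NA_character_, ring_st[k])
  # PEO chain: link O1, then n_eo CH2-CH2-O repeats; last O is the hydroxyl
  s <- 0.81
  add("O1", "OA", "EO_O", "O1", s)
  for (u in seq_len(n_eo)) {
    s <- s + 0.08; add(sprintf("CA%d", u), "CH2", "EO_C", NA, s)
    s <- s + 0.08; add(sprintf("CB%d", u), "CH2", "EO_C", NA, s)
    s <- s + 0.08
    if (u < n_eo) add(sprintf("O%d", u + 1), "OA", "EO_O",
                      sprintf("O%d", u + 1), s)
    else add("OH", "OA", "HYDROXYL_O", "OH", s)
  }
  add("HO", "H", "HYDROXYL_H", "HO", s + 0.08)

  props <- atom_properties()
  pi_ <- match(ty, props$type)
  atoms <- data.frame(name = nm, type = ty, element = props$element[pi_],
                      mass = props$mass[pi_], vdw = props$vdw[pi_],
                      role = rl, class = role_polarity(rl),
                      label = lb, stringsAsFactors = FALSE)

  bonds <- rbind(c(1, 4), c(2, 4), c(3, 4), c(4, 5), c(5, 6),
                 c(6, 7), c(6, 8), c(6, 9),
                 c(9, 10), c(10, 11), c(11, 12), c(12, 13), c(13, 14),
                 c(14, 9), c(12, 15))
  chain <- 15:nrow(atoms)          # O1 ... OH, HO are sequential
  bonds <- rbind(bonds, cbind(chain[-length(chain)], chain[-1]))
  storage.mode(bonds) <- "integer"

  out <- list(n_eo = n_eo, resname = tx_resname(n_eo), atoms = atoms,
              bonds = bonds, stations = st)
  class(out) <- "tx_template"
  validate_template(out)
  out
}

#' Validate a surfactant template
#'
#' Checks the structural invariants: positive masses and radii, exactly one
#' hydroxyl O and H, exactly n_eo ether oxygens (the phenol link included),
#' the role-to-polarity mapping, and a connected bond graph.
#'
#' @param tpl a \code{tx_template}.
#' @return the template, invisibly; errors on violation.
#' @export
validate_template <- function(tpl) {
  a <- tpl$atoms
  stopifnot(all(a$mass > 0), all(a$vdw > 0))
  if (sum(a$role == "HYDROXYL_O") != 1 || sum(a$role == "HYDROXYL_H") != 1)
    stop("template must have exactly one hydroxyl O and one hydroxyl H")
  if (sum(a$role == "EO_O") != tpl$n_eo)
    stop("template must have exactly n_eo ether (EO) oxygens")
  if (!identical(a$class, role_polarity(a$role)))
    stop("polarity classes inconsistent with roles")
  # connectivity by repeated neighbour expansion
  n <- nrow(a)
  seen <- logical(n); seen[1] <- TRUE
  repeat {
    grow <- seen[tpl$bonds[, 1]] | seen[tpl$bonds[, 2]]
    new <- seen
    new[tpl$bonds[grow, 1]] <- TRUE
    new[tpl$bonds[grow, 2]] <- TRUE
    if (identical(new, seen)) break
    seen <- new
  }
  if (!all(seen)) stop("template bond graph is not connected")
  invisible(tpl)
}

#' Read and write template files
#'
#' Declarative text format for surfactant templates: a key-value header
#' (\code{n_eo}, \code{resname}) followed by an atom table and a bond list.
#' \code{write_template} emits it; \code{read_template} parses it and
#' validates the result.
#'
#' @param tpl a \code{tx_template}.
#' @param path file path.
#' @return \code{read_template} returns a validated \code{tx_template}.
#' @export
write_template <- function(tpl, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("n_eo %d", tpl$n_eo),
               sprintf("resname %s", tpl$resname), "[atoms]"), con)
  a <- tpl$atoms
  writeLines(sprintf("%s %s %s %.4f %.4f %s %s %.3f", a$name, a$type,
                     a$element, a$mass, a$vdw, a$role,
                     ifelse(is.na(a$label), ".", a$label),
                     tpl$stations), con)
  writeLines("[bonds]", con)
  writeLines(sprintf("%d %d", tpl$bonds[, 1], tpl$bonds[, 2]), con)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  ia <- which(ln == "[atoms]"); ib <- which(ln == "[bonds]")
  if (!length(ia) || !length(ib))
    stop("template file missing [atoms] or [bonds] section: ", path)
  hdr <- ln[seq_len(ia - 1)]
  kv <- strsplit(hdr, "\\s+")
  keys <- vapply(kv, `[`, "", 1); vals <- vapply(kv, `[`, "", 2)
  n_eo <- as.integer(vals[keys == "n_eo"])
  at <- do.call(rbind, strsplit(ln[(ia + 1):(ib - 1)], "\\s+"))
  atoms <- data.frame(name = at[, 1], type = at[, 2], element = at[, 3],
                      mass = as.numeric(at[, 4]), vdw = as.numeric(at[, 5]),
                      role = at[, 6],
                      label = ifelse(at[, 7] == ".", NA_character_, at[, 7]),
                      stringsAsFactors = FALSE)
  atoms$class <- role_polarity(atoms$role)
  atoms <- atoms[, c("name", "type", "element", "mass", "vdw", "role",
                     "class", "label")]
  bd <- do.call(rbind, strsplit(ln[(ib + 1):length(ln)], "\\s+"))
  out <- list(n_eo = n_eo, resname = vals[keys == "resname"], atoms = atoms,
              bonds = cbind(as.integer(bd[, 1]), as.integer(bd[, 2])),
              stations = as.numeric(at[, 8]))
  class(out) <- "tx_template"
  validate_template(out)
  out
}

#' @export
print.tx_template <- function(x, ...) {
  cat(sprintf("TX surfactant template %s: n_eo = %d, %d atoms, %d bonds\n",
              x$resname, x$n_eo, nrow(x$atoms), nrow(x$bonds)))
  invisible(x)
}
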