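# Frame/trajectory containers and GRO/PDB coordinate I/O.
# Internal units: nm and ps. GRO is parsed by fixed columns; PDB goes
# through bio3d and is converted Angstrom -> nm.

#' Construct a coordinate frame
#'
#' @param positions N x 3 numeric matrix of positions (nm).
#' @param box length-3 positive box vector (nm), orthorhombic.
#' @param time frame time (ps).
#' @return object of class \code{mic_frame}.
#' @export
new_frame <- function(positions, box, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must be an N x 3 matrix")
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0))
    stop("box must be three positive lengths (orthorhombic)")
  structure(list(xyz = positions, box = box, time = as.numeric(time)),
            class = "mic_frame")
}

#' Construct a trajectory
#'
#' @param atoms atom table (data.frame, one row per atom) shared by all
#'   frames; typically carries name/resname/molid and, for template-bound
#'   systems, mass/vdw/role/class/label.
#' @param frames list of \code{mic_frame}s with strictly increasing times
#'   and N equal to \code{nrow(atoms)}.
#' @param dt_store spacing between stored frames (ps).
#' @param bonds optional 2-column matrix of global 1-based bonded pairs.
#' @return object of class \code{mic_trajectory}.
#' @export
new_trajectory <- function(atoms, frames, dt_store = 10, bonds = NULL) {
  stopifnot(is.data.frame(atoms), is.list(frames), length(frames) >= 1)
  n <- nrow(atoms)
  times <- vapply(frames, function(f) f$time, 0)
  if (any(vapply(frames, function(f) nrow(f$xyz), 0L) != n))
    stop("all frames must have as many rows as the atom table")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("frame times must be strictly increasing")
  structure(list(atoms = atoms, frames = frames,
                 dt_store = as.numeric(dt_store), bonds = bonds),
            class = "mic_trajectory")
}

#' @export
print.mic_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d atoms, %d frames, dt_store = %g ps, box = %s nm\n",
              nrow(x$atoms), length(x$frames), x$dt_store,
              paste(signif(x$frames[[1]]$box, 4), collapse = " x ")))
  invisible(x)
}

n_frames <- function(traj) length(traj$frames)

parse_gro_block <- function(lines, offset = 0) {
  if (length(lines) < 3)
    stop("GRO block too short (need title, atom count, box)")
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat))
    stop("GRO parse error at line ", offset + 2, ": bad atom count")
  if (length(lines) < nat + 3)
    stop("GRO file truncated: missing box line after atoms")
  al <- lines[3:(2 + nat)]
  bad <- which(nchar(al) < 44)
  if (length(bad))
    stop("GRO parse error at line ", offset + 2 + bad[1],
         ": atom line shorter than fixed-column format")
  num <- function(a, b) {
    v <- suppressWarnings(as.numeric(substr(al, a, b)))
    if (anyNA(v))
      stop("GRO parse error at line ", offset + 2 + which(is.na(v))[1],
           ": non-numeric coordinate field")
    v
  }
  atoms <- data.frame(
    resid = as.integer(substr(al, 1, 5)),
    resname = trimws(substr(al, 6, 10)),
    name = trimws(substr(al, 11, 15)),
    stringsAsFactors = FALSE)
  xyz <- cbind(num(21, 28), num(29, 36), num(37, 44))
  bx <- suppressWarnings(as.numeric(strsplit(trimws(lines[nat + 3]),
                                             "\\s+")[[1]]))
  if (length(bx) < 3 || anyNA(bx))
    stop("GRO parse error at line ", offset + nat + 3,
         ": missing or malformed box line")
  if (length(bx) > 3 && any(abs(bx[4:length(bx)]) > 1e-9))
    stop("triclinic boxes are not supported (orthorhombic only)")
  tm <- 0
  m <- regmatches(lines[1], regexec("t=\\s*([0-9.eE+-]+)", lines[1]))[[1]]
  if (length(m) == 2) tm <- as.numeric(m[2])
  list(atoms = atoms, frame = new_frame(xyz, bx[1:3], tm),
       used = nat + 3)
}

#' Read a coordinate file
#'
#' Reads a single-frame GRO (fixed-column, nm) or PDB (via bio3d, Angstrom
#' converted to nm) file. Malformed fixed-width GRO lines raise an error
#' naming the offending line; a missing GRO box line is an explicit error.
#'
#' @param path file path.
#' @param format "GRO" or "PDB"; default guessed from the extension.
#' @return list with \code{atoms} (resid, resname, name) and \code{frame}
#'   (a \code{mic_frame}).
#' @export
read_coordinates <- function(path, format = c("auto", "GRO", "PDB")) {
  format <- match.arg(toupper(format[1]), c("AUTO", "GRO", "PDB"))
  if (format == "AUTO")
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "PDB" else "GRO"
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "GRO") {
    blk <- parse_gro_block(readLines(path))
    return(blk[c("atoms", "frame")])
  }
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  xyz <- cbind(a$x, a$y, a$z) / 10            # Angstrom -> nm
  box <- rep(max(apply(xyz, 2, function(v) diff(range(v)))) + 2, 3)
  if (!is.null(pdb$cryst1) && length(pdb$cryst1$abc) == 3 &&
      all(is.finite(pdb$cryst1$abc)) && all(pdb$cryst1$abc > 0))
    box <- pdb$cryst1$abc / 10
  list(atoms = data.frame(resid = a$resno, resname = a$resid,
                          name = a$elety, stringsAsFactors = FALSE),
       frame = new_frame(xyz, box, 0))
}

#' Write a frame in GRO format
#'
#' Positions are written with the format's 3 decimal places (0.001 nm
#' resolution), so read(write(x)) reproduces x to 5e-4 nm.
#'
#' @param frame a \code{mic_frame}.
#' @param atoms atom table with \code{name}, \code{resname}, and either
#'   \code{resid} or \code{molid}.
#' @param path output path.
#' @param append append as an extra trajectory frame.
#' @param title title line (frame time is appended as \code{t= ...}).
#' @export
write_gro <- function(frame, atoms, path, append = FALSE,
                      title = "written by micellar") {
  resid <- if (!is.null(atoms$resid)) atoms$resid else atoms$molid
  if (is.null(resid)) resid <- seq_len(nrow(atoms))
  x <- frame$xyz
  lines <- c(sprintf("%s, t= %.3f", title, frame$time),
             sprintf("%5d", nrow(atoms)),
             sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                     resid %% 100000, substr(atoms$resname, 1, 5),
                     substr(atoms$name, 1, 5),
                     seq_len(nrow(atoms)) %% 100000,
                     x[, 1], x[, 2], x[, 3]),
             sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2],
                     frame$box[3]))
  con <- file(path, if (append) "a" else "w"); on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Write a frame in PDB format (via bio3d, nm converted to Angstrom)
#'
#' @inheritParams write_gro
#' @export
write_pdb_frame <- function(frame, atoms, path) {
  resid <- if (!is.null(atoms$resid)) atoms$resid else atoms$molid
  if (is.null(resid)) resid <- seq_len(nrow(atoms))
  x <- frame$xyz * 10
  bio3d::write.pdb(file = path, xyz = as.vector(t(x)),
                   resno = resid, resid = atoms$resname,
                   elety = atoms$name)
  invisible(path)
}

#' Read / write a concatenated-GRO trajectory
#'
#' The multi-frame dialect is a plain concatenation of GRO blocks; frame
#' times are taken from \code{t=} markers in the title lines (falling back
#' to \code{dt} spacing).
#'
#' @param path file path.
#' @param dt fallback frame spacing (ps) when titles carry no times.
#' @return a \code{mic_trajectory}.
#' @export
read_gro_trajectory <- function(path, dt = 10) {
  ln <- readLines(path)
  frames <- list(); atoms <- NULL; off <- 0
  while (off < length(ln)) {
    blk <- parse_gro_block(ln[(off + 1):length(ln)], offset = off)
    if (is.null(atoms)) atoms <- blk$atoms
    frames[[length(frames) + 1]] <- blk$frame
    off <- off + blk$used
  }
  times <- vapply(frames, function(f) f$time, 0)
  if (length(frames) > 1 && any(diff(times) <= 0))
    for (i in seq_along(frames)) frames[[i]]$time <- (i - 1) * dt
  new_trajectory(atoms, frames, dt_store = if (length(frames) > 1)
    frames[[2]]$time - frames[[1]]$time else dt)
}

#' @rdname read_gro_trajectory
#' @param traj a \code{mic_trajectory}.
#' @export
write_gro_trajectory <- function(traj, path) {
  for (i in seq_len(n_frames(traj)))
    write_gro(traj$frames[[i]], traj$atoms, path, append = i > 1)
  invisible(path)
}

#' Annotate a plain atom table with template roles
#'
#' Binds a surfactant template to atoms read from a coordinate file:
#' residues whose resname matches the template get the template's
#' mass/vdw/role/class/label columns (matched by within-residue order);
#' water residues (SOL/HOH/WAT) get WATER_O / WATER_H roles.
#'
#' @param atoms atom table from \code{read_coordinates} (needs resid,
#'   resname, name).
#' @param template a \code{tx_template}.
#' @return annotated atom table with a \code{molid} column.
#' @export
annotate_system <- function(atoms, template) {
  n <- nrow(atoms)
  molid <- cumsum(c(TRUE, atoms$resid[-1] != atoms$resid[-n] |
                      atoms$resname[-1] != atoms$resname[-n]))
  out <- atoms
  out$molid <- molid
  out$mass <- NA_real_; out$vdw <- NA_real_
  out$role <- NA_character_; out$class <- NA_character_
  out$label <- NA_character_
  props <- atom_properties()
  for (m in unique(molid)) {
    idx <- which(molid == m)
    rn <- atoms$resname[idx[1]]
    if (rn == template$resname) {
      if (length(idx) != nrow(template$atoms))
        stop("residue ", m, " has ", length(idx),
             " atoms; template expects ", nrow(template$atoms))
      for (col in c("mass", "vdw", "role", "class", "label"))
        out[[col]][idx] <- template$atoms[[col]]
    } else if (rn %in% c("SOL", "HOH", "WAT")) {
      isO <- grepl("^O", atoms$name[idx])
      out$role[idx] <- ifelse(isO, "WATER_O", "WATER_H")
      out$class[idx] <- "SOLVENT"
      out$mass[idx] <- ifelse(isO, props$mass[props$type == "OW"],
                              props$mass[props$type == "HW"])
      out$vdw[idx] <- ifelse(isO, props$vdw[props$type == "OW"],
                             props$vdw[props$type == "HW"])
    }
  }
  if (anyNA(out$role))
    stop("unrecognised residues: ",
         paste(unique(atoms$resname[is.na(out$role)]), collapse = ", "))
  out
}
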