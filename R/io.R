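# Reading and writing coordinate files: PDB, GRO, XYZ, single- and
# multi-frame. PDB and XYZ store Angstrom, GRO stores nm; beads are nm
# internally. Charges and radii are not representable in these formats;
# on read they are filled from a per-element default table.

.default_radii <- c(C = 0.17, N = 0.16, O = 0.15, S = 0.18,
                    AU = 0.145, H = 0.11, generic = 0.17)

.element_from_name <- function(name) {
  nm <- toupper(trimws(name))
  ifelse(substr(nm, 1, 2) == "AU", "AU",
    ifelse(substr(nm, 1, 1) %in% c("C", "N", "O", "S", "H"),
           substr(nm, 1, 1), "generic"))
}

.beads_from_fields <- function(name, residue_index, residue_name, pos_nm) {
  elem <- .element_from_name(name)
  bead_df(serial = seq_along(name), name = trimws(name),
          residue_index = residue_index, residue_name = trimws(residue_name),
          element_class = elem, position = pos_nm, charge = 0,
          radius = unname(.default_radii[elem]))
}

## ---- writers ---------------------------------------------------------------

.format_pdb_frame <- function(beads, model = NULL) {
  p <- nm_to_ang(bead_coords(beads))
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    beads$serial %% 100000, substr(beads$name, 1, 4),
    substr(beads$residue_name, 1, 3), beads$residue_index %% 10000,
    p[, 1], p[, 2], p[, 3])
  if (!is.null(model))
    lines <- c(sprintf("MODEL     %4d", model), lines, "ENDMDL")
  lines
}

.format_gro_frame <- function(beads, box_length = 0, time = NULL) {
  title <- "pepmpc structure"
  if (!is.null(time)) title <- sprintf("pepmpc structure t= %.3f", time)
  p <- bead_coords(beads)
  c(title,
    sprintf("%5d", nrow(beads)),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            beads$residue_index %% 100000,
            substr(beads$residue_name, 1, 5), substr(beads$name, 1, 5),
            beads$serial %% 100000, p[, 1], p[, 2], p[, 3]),
    sprintf("%10.5f%10.5f%10.5f", box_length, box_length, box_length))
}

.format_xyz_frame <- function(beads, time = NULL) {
  p <- nm_to_ang(bead_coords(beads))
  comment <- "pepmpc"
  if (!is.null(time)) comment <- sprintf("pepmpc t= %.3f", time)
  c(sprintf("%d", nrow(beads)), comment,
    sprintf("%-4s %12.5f %12.5f %12.5f", beads$name, p[, 1], p[, 2], p[, 3]))
}

#' Write a bead table to a coordinate file
#'
#' @param beads a bead table
#' @param path output file
#' @param format `"pdb"`, `"gro"` or `"xyz"`
#' @param box_length box edge written to GRO files, nm
#' @return the path, invisibly
#' @export
write_structure <- function(beads, path, format = c("pdb", "gro", "xyz"),
                            box_length = 0) {
  format <- match.arg(format)
  lines <- switch(format,
    pdb = c(.format_pdb_frame(beads), "END"),
    gro = .format_gro_frame(beads, box_length),
    xyz = .format_xyz_frame(beads))
  writeLines(lines, path)
  invisible(path)
}

#' Write a trajectory to a multi-frame coordinate file
#'
#' @param traj a `trajectory` (requires a topology for bead names)
#' @param path output file
#' @param format `"pdb"` (MODEL/ENDMDL blocks), `"gro"` or `"xyz"`
#' @return the path, invisibly
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "gro", "xyz")) {
  format <- match.arg(format)
  top <- traj$topology
  if (is.null(top))
    top <- .beads_from_fields(
      name = rep("X", dim(traj$coords)[2]),
      residue_index = seq_len(dim(traj$coords)[2]),
      residue_name = "UNK", pos_nm = frame_coords(traj, 1))
  box <- if (is.null(traj$box_length)) 0 else traj$box_length
  all_lines <- vector("list", n_frames(traj))
  for (f in seq_len(n_frames(traj))) {
    b <- set_bead_coords(top, frame_coords(traj, f))
    all_lines[[f]] <- switch(format,
      pdb = .format_pdb_frame(b, model = f),
      gro = .format_gro_frame(b, box, time = traj$times[f]),
      xyz = .format_xyz_frame(b, time = traj$times[f]))
  }
  lines <- unlist(all_lines)
  if (format == "pdb") lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

## ---- readers ---------------------------------------------------------------

.num <- function(s, line_no, what) {
  v <- suppressWarnings(as.numeric(s))
  if (any(is.na(v)))
    stop(sprintf("parse error at line %d: bad %s field '%s'",
                 line_no[which(is.na(v))[1]], what, s[which(is.na(v))[1]]))
  v
}

.parse_pdb_atoms <- function(lines, line_no) {
  ok <- grepl("^(ATOM  |HETATM)", lines)
  lines <- lines[ok]; line_no <- line_no[ok]
  if (!length(lines)) stop("no ATOM records found")
  short <- nchar(lines) < 54
  if (any(short))
    stop(sprintf("parse error at line %d: truncated ATOM record",
                 line_no[which(short)[1]]))
  name <- substr(lines, 13, 16)
  resn <- substr(lines, 18, 20)
  resi <- as.integer(.num(substr(lines, 23, 26), line_no, "residue index"))
  x <- .num(substr(lines, 31, 38), line_no, "x")
  y <- .num(substr(lines, 39, 46), line_no, "y")
  z <- .num(substr(lines, 47, 54), line_no, "z")
  .beads_from_fields(name, resi, resn, ang_to_nm(cbind(x, y, z)))
}

.parse_gro_block <- function(lines, line_no) {
  if (length(lines) < 3) stop("truncated GRO block")
  nat <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(nat)) stop(sprintf("parse error at line %d: bad atom count",
                               line_no[2]))
  if (length(lines) < 3 + nat)
    stop(sprintf("parse error at line %d: GRO block shorter than atom count",
                 line_no[length(line_no)]))
  al <- lines[3:(2 + nat)]; aln <- line_no[3:(2 + nat)]
  short <- nchar(al) < 44
  if (any(short))
    stop(sprintf("parse error at line %d: truncated GRO atom line",
                 aln[which(short)[1]]))
  resi <- as.integer(.num(substr(al, 1, 5), aln, "residue index"))
  resn <- substr(al, 6, 10)
  name <- substr(al, 11, 15)
  x <- .num(substr(al, 21, 28), aln, "x")
  y <- .num(substr(al, 29, 36), aln, "y")
  z <- .num(substr(al, 37, 44), aln, "z")
  box <- .num(strsplit(trimws(lines[3 + nat]), "\\s+")[[1]][1],
              line_no[3 + nat], "box")
  t <- NA_real_
  m <- regmatches(lines[1], regexec("t=\\s*([-0-9.eE+]+)", lines[1]))[[1]]
  if (length(m) == 2) t <- as.numeric(m[2])
  list(beads = .beads_from_fields(name, resi, resn, cbind(x, y, z)),
       box = box, time = t, used = 3 + nat)
}

.parse_xyz_block <- function(lines, line_no) {
  nat <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(nat)) stop(sprintf("parse error at line %d: bad atom count",
                               line_no[1]))
  if (length(lines) < 2 + nat)
    stop(sprintf("parse error at line %d: XYZ block shorter than atom count",
                 line_no[length(line_no)]))
  al <- lines[3:(2 + nat)]; aln <- line_no[3:(2 + nat)]
  parts <- strsplit(trimws(al), "\\s+")
  bad <- vapply(parts, length, 1L) < 4
  if (any(bad))
    stop(sprintf("parse error at line %d: XYZ atom line needs 4 fields",
                 aln[which(bad)[1]]))
  name <- vapply(parts, `[[`, "", 1)
  xyz <- t(vapply(parts, function(p) .num(p[2:4], rep(aln[1], 3), "coord"),
                  numeric(3)))
  t <- NA_real_
  m <- regmatches(lines[2], regexec("t=\\s*([-0-9.eE+]+)", lines[2]))[[1]]
  if (length(m) == 2) t <- as.numeric(m[2])
  list(beads = .beads_from_fields(name, seq_len(nat), "UNK", ang_to_nm(xyz)),
       box = NA_real_, time = t, used = 2 + nat)
}

#' Read a single-frame coordinate file
#'
#' @param path input file
#' @param format `"pdb"`, `"gro"` or `"xyz"`
#' @return a bead table; for GRO, the box edge (nm) is attached as
#'   attribute `box_length`
#' @export
read_structure <- function(path, format = c("pdb", "gro", "xyz")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  line_no <- seq_along(lines)
  switch(format,
    pdb = .parse_pdb_atoms(lines, line_no),
    gro = {
      blk <- .parse_gro_block(lines, line_no)
      attr(blk$beads, "box_length") <- blk$box
      blk$beads
    },
    xyz = .parse_xyz_block(lines, line_no)$beads)
}

#' Read a multi-frame coordinate file into a trajectory
#'
#' Frame times are taken from `t=` tags in GRO titles / XYZ comments when
#' present, otherwise a uniform spacing `dt` is assumed. All frames must
#' share the same atom count and ordering.
#'
#' @param path input file
#' @param format `"pdb"` (MODEL/ENDMDL), `"gro"` or `"xyz"`
#' @param dt frame spacing used when the file carries no times, ps
#' @param molecules optional molecule map (named list of bead indices)
#' @param box_length override for formats without a box record, nm
#' @return a `trajectory`
#' @export
read_trajectory <- function(path, format = c("pdb", "gro", "xyz"), dt = 1,
                            molecules = NULL, box_length = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  line_no <- seq_along(lines)
  frames <- list(); times <- numeric(0); box <- box_length
  if (format == "pdb") {
    starts <- grep("^MODEL", lines)
    if (!length(starts)) {
      frames[[1]] <- .parse_pdb_atoms(lines, line_no)
    } else {
      ends <- grep("^ENDMDL", lines)
      if (length(ends) != length(starts)) stop("unbalanced MODEL/ENDMDL")
      for (k in seq_along(starts)) {
        sel <- (starts[k] + 1):(ends[k] - 1)
        frames[[k]] <- .parse_pdb_atoms(lines[sel], line_no[sel])
      }
    }
  } else {
    pos <- 1
    parser <- if (format == "gro") .parse_gro_block else .parse_xyz_block
    while (pos <= length(lines)) {
      if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1; next }
      sel <- pos:length(lines)
      blk <- parser(lines[sel], line_no[sel])
      frames[[length(frames) + 1]] <- blk$beads
      times <- c(times, blk$time)
      if (is.null(box) && !is.na(blk$box) && blk$box > 0) box <- blk$box
      pos <- pos + blk$used
    }
  }
  if (!length(frames)) stop("no frames found in ", path)
  nat <- vapply(frames, nrow, 1L)
  if (length(unique(nat)) != 1)
    stop("inconsistent atom counts across frames: ",
         paste(unique(nat), collapse = ", "))
  if (!length(times) || anyNA(times) ||
      (length(times) > 1 && any(diff(times) <= 0)))
    times <- (seq_along(frames) - 1) * dt
  coords <- array(0, c(length(frames), nat[1], 3))
  for (f in seq_along(frames)) coords[f, , ] <- bead_coords(frames[[f]])
  trajectory(times, coords, box_length = box, molecules = molecules,
             topology = frames[[1]])
}
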