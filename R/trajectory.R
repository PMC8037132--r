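# Trajectory container: time-stamped multi-frame coordinates for one or
# more molecules in a (optionally periodic) cubic box. Coordinates in nm,
# times in ps.

#' Construct a trajectory
#'
#' @param times strictly increasing frame times, ps
#' @param coords numeric array `[frame, bead, xyz]`, nm
#' @param box_length cubic box edge, nm, or `NULL` for no periodicity
#' @param molecules named list of bead index vectors (molecule map);
#'   defaults to a single molecule `all`
#' @param topology optional bead table with the static per-bead fields
#'   (names, residues, element classes, charges, radii)
#' @return an object of class `trajectory`
#' @export
trajectory <- function(times, coords, box_length = NULL,
                       molecules = NULL, topology = NULL) {
  times <- as.numeric(times)
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3)
    stop("coords must be a [frame, bead, 3] array")
  if (dim(coords)[1] != length(times))
    stop("frame count must equal time count")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (!is.null(box_length) && box_length <= 0)
    stop("box_length must be > 0")
  n_beads <- dim(coords)[2]
  if (is.null(molecules)) molecules <- list(all = seq_len(n_beads))
  for (idx in molecules)
    stopifnot(all(idx >= 1), all(idx <= n_beads))
  if (!is.null(topology) && nrow(topology) != n_beads)
    stop("topology row count must match bead count")
  structure(list(times = times, coords = coords, box_length = box_length,
                 molecules = molecules, topology = topology),
            class = "trajectory")
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj a `trajectory`
#' @param frame frame index
#' @param molecule optional molecule name to subset beads
#' @return n x 3 matrix, nm
#' @export
frame_coords <- function(traj, frame, molecule = NULL) {
  x <- traj$coords[frame, , , drop = FALSE]
  x <- matrix(x, ncol = 3)
  if (!is.null(molecule)) {
    if (!molecule %in% names(traj$molecules))
      stop("unknown molecule: ", molecule)
    x <- x[traj$molecules[[molecule]], , drop = FALSE]
  }
  x
}

#' Per-frame centre-of-mass series of a molecule
#' @param traj a `trajectory`
#' @param molecule molecule name (default first)
#' @param masses optional per-bead masses for that molecule
#' @return n_frames x 3 matrix, nm
#' @export
com_series <- function(traj, molecule = NULL, masses = NULL) {
  if (is.null(molecule)) molecule <- names(traj$molecules)[1]
  idx <- traj$molecules[[molecule]]
  if (is.null(idx)) stop("unknown molecule: ", molecule)
  if (is.null(masses)) masses <- rep(1, length(idx))
  w <- masses / sum(masses)
  sub <- traj$coords[, idx, , drop = FALSE]
  out <- matrix(0, n_frames(traj), 3)
  for (k in 1:3) out[, k] <- matrix(sub[, , k], ncol = length(idx)) %*% w
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "trajectory: %d frames x %d beads, t = [%g, %g] ps, box %s nm, molecules: %s\n",
    n_frames(x), dim(x$coords)[2], x$times[1], x$times[length(x$times)],
    if (is.null(x$box_length)) "none" else format(x$box_length),
    paste(names(x$molecules), collapse = ", ")))
  invisible(x)
}

# minimum-image displacement under a cubic box (NULL box = plain difference)
min_image <- function(d, box_length = NULL) {
  if (is.null(box_length)) return(d)
  d - box_length * round(d / box_length)
}
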