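# Bead tables: the coarse site-level representation shared by the peptide
# and nanocluster models. A bead table is a data.frame with one row per
# site; positions are in nm, charges in elementary charges, radii in nm.

.bead_cols <- c("serial", "name", "residue_index", "residue_name",
                "element_class", "x", "y", "z", "charge", "radius")

.element_classes <- c("C", "N", "O", "S", "AU", "H", "generic")

#' Construct a bead table
#'
#' @param serial integer serials, unique within a molecule
#' @param name short site names (e.g. "CA", "NT", "OD1")
#' @param residue_index 1-based residue numbers
#' @param residue_name 3-letter residue codes
#' @param element_class one of C, N, O, S, AU, H, generic
#' @param position n x 3 matrix of coordinates, nm
#' @param charge formal/effective charges, e
#' @param radius bead radii, nm (must be > 0)
#' @return a `data.frame` of class `bead_df`
#' @export
bead_df <- function(serial, name, residue_index, residue_name,
                    element_class, position, charge = 0, radius = 0.15) {
  position <- matrix(as.numeric(position), ncol = 3)
  n <- length(serial)
  df <- data.frame(
    serial = as.integer(serial),
    name = as.character(name),
    residue_index = as.integer(residue_index),
    residue_name = as.character(residue_name),
    element_class = as.character(element_class),
    x = position[, 1], y = position[, 2], z = position[, 3],
    charge = rep_len(as.numeric(charge), n),
    radius = rep_len(as.numeric(radius), n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("bead_df", "data.frame")
  validate_beads(df)
  df
}

#' Validate a bead table's invariants
#'
#' Checks finite positions, positive radii, unique serials and a known
#' element class; stops on violation, returns the table invisibly.
#' @param beads a bead table
#' @export
validate_beads <- function(beads) {
  stopifnot(is.data.frame(beads), all(.bead_cols %in% names(beads)))
  if (anyDuplicated(beads$serial))
    stop("bead serials must be unique within a molecule")
  if (!all(is.finite(as.matrix(beads[, c("x", "y", "z")]))))
    stop("bead positions must be finite")
  if (any(beads$radius <= 0))
    stop("bead radii must be > 0")
  bad <- setdiff(unique(beads$element_class), .element_classes)
  if (length(bad))
    stop("unknown element class: ", paste(bad, collapse = ", "))
  invisible(beads)
}

#' Extract the coordinate matrix (nm) from a bead table
#' @param beads a bead table
#' @return n x 3 numeric matrix
#' @export
bead_coords <- function(beads) {
  as.matrix(beads[, c("x", "y", "z")])
}

#' Replace the coordinates of a bead table
#' @param beads a bead table
#' @param coords n x 3 matrix, nm
#' @return the updated bead table
#' @export
set_bead_coords <- function(beads, coords) {
  coords <- matrix(coords, ncol = 3)
  stopifnot(nrow(coords) == nrow(beads))
  beads$x <- coords[, 1]; beads$y <- coords[, 2]; beads$z <- coords[, 3]
  beads
}
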