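# Idealized monolayer-protected gold nanocluster: a spherical core with
# quasi-uniform thiolate anchors (Fibonacci lattice) carrying straight
# alkyl chains that terminate in a cationic amine nitrogen (+1 e each).
# The Au144 staple motif is deliberately not reproduced.

#' Quasi-uniform points on the unit sphere (Fibonacci lattice)
#'
#' @param n number of points
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i           # golden-angle longitude
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build an idealized Au-MPC nanocluster model
#'
#' Gold core beads fill a sphere of `core_radius`; `n_ligands` thiolate
#' anchors sit on the core surface on a Fibonacci lattice, each carrying a
#' radial chain of `chain_beads` methylene-like beads (0.15 nm spacing)
#' ending in a terminal amine nitrogen with charge +1 e. The core is
#' neutral, so the model's total charge equals `n_ligands`
#' (+60 for the default Au144(L)60 with L = S(CH2)8NH3+).
#'
#' @param n_core number of gold core beads (144)
#' @param n_ligands number of ligand chains (60)
#' @param chain_beads beads per chain between anchor and terminal N (9)
#' @param core_radius nm (0.9, i.e. a ~1.8 nm diameter core)
#' @param min_anchor_sep minimum allowed anchor separation, nm
#' @return an object of class `nanocluster_model`: list with `beads`
#'   (one bead table: core, anchors, chain beads, terminal N sites),
#'   `core_radius`, `n_ligands`, `ligand_of` (per-bead ligand id, NA for
#'   core), and `terminal_idx` (row indices of the terminal N sites,
#'   in ligand-id order)
#' @export
build_nanocluster <- function(n_core = 144, n_ligands = 60, chain_beads = 9,
                              core_radius = 0.9, min_anchor_sep = 0.3) {
  stopifnot(n_core >= 1, n_ligands >= 0, chain_beads >= 1, core_radius > 0)
  # hexagonal-packing capacity estimate for caps of radius min_anchor_sep/2
  if (n_ligands > 0) {
    capacity <- floor(0.9069 * (4 * pi * core_radius^2) /
                        (pi * (min_anchor_sep / 2)^2))
    if (n_ligands > capacity)
      stop(sprintf(
        "n_ligands = %d exceeds sphere packing capacity (~%d) at %.2f nm separation",
        n_ligands, capacity, min_anchor_sep))
  }
  rows <- list(); serial <- 0L
  add <- function(name, ri, rn, elem, pos, charge, radius, lig) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, residue_index = ri, residue_name = rn,
      element_class = elem, x = pos[1], y = pos[2], z = pos[3],
      charge = charge, radius = radius, ligand = lig,
      stringsAsFactors = FALSE)
  }
  # core: one central bead plus shells out to core_radius (positions are
  # cosmetic; the core is rigid and neutral)
  core_pts <- if (n_core == 1) matrix(0, 1, 3) else {
    n_surf <- max(1, n_core - 1)
    rbind(matrix(0, 1, 3), fibonacci_sphere(n_surf) * core_radius * 0.85)
  }
  for (i in seq_len(nrow(core_pts)))
    add("AU", 1L, "AUC", "AU", core_pts[i, ], 0, 0.145, NA_integer_)
  # ligands
  if (n_ligands > 0) {
    dirs <- fibonacci_sphere(n_ligands)
    for (l in seq_len(n_ligands)) {
      u <- dirs[l, ]
      ri <- 1L + l
      add("S", ri, "LIG", "S", u * core_radius, 0, 0.18, l)
      for (k in seq_len(chain_beads))
        add(paste0("C", k), ri, "LIG", "C",
            u * (core_radius + 0.15 * k), 0, 0.17, l)
      add("NT", ri, "LIG", "N",
          u * (core_radius + 0.15 * (chain_beads + 1)), +1, 0.16, l)
    }
  }
  beads <- do.call(rbind, rows)
  rownames(beads) <- NULL
  ligand_of <- beads$ligand
  beads$ligand <- NULL
  class(beads) <- c("bead_df", "data.frame")
  validate_beads(beads)
  terminal_idx <- which(beads$name == "NT" & beads$element_class == "N")
  structure(list(beads = beads, core_radius = core_radius,
                 n_ligands = n_ligands, ligand_of = ligand_of,
                 terminal_idx = terminal_idx),
            class = "nanocluster_model")
}

#' Total model charge of a nanocluster
#' @param model a `nanocluster_model`
#' @return charge in e (equals `n_ligands` by construction)
#' @export
nanocluster_charge <- function(model) sum(model$beads$charge)

#' @export
print.nanocluster_model <- function(x, ...) {
  cat(sprintf(
    "nanocluster_model: %d beads, %d ligands, core radius %.2f nm, charge %+g e\n",
    nrow(x$beads), x$n_ligands, x$core_radius, nanocluster_charge(x)))
  invisible(x)
}
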