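# Three-term solute-solute interaction energy used by the Brownian-dynamics
# docking: screened Coulomb electrostatics over effective charge sites,
# a short-range electrostatic desolvation penalty, and a contact-count
# non-polar (hydrophobic) desolvation reward. All energies in kT.

#' Docking configuration
#'
#' Physical and protocol parameters of the flexible BD docking. Distances
#' are in Angstrom, diffusion coefficients in cm^2/s (translation) and
#' rad^2/ps (rotation), matching how such protocols are specified.
#'
#' @param ionic_strength mol/L
#' @param solvent_dielectric relative permittivity of water
#' @param solute_dielectric relative permittivity of the solute interior
#'   (kept for documentation; the analytic screened-Coulomb model does not
#'   use a grid)
#' @param temperature K
#' @param start_separation initial centre-centre distance, Angstrom
#' @param fine_step_distance below this centre-centre distance the fine
#'   timestep is used, Angstrom
#' @param dt_fine fine BD timestep, ps
#' @param dt_max cap on the coarse (far-field) timestep, ps
#' @param n_runs number of independent BD runs
#' @param run_length per-run simulated time, ns
#' @param n_record size of the lowest-energy pose store
#' @param rmsd_distinct minimum peptide-bead RMSD between stored poses,
#'   Angstrom
#' @param D_trans_peptide,D_trans_cluster translational diffusion
#'   coefficients, cm^2/s
#' @param D_rot_peptide,D_rot_cluster rotational diffusion coefficients,
#'   rad^2/ps
#' @param desolv_coeff_elec electrostatic desolvation coefficient,
#'   kT per unit charge^2 (>= 0)
#' @param desolv_coeff_hydro non-polar desolvation coefficient, kT per
#'   nonpolar contact pair (<= 0 for a favourable term)
#' @param lambda_dse decay length of the desolvation proximity kernel,
#'   Angstrom
#' @param dsh_contact_range nonpolar pair distance defining a contact,
#'   Angstrom
#' @param clash_distance site-site distance flagged as a clash, Angstrom
#' @param U_max energy cap applied on clash, kT
#' @param escape_radius centre-centre distance terminating a run, Angstrom
#' @param swap_period BD steps between conformer-exchange attempts
#' @param record_every BD steps between pose-recording attempts
#' @param grid_dim electrostatic grid dimension kept for provenance only
#' @param rng_seed base seed; run index offsets it per run
#' @return a list of class `docking_config`
#' @export
docking_config <- function(ionic_strength = 0.010,
                           solvent_dielectric = 78.0,
                           solute_dielectric = 2.0,
                           temperature = 300,
                           start_separation = 100,
                           fine_step_distance = 50,
                           dt_fine = 1,
                           dt_max = 20,
                           n_runs = 5000,
                           run_length = 500,
                           n_record = 1000,
                           rmsd_distinct = 1.0,
                           D_trans_peptide = 0.27e-5,
                           D_trans_cluster = 0.11e-5,
                           D_rot_peptide = 30.7e-5,
                           D_rot_cluster = 2.1e-5,
                           desolv_coeff_elec = 0.5,
                           desolv_coeff_hydro = -0.1,
                           lambda_dse = 3.0,
                           dsh_contact_range = 4.5,
                           clash_distance = 0.5,
                           U_max = 1e4,
                           escape_radius = 300,
                           swap_period = 20,
                           record_every = 10,
                           grid_dim = 161,
                           rng_seed = 1L) {
  cfg <- as.list(environment())
  with(cfg, stopifnot(
    ionic_strength >= 0, solvent_dielectric > 0, solute_dielectric > 0,
    temperature > 0, start_separation > 0, dt_fine > 0, dt_max >= dt_fine,
    n_runs >= 1, run_length > 0, n_record >= 1, rmsd_distinct > 0,
    D_trans_peptide > 0, D_trans_cluster > 0,
    D_rot_peptide > 0, D_rot_cluster > 0,
    desolv_coeff_elec >= 0, lambda_dse > 0, dsh_contact_range > 0,
    U_max > 0, escape_radius > start_separation, swap_period >= 1))
  class(cfg) <- "docking_config"
  cfg
}

#' Screened-Coulomb electrostatic interaction energy
#'
#' Debye-Hueckel pair sum over effective charge sites:
#' \eqn{U_{EP} = \sum_{ij} q_i q_j \, l_B \, e^{-\kappa r_{ij}} / r_{ij}}
#' in kT, with the Bjerrum length from the solvent dielectric and
#' temperature and the screening constant from the ionic strength.
#' Site pairs closer than `clash_distance` flag a clash and the energy is
#' capped at `+/- U_max` (attribute `clash`).
#'
#' @param sites_A,sites_B bead tables carrying charges (rows with zero
#'   charge are ignored)
#' @param config a `docking_config`
#' @return energy in kT, with attribute `clash` (logical)
#' @export
electrostatic_energy <- function(sites_A, sites_B, config = docking_config()) {
  qa <- sites_A$charge; qb <- sites_B$charge
  A <- bead_coords(sites_A)[qa != 0, , drop = FALSE]
  B <- bead_coords(sites_B)[qb != 0, , drop = FALSE]
  qa <- qa[qa != 0]; qb <- qb[qb != 0]
  if (!length(qa) || !length(qb)) stop("need >= 1 charge site on each side")
  lb <- bjerrum_length(config$solvent_dielectric, config$temperature)
  kap <- debye_kappa(config$ionic_strength, config$solvent_dielectric,
                     config$temperature)
  r <- .cdist(A, B)
  clash <- any(r < ang_to_nm(config$clash_distance))
  r <- pmax(r, 1e-6)
  U <- sum(outer(qa, qb) * lb * exp(-kap * r) / r)
  if (clash) U <- sign(U) * min(abs(U), config$U_max)
  structure(U, clash = clash)
}

#' Electrostatic desolvation penalty
#'
#' Penalty for bringing charge sites of one solute close to the
#' low-dielectric body of the other:
#' \eqn{U_{dse} = a_{dse} \sum_i q_i^2 \sum_j e^{-r_{ij}/\lambda}}
#' (always >= 0, -> 0 at infinite separation).
#'
#' @param sites_A bead table whose charges are desolvated
#' @param surface_beads_B bead table of the other solute's beads
#' @param config a `docking_config`
#' @return energy in kT (>= 0)
#' @export
electrostatic_desolvation <- function(sites_A, surface_beads_B,
                                      config = docking_config()) {
  if (config$lambda_dse <= 0) stop("lambda_dse must be > 0")
  qa <- sites_A$charge
  A <- bead_coords(sites_A)[qa != 0, , drop = FALSE]
  qa <- qa[qa != 0]
  if (!length(qa)) return(0)
  B <- bead_coords(surface_beads_B)
  lam <- ang_to_nm(config$lambda_dse)
  r <- .cdist(A, B)
  config$desolv_coeff_elec * sum(qa^2 * rowSums(exp(-r / lam)))
}

#' Non-polar (hydrophobic) desolvation term
#'
#' `desolv_coeff_hydro` (negative by default) times the number of
#' nonpolar bead pairs (element classes C, S, AU) within
#' `dsh_contact_range`; <= 0 and -> 0 at infinite separation.
#'
#' @param surface_beads_A,surface_beads_B bead tables
#' @param config a `docking_config`
#' @return energy in kT
#' @export
hydrophobic_desolvation <- function(surface_beads_A, surface_beads_B,
                                    config = docking_config()) {
  np <- c("C", "S", "AU")
  A <- bead_coords(surface_beads_A)[surface_beads_A$element_class %in% np, ,
                                    drop = FALSE]
  B <- bead_coords(surface_beads_B)[surface_beads_B$element_class %in% np, ,
                                    drop = FALSE]
  if (!nrow(A) || !nrow(B)) return(0)
  r <- .cdist(A, B)
  config$desolv_coeff_hydro * sum(r < ang_to_nm(config$dsh_contact_range))
}

#' Assemble the three-term energy breakdown
#'
#' The total interaction energy is the plain sum of the long-range
#' electrostatic term, the electrostatic desolvation penalty and the
#' non-polar desolvation term.
#'
#' @param U_EP,U_dse,U_dsh component energies, kT
#' @return a list of class `energy_breakdown` with fields `U_EP`,
#'   `U_dse`, `U_dsh`, `U_repr`
#' @examples
#' total_interaction_energy(-49.864, 9.771, -10.913)$U_repr  # -51.006
#' @export
total_interaction_energy <- function(U_EP, U_dse, U_dsh) {
  vals <- c(U_EP, U_dse, U_dsh)
  if (any(!is.finite(vals))) stop("energy components must be finite")
  structure(list(U_EP = U_EP, U_dse = U_dse, U_dsh = U_dsh,
                 U_repr = U_EP + U_dse + U_dsh),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("U_repr = %.3f kT (U_EP %.3f, U_dse %.3f, U_dsh %.3f)\n",
              x$U_repr, x$U_EP, x$U_dse, x$U_dsh))
  invisible(x)
}

#' Full interaction energy of a peptide frame against the cluster
#'
#' Convenience wrapper evaluating all three terms between a posed peptide
#' bead table and a nanocluster model, including both desolvation
#' directions (peptide charges against cluster body and vice versa).
#'
#' @param pep_beads peptide bead table in the cluster frame
#' @param cluster a `nanocluster_model`
#' @param config a `docking_config`
#' @return an `energy_breakdown` with attribute `clash`
#' @export
interaction_energy <- function(pep_beads, cluster,
                               config = docking_config()) {
  U_ep <- electrostatic_energy(pep_beads, cluster$beads, config)
  U_dse <- electrostatic_desolvation(pep_beads, cluster$beads, config) +
    electrostatic_desolvation(cluster$beads, pep_beads, config)
  U_dsh <- hydrophobic_desolvation(pep_beads, cluster$beads, config)
  out <- total_interaction_energy(as.numeric(U_ep), U_dse, U_dsh)
  attr(out, "clash") <- attr(U_ep, "clash")
  out
}

# per-site electrostatic + desolvation force (kT/nm) on each charge site
# of A from the sites/beads of B; used by the BD propagator. Returns a
# list(force = n_A x 3, on the rows of A_coords).
.pair_forces <- function(A_coords, A_charges, B_coords, B_charges,
                         config) {
  lb <- bjerrum_length(config$solvent_dielectric, config$temperature)
  kap <- debye_kappa(config$ionic_strength, config$solvent_dielectric,
                     config$temperature)
  lam <- ang_to_nm(config$lambda_dse)
  F <- matrix(0, nrow(A_coords), 3)
  chgB <- which(B_charges != 0)
  for (i in seq_len(nrow(A_coords))) {
    dvec <- sweep(B_coords, 2, A_coords[i, ], "-")   # i -> j
    r <- sqrt(rowSums(dvec^2)); r <- pmax(r, 1e-6)
    u <- -dvec / r                                   # unit j -> i
    f <- numeric(length(r))
    if (A_charges[i] != 0 && length(chgB)) {
      # -dU/dr of the screened Coulomb term
      f[chgB] <- f[chgB] + A_charges[i] * B_charges[chgB] * lb *
        exp(-kap * r[chgB]) * (1 / r[chgB]^2 + kap / r[chgB])
      # desolvation of charge i by the body of B
      f <- f + config$desolv_coeff_elec * A_charges[i]^2 *
        exp(-r / lam) / lam
    }
    # desolvation of B's charges by the body of A acts on A via reaction
    if (length(chgB)) {
      f[chgB] <- f[chgB] + config$desolv_coeff_elec * B_charges[chgB]^2 *
        exp(-r[chgB] / lam) / lam
    }
    F[i, ] <- colSums(f * u)
  }
  F
}

# all-pairs Euclidean distance matrix between two coordinate sets (nm)
.cdist <- function(A, B) {
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * (A %*% t(B))
  sqrt(pmax(d2, 0))
}
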