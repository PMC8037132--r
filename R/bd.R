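# Flexible Brownian-dynamics docking: overdamped rigid-body propagation of
# the peptide relative to a fixed nanocluster (relative diffusion
# coefficients), Metropolis conformer exchange, and a bounded store of the
# lowest-energy mutually-distinct poses.

#' Construct a docked pose
#'
#' A pose is one rigid-body placement of one peptide conformer relative
#' to the cluster: `displacement` is the cluster-COM to peptide-COM
#' vector (nm, internal convention) and `orientation` a unit quaternion
#' applied to the conformer about its own COM.
#'
#' @param conformer_index index into the peptide's conformer list
#' @param displacement 3-vector, nm
#' @param orientation unit quaternion (w, x, y, z)
#' @param energy optional `energy_breakdown`
#' @return an object of class `docked_pose`
#' @export
docked_pose <- function(conformer_index, displacement,
                        orientation = c(1, 0, 0, 0), energy = NULL) {
  nq <- sqrt(sum(orientation^2))
  if (abs(nq - 1) > 1e-6) stop("orientation must be a unit quaternion")
  structure(list(conformer_index = as.integer(conformer_index),
                 displacement = as.numeric(displacement),
                 orientation = orientation / nq,
                 energy = energy),
            class = "docked_pose")
}

#' Peptide coordinates of a pose (cluster frame)
#'
#' @param pose a `docked_pose`
#' @param peptide a `peptide_model`
#' @return the conformer's bead table, rotated about its COM and
#'   translated so its COM sits at `pose$displacement`
#' @export
pose_coords <- function(pose, peptide) {
  beads <- peptide$conformers[[pose$conformer_index]]
  p <- bead_coords(beads)
  cm <- colMeans(p)
  p <- quat_rotate(pose$orientation, sweep(p, 2, cm))
  p <- sweep(p, 2, pose$displacement, "+")
  set_bead_coords(beads, p)
}

#' One Ermak-McCammon BD step on the relative coordinates
#'
#' Translation: `dr = D_rel F dt + xi`, `xi ~ N(0, 2 D_rel dt)` per axis,
#' with `D_rel` the sum of both solutes' translational coefficients
#' (energies in kT, so kT = 1 in these units). Rotation: analogous
#' angular update of the mobile solute with its rotational coefficient;
#' the quaternion is renormalized.
#'
#' @param pose a `docked_pose`
#' @param force 3-vector, kT/nm (internal nm convention)
#' @param torque 3-vector, kT/rad
#' @param dt timestep, ps
#' @param config a `docking_config`
#' @param noise logical; `FALSE` gives the deterministic drift only
#' @return the propagated `docked_pose`
#' @export
bd_step <- function(pose, force = c(0, 0, 0), torque = c(0, 0, 0), dt,
                    config = docking_config(), noise = TRUE) {
  if (dt <= 0) stop("dt must be > 0")
  D_rel <- cm2_per_s_to_nm2_per_ps(config$D_trans_peptide +
                                     config$D_trans_cluster)  # nm^2/ps
  D_rot <- config$D_rot_peptide                               # rad^2/ps
  dr <- D_rel * force * dt
  dphi <- D_rot * torque * dt
  if (noise) {
    dr <- dr + stats::rnorm(3, 0, sqrt(2 * D_rel * dt))
    dphi <- dphi + stats::rnorm(3, 0, sqrt(2 * D_rot * dt))
  }
  q <- quat_multiply(quat_from_rotvec(dphi), pose$orientation)
  q <- q / sqrt(sum(q^2))
  docked_pose(pose$conformer_index, pose$displacement + dr, q)
}

#' Timestep schedule as a function of centre-centre distance
#'
#' The fine timestep applies below `fine_step_distance`; beyond it the
#' step grows linearly (one fine step per 10 Angstrom of extra
#' separation) up to `dt_max`.
#'
#' @param distance centre-centre distance, Angstrom
#' @param config a `docking_config`
#' @return timestep, ps
#' @export
bd_timestep <- function(distance, config = docking_config()) {
  if (distance < config$fine_step_distance) return(config$dt_fine)
  min(config$dt_max,
      config$dt_fine * max(1, (distance - config$fine_step_distance) / 10))
}

#' Metropolis acceptance for an energy difference
#' @param dU energy difference (trial - current), kT
#' @return logical, accepted or not
#' @export
metropolis_accept <- function(dU) {
  if (dU <= 0) return(TRUE)
  stats::runif(1) < exp(-dU)
}

#' Metropolis conformer-exchange move
#'
#' Proposes the adjacent conformer in the (circular) list -- direction
#' chosen at random when more than two conformers exist -- and accepts
#' with probability `min(1, exp(-dU_repr))`. Position and orientation
#' are preserved either way.
#'
#' @param pose a `docked_pose`
#' @param peptide a `peptide_model` with >= 2 conformers
#' @param cluster a `nanocluster_model` (ignored when `energy_fn` given)
#' @param config a `docking_config`
#' @param energy_fn optional `function(pose)` returning U_repr in kT;
#'   defaults to the full three-term interaction energy
#' @return the (possibly updated) `docked_pose`; attribute `accepted`
#'   records the outcome
#' @export
metropolis_conformer_swap <- function(pose, peptide, cluster = NULL,
                                      config = docking_config(),
                                      energy_fn = NULL) {
  n_conf <- length(peptide$conformers)
  if (n_conf < 2) stop("conformer exchange needs >= 2 conformers")
  if (is.null(energy_fn))
    energy_fn <- function(p)
      interaction_energy(pose_coords(p, peptide), cluster, config)$U_repr
  step <- if (n_conf == 2) 1 else sample(c(-1L, 1L), 1)
  trial_idx <- ((pose$conformer_index - 1L + step) %% n_conf) + 1L
  trial <- docked_pose(trial_idx, pose$displacement, pose$orientation)
  dU <- energy_fn(trial) - energy_fn(pose)
  if (metropolis_accept(dU)) {
    structure(trial, accepted = TRUE)
  } else {
    structure(pose, accepted = FALSE)
  }
}

# clash test: any inter-bead distance below 0.9 * (r_i + r_j)
.has_clash <- function(pep_beads, cluster) {
  r <- .cdist(bead_coords(pep_beads), bead_coords(cluster$beads))
  lim <- 0.9 * outer(pep_beads$radius, cluster$beads$radius, "+")
  any(r < lim)
}

#' Run the flexible BD docking protocol
#'
#' Each run starts the peptide at `start_separation` in a random
#' direction with a random orientation and propagates the relative
#' coordinates until `run_length` (ns) or escape beyond
#' `escape_radius`. Periodically the current configuration competes for
#' a slot in a bounded store of the `n_record` lowest-energy poses, any
#' two of which differ by peptide-bead RMSD > `rmsd_distinct`
#' (no re-superposition: poses share the cluster frame). Conformer
#' exchange is attempted every `swap_period` steps.
#'
#' @param peptide a `peptide_model`
#' @param cluster a `nanocluster_model`
#' @param config a `docking_config`
#' @param progress logical, print per-run progress
#' @return a list of class `docking_result`: `poses` (list of
#'   `docked_pose` sorted by increasing U_repr), `energies` (their
#'   U_repr), `visit_fractions` (per-conformer, sums to 1), `n_steps`
#' @export
run_docking <- function(peptide, cluster, config = docking_config(),
                        progress = FALSE) {
  n_conf <- length(peptide$conformers)
  store <- list()        # entries: list(pose, U, coords)
  visit <- numeric(n_conf)
  total_steps <- 0L
  run_cap_ps <- config$run_length * 1000
  esc_nm <- ang_to_nm(config$escape_radius)
  start_nm <- ang_to_nm(config$start_separation)
  rms_cut <- config$rmsd_distinct   # Angstrom (rmsd() returns Angstrom)

  for (run in seq_len(config$n_runs)) {
    set.seed(config$rng_seed + run - 1L)
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    pose <- docked_pose(sample.int(n_conf, 1), u * start_nm, quat_random())
    t_ps <- 0; step <- 0L
    while (t_ps < run_cap_ps) {
      d_nm <- sqrt(sum(pose$displacement^2))
      if (d_nm > esc_nm) break
      dt <- bd_timestep(nm_to_ang(d_nm), config)
      pep <- pose_coords(pose, peptide)
      P <- bead_coords(pep)
      F <- .pair_forces(P, pep$charge, bead_coords(cluster$beads),
                        cluster$beads$charge, config)
      F_tot <- colSums(F)
      arm <- sweep(P, 2, colMeans(P))
      torque <- c(sum(arm[, 2] * F[, 3] - arm[, 3] * F[, 2]),
                  sum(arm[, 3] * F[, 1] - arm[, 1] * F[, 3]),
                  sum(arm[, 1] * F[, 2] - arm[, 2] * F[, 1]))
      trial <- bd_step(pose, F_tot, torque, dt, config)
      if (!.has_clash(pose_coords(trial, peptide), cluster))
        pose <- trial
      step <- step + 1L; t_ps <- t_ps + dt
      visit[pose$conformer_index] <- visit[pose$conformer_index] + 1
      if (step %% config$swap_period == 0L)
        pose <- metropolis_conformer_swap(pose, peptide, cluster, config)
      if (step %% config$record_every == 0L) {
        pep_now <- pose_coords(pose, peptide)
        eb <- interaction_energy(pep_now, cluster, config)
        store <- .store_insert(store, pose, eb, bead_coords(pep_now),
                               config$n_record, rms_cut)
      }
    }
    total_steps <- total_steps + step
    if (progress)
      message(sprintf("run %d/%d: %d steps, store %d",
                      run, config$n_runs, step, length(store)))
  }
  if (!length(store))
    warning("no poses recorded (no attractive encounters)")
  ord <- order(vapply(store, `[[`, 0, "U"))
  store <- store[ord]
  poses <- lapply(store, function(e) {
    p <- e$pose; p$energy <- e$energy; p
  })
  vf <- if (sum(visit) > 0) visit / sum(visit) else visit
  names(vf) <- paste0("conf", seq_len(n_conf))
  structure(list(poses = poses,
                 energies = vapply(store, `[[`, 0, "U"),
                 visit_fractions = vf,
                 n_steps = total_steps),
            class = "docking_result")
}

# insert a candidate into the bounded lowest-energy store keeping all
# stored poses mutually distinct by raw RMSD > rms_cut (Angstrom)
.store_insert <- function(store, pose, energy, coords, n_record, rms_cut) {
  U <- energy$U_repr
  if (length(store) >= n_record) {
    worst <- max(vapply(store, `[[`, 0, "U"))
    if (U >= worst) return(store)
  }
  entry <- list(pose = pose, U = U, energy = energy, coords = coords)
  for (k in seq_along(store)) {
    if (rmsd(store[[k]]$coords, coords, superpose = FALSE) <= rms_cut) {
      if (U < store[[k]]$U) store[[k]] <- entry
      return(store)
    }
  }
  store[[length(store) + 1L]] <- entry
  if (length(store) > n_record) {
    worst <- which.max(vapply(store, `[[`, 0, "U"))
    store <- store[-worst]
  }
  store
}
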