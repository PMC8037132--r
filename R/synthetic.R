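# Synthetic trajectory generators with known ground truth. Each generator
# is deterministic under its seed and returns list(trajectory|quats, truth)
# where truth mirrors the generating parameters and per-frame labels.

#' Generator specification
#'
#' @param kind one of `free_diffusion`, `rotational_diffusion`,
#'   `staged_association`, `conformer_chain`, `bound_complex`
#' @param dt frame spacing, ps
#' @param n_frames number of frames
#' @param seed RNG seed (recorded in the output truth)
#' @param ... kind-specific parameters, see the individual generators
#' @return a list of class `generator_spec`
#' @export
generator_spec <- function(kind = c("free_diffusion", "rotational_diffusion",
                                    "staged_association", "conformer_chain",
                                    "bound_complex"),
                           dt = 1, n_frames = 1000, seed = 1L, ...) {
  kind <- match.arg(kind)
  if (dt <= 0) stop("dt must be > 0")
  if (n_frames < 1) stop("n_frames must be >= 1")
  structure(c(list(kind = kind, dt = dt, n_frames = n_frames,
                   seed = as.integer(seed)), list(...)),
            class = "generator_spec")
}

.truth <- function(spec, ...) {
  structure(c(list(spec = spec), list(...)), class = "ground_truth")
}

# combine peptide + cluster bead tables into one system topology
.system_topology <- function(pep_beads, clus_beads) {
  top <- rbind(pep_beads, clus_beads)
  top$serial <- seq_len(nrow(top))
  class(top) <- c("bead_df", "data.frame")
  molecules <- list(peptide = seq_len(nrow(pep_beads)),
                    cluster = nrow(pep_beads) + seq_len(nrow(clus_beads)))
  list(topology = top, molecules = molecules)
}

#' Free translational diffusion of a point solute
#'
#' Gaussian increments with per-axis variance `2 D dt`.
#'
#' @param spec a `generator_spec` of kind `free_diffusion` with
#'   parameter `D_trans` (cm^2/s)
#' @return list with `trajectory` (single-bead molecule `peptide`) and
#'   `truth`
#' @export
gen_free_diffusion <- function(spec) {
  stopifnot(spec$kind == "free_diffusion")
  D <- cm2_per_s_to_nm2_per_ps(spec$D_trans)
  set.seed(spec$seed)
  n <- spec$n_frames
  steps <- matrix(stats::rnorm(3 * (n - 1), 0, sqrt(2 * D * spec$dt)),
                  n - 1, 3)
  pos <- rbind(0, apply(steps, 2, cumsum))
  coords <- array(pos, c(n, 1, 3))
  top <- bead_df(1, "CA", 1, "GLY", "C", matrix(0, 1, 3))
  traj <- trajectory(times = (seq_len(n) - 1) * spec$dt, coords = coords,
                     molecules = list(peptide = 1L), topology = top)
  list(trajectory = traj, truth = .truth(spec, D_trans = spec$D_trans))
}

#' Isotropic rotational diffusion of a rigid body
#'
#' Per step a random rotation vector with per-axis variance
#' `2 D_rot dt` composes onto the orientation quaternion, giving a
#' body-axis autocorrelation `exp(-2 D_rot tau)`.
#'
#' @param spec a `generator_spec` of kind `rotational_diffusion` with
#'   parameter `D_rot` (rad^2/ps)
#' @return list with `quats` (n x 4 unit quaternions), `times` and
#'   `truth`
#' @export
gen_rotational_diffusion <- function(spec) {
  stopifnot(spec$kind == "rotational_diffusion")
  D <- spec$D_rot
  if (4 * D * spec$dt > 0.1)
    warning("dt too large for small-angle rotational steps")
  set.seed(spec$seed)
  n <- spec$n_frames
  omega <- matrix(stats::rnorm(3 * (n - 1), 0, sqrt(2 * D * spec$dt)),
                  n - 1, 3)
  q <- matrix(0, n, 4); q[1, ] <- c(1, 0, 0, 0)
  for (t in seq_len(n - 1)) {
    qt <- quat_multiply(quat_from_rotvec(omega[t, ]), q[t, ])
    q[t + 1, ] <- qt / sqrt(sum(qt^2))
  }
  list(quats = q, times = (seq_len(n) - 1) * spec$dt,
       truth = .truth(spec, D_rot = D))
}

# discrete Ornstein-Uhlenbeck series around a (possibly per-frame) mean
.ou_series <- function(n, mean_series, sigma, tau_frames) {
  rho <- exp(-1 / tau_frames)
  x <- numeric(n)
  x[1] <- mean_series[1] + stats::rnorm(1, 0, sigma)
  innov <- stats::rnorm(n - 1, 0, sigma * sqrt(1 - rho^2))
  for (t in 2:n)
    x[t] <- mean_series[t] + rho * (x[t - 1] - mean_series[t]) + innov[t - 1]
  x
}

#' Staged approach-and-adsorb association trajectory
#'
#' The peptide-cluster COM distance follows per-stage means (default
#' 25, 17, 16 Angstrom -- far approach, near approach, adsorbed) with
#' Ornstein-Uhlenbeck fluctuations, while the COM direction drifts
#' slowly on the sphere. Two single-bead molecules are emitted so the
#' full association-profile machinery applies.
#'
#' @param spec a `generator_spec` of kind `staged_association` with
#'   parameters `stage_distances` (Angstrom), `stage_frames` (frames per
#'   stage; same length), `sigma` (OU sd, Angstrom, default 0.5),
#'   `tau_frames` (OU relaxation, default 100), `angular_step` (rad per
#'   frame sd, default 0.01)
#' @return list with `trajectory` and `truth` (per-frame `stage_labels`)
#' @export
gen_staged_association <- function(spec) {
  stopifnot(spec$kind == "staged_association")
  d_mean <- spec$stage_distances
  nfr <- spec$stage_frames
  if (length(d_mean) < 1 || length(d_mean) != length(nfr))
    stop("stage_distances and stage_frames must have equal length >= 1")
  sigma <- if (is.null(spec$sigma)) 0.5 else spec$sigma
  tau <- if (is.null(spec$tau_frames)) 100 else spec$tau_frames
  astep <- if (is.null(spec$angular_step)) 0.01 else spec$angular_step
  if (length(d_mean) > 1 && any(abs(diff(d_mean)) < 2 * sigma))
    warning("adjacent stage means closer than 2 sigma; segmentation may be unidentifiable")
  n <- sum(nfr)
  labels <- rep(seq_along(nfr), nfr)
  set.seed(spec$seed)
  # OU fluctuation around zero, added to the per-stage mean: stage jumps
  # are instantaneous, the fluctuation alone carries the autocorrelation
  d <- d_mean[labels] + .ou_series(n, rep(0, n), sigma, tau)   # Angstrom
  theta <- numeric(n); phi <- numeric(n)
  theta[1] <- pi / 2
  dth <- stats::rnorm(n - 1, 0, astep); dph <- stats::rnorm(n - 1, 0, astep)
  for (t in 2:n) {
    theta[t] <- min(pi - 1e-3, max(1e-3, theta[t - 1] + dth[t - 1]))
    phi[t] <- phi[t - 1] + dph[t - 1]
  }
  u <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  pep <- ang_to_nm(d) * u
  coords <- array(0, c(n, 2, 3))
  coords[, 1, ] <- pep     # peptide COM bead; cluster bead stays at origin
  pep_top <- bead_df(1, "CA", 1, "GLY", "C", matrix(0, 1, 3))
  clus_top <- bead_df(1, "AU", 1, "AUC", "AU", matrix(0, 1, 3))
  st <- .system_topology(pep_top, clus_top)
  traj <- trajectory((seq_len(n) - 1) * spec$dt, coords,
                     molecules = st$molecules, topology = st$topology)
  list(trajectory = traj,
       truth = .truth(spec, stage_labels = labels, stage_means = d_mean))
}

#' Two-state conformer-switching peptide trajectory
#'
#' The bead chain toggles between the extended and horseshoe templates
#' of [build_peptide()] through a two-state Markov chain, with isotropic
#' Gaussian positional noise.
#'
#' @param spec a `generator_spec` of kind `conformer_chain` with
#'   parameters `switch_rate` (transitions/ns, used for both directions
#'   unless `rate_to_horseshoe`/`rate_to_extended` are given) and
#'   `noise_sigma` (Angstrom, default 0.5)
#' @param sequence one-letter peptide sequence
#' @return list with `trajectory` (molecule `peptide`), `peptide` (the
#'   model) and `truth` (per-frame `conformer_labels`: 1 extended,
#'   2 horseshoe)
#' @export
gen_conformer_chain <- function(spec, sequence) {
  stopifnot(spec$kind == "conformer_chain")
  pep <- build_peptide(sequence, c("extended", "horseshoe"))
  r12 <- if (!is.null(spec$rate_to_horseshoe)) spec$rate_to_horseshoe
         else spec$switch_rate
  r21 <- if (!is.null(spec$rate_to_extended)) spec$rate_to_extended
         else spec$switch_rate
  sig <- ang_to_nm(if (is.null(spec$noise_sigma)) 0.5 else spec$noise_sigma)
  dt_ns <- spec$dt / 1000
  p12 <- 1 - exp(-r12 * dt_ns); p21 <- 1 - exp(-r21 * dt_ns)
  if ((r12 > 0 && 1 / (r12 * dt_ns) < 10) ||
      (r21 > 0 && 1 / (r21 * dt_ns) < 10))
    warning("expected conformer dwell below 10 frames")
  n <- spec$n_frames
  set.seed(spec$seed)
  state <- integer(n); state[1] <- 1L
  u <- stats::runif(n - 1)
  for (t in 2:n)
    state[t] <- if (state[t - 1] == 1L) {
      if (u[t - 1] < p12) 2L else 1L
    } else {
      if (u[t - 1] < p21) 1L else 2L
    }
  tpl <- lapply(pep$conformers, bead_coords)
  nb <- nrow(tpl[[1]])
  coords <- array(0, c(n, nb, 3))
  noise <- array(stats::rnorm(n * nb * 3, 0, sig), c(n, nb, 3))
  for (t in seq_len(n)) coords[t, , ] <- tpl[[state[t]]] + noise[t, , ]
  traj <- trajectory((seq_len(n) - 1) * spec$dt, coords,
                     molecules = list(peptide = seq_len(nb)),
                     topology = pep$conformers[[1]])
  list(trajectory = traj, peptide = pep,
       truth = .truth(spec, conformer_labels = state))
}

#' Bound peptide-cluster complex with a persistent binding patch
#'
#' The peptide COM is tethered (3D Ornstein-Uhlenbeck, stationary sd set
#' by `confinement_radius`) above a designated patch of ligands whose
#' terminal amine N sites are kept within contact range of the
#' peptide's anionic sites; all other cluster beads fluctuate freely
#' about their model positions. The confinement makes the long-lag MSD
#' sub-linear by construction.
#'
#' @param spec a `generator_spec` of kind `bound_complex` with
#'   parameters `patch_ligand_ids` (integer), `confinement_radius`
#'   (Angstrom, default 2), `noise_sigma` (Angstrom, default 0.3),
#'   `contact_distance` (Angstrom, default 2.5), `exclusion_distance`
#'   (Angstrom, default 4.5; non-patch terminal N sites are kept at
#'   least this far from every peptide bead), `tau_frames` (default 50)
#' @param peptide a `peptide_model`
#' @param cluster a `nanocluster_model`
#' @return list with `trajectory` (molecules `peptide`, `cluster`) and
#'   `truth` (`patch_ligand_ids`, per-frame `bound` flags)
#' @export
gen_bound_complex <- function(spec, peptide, cluster) {
  stopifnot(spec$kind == "bound_complex")
  patch <- as.integer(spec$patch_ligand_ids)
  if (!length(patch) || any(patch < 1) || any(patch > cluster$n_ligands))
    stop("invalid patch ligand ids")
  Rconf <- ang_to_nm(if (is.null(spec$confinement_radius)) 2
                     else spec$confinement_radius)
  sig <- ang_to_nm(if (is.null(spec$noise_sigma)) 0.3 else spec$noise_sigma)
  dcon <- ang_to_nm(if (is.null(spec$contact_distance)) 2.5
                    else spec$contact_distance)
  tau <- if (is.null(spec$tau_frames)) 50 else spec$tau_frames
  excl <- ang_to_nm(if (is.null(spec$exclusion_distance)) 4.5
                    else spec$exclusion_distance)

  clus_xyz <- bead_coords(cluster$beads)
  term_idx <- cluster$terminal_idx
  anchors <- clus_xyz[term_idx[patch], , drop = FALSE]
  u0 <- colSums(anchors); u0 <- u0 / sqrt(sum(u0^2))
  dots <- anchors %*% u0
  if (any(dots <= 0))
    stop("patch ligands lie on the opposite side of the confinement point")

  pep_beads <- peptide$conformers[[1]]
  P0 <- bead_coords(pep_beads)
  tip_r <- max(sqrt(rowSums(clus_xyz[term_idx, , drop = FALSE]^2)))
  # orient the chain tangentially, COM just outside the monolayer tip
  ez <- c(0, 0, 1)
  axis <- .cross3(ez, u0); s <- sqrt(sum(axis^2))
  Rm <- if (s < 1e-9) diag(3) else {
    ang <- atan2(s, sum(ez * u0))
    quat_to_matrix(quat_from_rotvec(axis / s * ang))
  }
  P0 <- sweep(P0, 2, colMeans(P0))
  P0 <- P0 %*% t(Rm)
  com0 <- u0 * (tip_r + 0.25)
  P0 <- sweep(P0, 2, com0, "+")

  # anionic peptide sites the patch terminal sites are tethered to
  neg_rows <- which(pep_beads$charge < 0)
  if (!length(neg_rows)) neg_rows <- seq_len(nrow(pep_beads))
  target_of <- neg_rows[((seq_along(patch) - 1) %% length(neg_rows)) + 1]

  n <- spec$n_frames
  nb_p <- nrow(P0); nb_c <- nrow(clus_xyz)
  set.seed(spec$seed)
  disp <- vapply(1:3, function(k)
    .ou_series(n, rep(0, n), Rconf / sqrt(3), tau), numeric(n))
  coords <- array(0, c(n, nb_p + nb_c, 3))
  for (t in seq_len(n)) {
    Pt <- P0 + matrix(stats::rnorm(nb_p * 3, 0, sig), nb_p, 3)
    Pt <- sweep(Pt, 2, disp[t, ], "+")
    Ct <- clus_xyz + matrix(stats::rnorm(nb_c * 3, 0, sig), nb_c, 3)
    # pin patch terminal N sites near their assigned peptide sites
    for (k in seq_along(patch)) {
      site <- Pt[target_of[k], ]
      a <- clus_xyz[term_idx[patch[k]], ]
      dir <- a - site; dir <- dir / max(sqrt(sum(dir^2)), 1e-9)
      Ct[term_idx[patch[k]], ] <- site + dir * dcon +
        stats::rnorm(3, 0, sig / 3)
    }
    # generator contract: non-patch terminal N sites stay outside the
    # exclusion range of every peptide bead
    nonpatch <- setdiff(seq_len(cluster$n_ligands), patch)
    if (length(nonpatch)) {
      np_idx <- term_idx[nonpatch]
      for (pass in 1:2) {
        dmat <- .cdist(Ct[np_idx, , drop = FALSE], Pt)
        dmin <- apply(dmat, 1, min)
        bad <- which(dmin < excl)
        if (!length(bad)) break
        for (b in bad) {
          j <- which.min(dmat[b, ])
          away <- Ct[np_idx[b], ] - Pt[j, ]
          away <- away / max(sqrt(sum(away^2)), 1e-9)
          Ct[np_idx[b], ] <- Pt[j, ] + away * excl
        }
      }
    }
    coords[t, , ] <- rbind(Pt, Ct)
  }
  st <- .system_topology(pep_beads, cluster$beads)
  traj <- trajectory((seq_len(n) - 1) * spec$dt, coords,
                     molecules = st$molecules, topology = st$topology)
  list(trajectory = traj,
       truth = .truth(spec, patch_ligand_ids = patch,
                      bound = rep(TRUE, n),
                      confinement_radius = nm_to_ang(Rconf)))
}
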