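test_that("bd_step drift is exact and noise variance matches theory", {
  cfg <- docking_config()
  D_rel <- (cfg$D_trans_peptide + cfg$D_trans_cluster) * 100  # nm^2/ps
  pose <- docked_pose(1, c(0, 0, 0))
  # deterministic drift: dr = D_rel F dt
  F <- c(1, -2, 0.5)
  p2 <- bd_step(pose, F, c(0, 0, 0), dt = 1, cfg, noise = FALSE)
  expect_equal(p2$displacement, D_rel * F * 1, tolerance = 1e-12)
  # zero force: per-axis displacement variance 2 D_rel dt within 5%
  set.seed(11)
  n <- 1e5
  steps <- matrix(0, n, 3)
  p <- pose
  for (i in seq_len(n)) {
    pn <- bd_step(p, dt = 1, config = cfg)
    steps[i, ] <- pn$displacement - p$displacement
    p <- pn
  }
  v <- apply(steps, 2, var)
  expect_equal(unname(v), rep(2 * D_rel, 3), tolerance = 0.05)
  expect_error(bd_step(pose, dt = 0, config = cfg), "dt")
})

test_that("the timestep schedule honours the fine-step distance", {
  cfg <- docking_config()
  expect_equal(bd_timestep(49, cfg), 1)
  expect_gt(bd_timestep(200, cfg), 1)
  expect_lte(bd_timestep(1e4, cfg), cfg$dt_max)
})

test_that("free BD diffusion has MSD slope 6 D_rel", {
  cfg <- docking_config()
  D_rel <- (cfg$D_trans_peptide + cfg$D_trans_cluster) * 100  # nm^2/ps
  set.seed(5)
  reps <- lapply(1:10, function(r) {
    p <- docked_pose(1, c(0, 0, 0))
    out <- matrix(0, 3000, 3)
    for (i in 1:3000) {
      p <- bd_step(p, dt = 1, config = cfg)
      out[i, ] <- p$displacement
    }
    out
  })
  res <- ensemble_msd(reps, times = 1:3000, lags = seq(5, 300, by = 5),
                      fit_window = c(5, 300))
  slope_nm2 <- res$D_fit * 100 * 6   # back to nm^2/ps
  expect_equal(slope_nm2, 6 * D_rel, tolerance = 0.05)
  expect_equal(res$alpha, 1, tolerance = 0.05)
})

test_that("Metropolis conformer exchange follows the acceptance law", {
  expect_true(metropolis_accept(-5))
  set.seed(1)
  expect_false(any(replicate(50, metropolis_accept(1e6))))
  # dU = +1 kT acceptance ratio e^-1 within 2%
  set.seed(2)
  acc <- mean(replicate(1e5, metropolis_accept(1)))
  expect_equal(acc, exp(-1), tolerance = 0.02)
})

test_that("conformer swaps preserve pose and satisfy detailed balance", {
  pep <- build_peptide("HWDDD", c("extended", "horseshoe"))
  E <- c(0, 1.2)  # kT, conformer-dependent only
  efn <- function(p) E[p$conformer_index]
  pose <- docked_pose(1, c(5, 0, 0), quat_random())
  p2 <- metropolis_conformer_swap(pose, pep, config = docking_config(),
                                  energy_fn = efn)
  expect_equal(p2$displacement, pose$displacement)
  expect_equal(p2$orientation, pose$orientation)
  # occupancy ratio exp(-(E2 - E1)) over a long swap chain, within 3%
  set.seed(7)
  n <- 2e5
  state <- integer(n)
  p <- pose
  for (i in seq_len(n)) {
    p <- metropolis_conformer_swap(p, pep, config = docking_config(),
                                   energy_fn = efn)
    state[i] <- p$conformer_index
  }
  ratio <- mean(state == 2) / mean(state == 1)
  expect_equal(ratio, exp(-(E[2] - E[1])), tolerance = 0.03)
})

test_that("run_docking honours its store and normalization contracts", {
  pep <- build_peptide("HWDDD", c("extended", "horseshoe"))
  clus <- build_nanocluster(n_core = 20, n_ligands = 20, chain_beads = 4)
  cfg <- docking_config(n_runs = 4, run_length = 0.01, n_record = 15,
                        start_separation = 40, escape_radius = 150,
                        record_every = 2, rng_seed = 3)
  res <- run_docking(pep, clus, cfg)
  expect_equal(sum(res$visit_fractions), 1, tolerance = 1e-12)
  expect_lte(length(res$poses), cfg$n_record)
  expect_gt(length(res$poses), 0)
  # store sorted by increasing energy
  expect_true(!is.unsorted(res$energies))
  # stored poses mutually distinct by > rmsd_distinct
  if (length(res$poses) > 1) {
    crd <- lapply(res$poses, function(p) bead_coords(pose_coords(p, pep)))
    for (a in 1:(length(crd) - 1)) for (b in (a + 1):length(crd))
      expect_gt(rmsd(crd[[a]], crd[[b]], superpose = FALSE),
                cfg$rmsd_distinct)
  }
  # three-term identity on every emitted pose
  for (p in res$poses)
    expect_equal(p$energy$U_repr,
                 p$energy$U_EP + p$energy$U_dse + p$energy$U_dsh,
                 tolerance = 1e-9)
})

test_that("a purely repulsive system records only positive energies", {
  pep <- build_peptide("KKK", c("extended", "horseshoe"))  # net +3
  clus <- build_nanocluster(n_core = 10, n_ligands = 12, chain_beads = 3)
  cfg <- docking_config(n_runs = 2, run_length = 0.005, n_record = 10,
                        start_separation = 30, escape_radius = 120,
                        record_every = 2, rng_seed = 9)
  res <- suppressWarnings(run_docking(pep, clus, cfg))
  if (length(res$energies))
    expect_true(all(res$energies > 0))
})
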