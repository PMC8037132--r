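test_that("generators are bitwise deterministic under a fixed seed", {
  s1 <- generator_spec("free_diffusion", dt = 1, n_frames = 500, seed = 5,
                       D_trans = 0.27e-5)
  expect_identical(gen_free_diffusion(s1)$trajectory$coords,
                   gen_free_diffusion(s1)$trajectory$coords)
  s2 <- generator_spec("rotational_diffusion", dt = 0.1, n_frames = 500,
                       seed = 5, D_rot = 30.7e-5)
  expect_identical(gen_rotational_diffusion(s2)$quats,
                   gen_rotational_diffusion(s2)$quats)
  s3 <- generator_spec("staged_association", dt = 10, n_frames = 60,
                       seed = 5, stage_distances = c(25, 16),
                       stage_frames = c(30, 30))
  expect_identical(gen_staged_association(s3)$trajectory$coords,
                   gen_staged_association(s3)$trajectory$coords)
  s4 <- generator_spec("conformer_chain", dt = 100, n_frames = 50,
                       seed = 5, switch_rate = 1)
  expect_identical(gen_conformer_chain(s4, "HWDDD")$trajectory$coords,
                   gen_conformer_chain(s4, "HWDDD")$trajectory$coords)
  pep <- build_peptide("HWDDD")
  clus <- build_nanocluster(n_core = 10, n_ligands = 12, chain_beads = 3)
  s5 <- generator_spec("bound_complex", dt = 10, n_frames = 20, seed = 5,
                       patch_ligand_ids = c(1, 2))
  expect_identical(gen_bound_complex(s5, pep, clus)$trajectory$coords,
                   gen_bound_complex(s5, pep, clus)$trajectory$coords)
})

test_that("free-diffusion increments have the stated variance", {
  # D = 0 -> static
  g0 <- gen_free_diffusion(generator_spec(
    "free_diffusion", dt = 1, n_frames = 50, seed = 1, D_trans = 0))
  expect_true(all(g0$trajectory$coords == 0))
  # increment variance 2 D dt within 3%
  D <- 0.27e-5
  g <- gen_free_diffusion(generator_spec(
    "free_diffusion", dt = 1, n_frames = 2e5, seed = 2, D_trans = D))
  x <- com_series(g$trajectory, "peptide")
  v <- apply(diff(x), 2, var)
  expect_equal(unname(v), rep(2 * D * 100, 3), tolerance = 0.03)
  expect_error(generator_spec("free_diffusion", dt = 0), "dt")
})

test_that("rotational generator keeps unit quaternions and its decay law", {
  g0 <- gen_rotational_diffusion(generator_spec(
    "rotational_diffusion", dt = 0.1, n_frames = 200, seed = 1,
    D_rot = 0))
  expect_true(all(g0$quats[, 1] == 1))
  g <- gen_rotational_diffusion(generator_spec(
    "rotational_diffusion", dt = 0.1, n_frames = 5e4, seed = 3,
    D_rot = 30.7e-5))
  expect_true(all(abs(rowSums(g$quats^2) - 1) < 1e-8))
  fit <- fit_rotational_diffusion(g$quats, g$times)
  expect_equal(fit$D_rot, 30.7e-5, tolerance = 0.10)
  expect_warning(gen_rotational_diffusion(generator_spec(
    "rotational_diffusion", dt = 100, n_frames = 120, seed = 1,
    D_rot = 30.7e-5)), "dt too large")
})

test_that("staged association hits its stage means and labels", {
  spec <- generator_spec("staged_association", dt = 10, n_frames = 3000,
                         seed = 13, stage_distances = c(25, 17, 16),
                         stage_frames = c(1000, 1000, 1000), sigma = 0.5,
                         tau_frames = 25)
  g <- gen_staged_association(spec)
  pr <- association_profile(g$trajectory)
  for (s in 1:3)
    expect_lt(abs(mean(pr$d_com[g$truth$stage_labels == s]) -
                    c(25, 17, 16)[s]), 0.2)
  # labels partition all frames
  expect_identical(length(g$truth$stage_labels), n_frames(g$trajectory))
  expect_identical(sort(unique(g$truth$stage_labels)), 1:3)
  # single stage: constant-mean OU
  g1 <- gen_staged_association(generator_spec(
    "staged_association", dt = 10, n_frames = 500, seed = 2,
    stage_distances = 20, stage_frames = 500, sigma = 0.5,
    tau_frames = 20))
  d1 <- association_profile(g1$trajectory)$d_com
  expect_lt(abs(mean(d1) - 20), 0.3)
  expect_lt(sd(d1), 1.5)
  # overlapping stage means warn
  expect_warning(gen_staged_association(generator_spec(
    "staged_association", dt = 10, n_frames = 40, seed = 1,
    stage_distances = c(20, 20.1), stage_frames = c(20, 20),
    sigma = 0.5)), "unidentifiable")
})

test_that("conformer chain switches with Markov statistics", {
  # switch rate 0, started extended: end-to-end constant up to noise
  g0 <- gen_conformer_chain(generator_spec(
    "conformer_chain", dt = 100, n_frames = 200, seed = 3,
    switch_rate = 0, noise_sigma = 0.3), "HWDDD")
  e2e <- sapply(seq_len(200), function(f)
    end_to_end(set_bead_coords(g0$peptide$conformers[[1]],
                               frame_coords(g0$trajectory, f))))
  expect_equal(mean(e2e), 17.8, tolerance = 0.05)
  expect_lt(sd(e2e), 1.5)
  # symmetric rates -> 50/50 occupancy within 2%
  g <- gen_conformer_chain(generator_spec(
    "conformer_chain", dt = 100, n_frames = 4e4, seed = 17,
    switch_rate = 1, noise_sigma = 0.3), "HWDDD")
  occ <- mean(g$truth$conformer_labels == 1)
  expect_equal(occ, 0.5, tolerance = 0.04)  # 2% absolute
  # end-to-end distribution is bimodal (cross-module consistency)
  e2e_all <- sapply(seq_len(2000), function(f)
    end_to_end(set_bead_coords(g$peptide$conformers[[1]],
                               frame_coords(g$trajectory, f))))
  expect_identical(distribution(e2e_all, n_bins = 40)$mode_count, 2L)
  expect_warning(gen_conformer_chain(generator_spec(
    "conformer_chain", dt = 1000, n_frames = 50, seed = 1,
    switch_rate = 500, noise_sigma = 0.3), "HWDDD"), "dwell")
})

test_that("bound complex confines the peptide and pins its patch", {
  pep <- build_peptide("HWDDD")
  clus <- build_nanocluster()
  patch <- c(12L, 26L, 33L)
  g <- gen_bound_complex(generator_spec(
    "bound_complex", dt = 10, n_frames = 1500, seed = 23,
    patch_ligand_ids = patch, confinement_radius = 2,
    noise_sigma = 0.3), pep, clus)
  # exact patch recovery from contacts
  ct <- ligand_contacts(g$trajectory, cutoff = 3.0)
  expect_identical(sort(as.integer(ct$ligand_ids[ct$P > 0.5])),
                   sort(patch))
  # sub-linear MSD at long lags
  pos <- com_series(g$trajectory, "peptide")
  res <- msd(pos, g$trajectory$times, lags = seq(500, 5000, by = 250),
             fit_window = c(500, 5000))
  expect_lt(res$alpha, 0.9)
  # plateau near the confinement scale 6 sigma_axis^2 = 2 R^2
  expect_lt(abs(mean(res$msd[res$lags > 2000]) - 2 * 2^2) , 4)
  expect_error(gen_bound_complex(generator_spec(
    "bound_complex", dt = 10, n_frames = 10, seed = 1,
    patch_ligand_ids = 999), pep, clus), "patch")
})
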