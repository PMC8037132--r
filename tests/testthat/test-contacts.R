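test_that("ligand_contacts computes inclusive-cutoff probabilities", {
  # 3 ligands: #1 always at 2 A, #2 never closer than 10 A, #3 at 2 A in
  # exactly half the frames
  nf <- 10
  pep <- matrix(0, nf, 3)
  term <- lapply(seq_len(nf), function(f) rbind(
    c(0.2, 0, 0),
    c(1.0, 0, 0),
    if (f <= 5) c(0, 0.2, 0) else c(0, 2, 0)))
  tr <- make_contact_traj(pep, term)
  ct <- ligand_contacts(tr, cutoff = 3.0)
  expect_equal(unname(ct$P), c(1, 0, 0.5))
  # inclusive boundary: a ligand at exactly 3.0 A counts
  term_b <- list(matrix(c(0.3, 0, 0), 1))
  trb <- make_contact_traj(matrix(0, 1, 3), term_b)
  expect_equal(unname(ligand_contacts(trb, cutoff = 3.0)$P), 1)
  # brute-force oracle over all fixture frames
  P_oracle <- sapply(1:3, function(l)
    mean(sapply(seq_len(nf), function(f)
      sqrt(sum((term[[f]][l, ] - pep[f, ])^2)) <= 0.3)))
  expect_equal(unname(ct$P), P_oracle)
  # untagged topology errors
  tr2 <- tr; tr2$topology$name[2:4] <- "CX"
  expect_error(ligand_contacts(tr2), "terminal-N")
})

test_that("simultaneous contacts match hand enumeration", {
  nf <- 12
  pep <- matrix(0, nf, 3)
  near <- c(0.2, 0, 0); far <- c(3, 0, 0)
  # ligand 1 in contact frames 1-8, ligand 2 frames 5-12, ligand 3 never
  term <- lapply(seq_len(nf), function(f) rbind(
    if (f <= 8) near else far,
    if (f >= 5) c(0, 0.2, 0) else far,
    far + c(0, 0, 1)))
  ct <- ligand_contacts(make_contact_traj(pep, term))
  M <- simultaneous_contact_matrix(ct)
  expect_true(isSymmetric(M))
  expect_equal(unname(diag(M)), c(8L, 8L, 0L))
  expect_identical(M[1, 2], 4L)   # frames 5-8
  expect_identical(M[1, 3], 0L)
  # disjoint epochs -> zero off-diagonal
  term2 <- lapply(seq_len(nf), function(f) rbind(
    if (f <= 6) near else far,
    if (f > 6) c(0, 0.2, 0) else far))
  M2 <- simultaneous_contact_matrix(ligand_contacts(
    make_contact_traj(pep, term2)))
  expect_identical(M2[1, 2], 0L)
  # always-co-bound pair -> frame count
  term3 <- lapply(seq_len(nf), function(f) rbind(near, c(0, 0.2, 0)))
  M3 <- simultaneous_contact_matrix(ligand_contacts(
    make_contact_traj(pep, term3)))
  expect_identical(M3[1, 2], as.integer(nf))
})

test_that("inter_ligand_distances reports exact geometry", {
  nf <- 5
  term <- lapply(seq_len(nf), function(f) rbind(
    c(0, 0, 0), c(0.5, 0, 0), c(0, 1.2, 0)))
  tr <- make_contact_traj(matrix(5, nf, 3), term)
  res <- inter_ligand_distances(tr, c(1, 2, 3))
  expect_equal(dim(res$distances), c(nf, 3L))
  expect_equal(unname(res$pair_means), c(5, 12, 13), tolerance = 1e-12)
  expect_equal(unname(res$pair_sd), c(0, 0, 0))
  expect_equal(res$pooled_mean, 10)
  expect_error(inter_ligand_distances(tr, c(1, 99)), "unknown ligand")
  expect_error(inter_ligand_distances(tr, 1), ">= 2")
})

test_that("pair_correlation is flat for an ideal gas and exact for a spike", {
  box <- 5
  set.seed(71)
  nA <- 40; nB <- 40; nf <- 30
  coords <- array(runif(nf * (nA + nB) * 3, 0, box), c(nf, nA + nB, 3))
  top <- make_beads(matrix(0, nA + nB, 3))
  tr <- trajectory(seq_len(nf), coords, box_length = box,
                   molecules = list(A = 1:nA, B = (nA + 1):(nA + nB)),
                   topology = top)
  g <- pair_correlation(tr, 1:nA, (nA + 1):(nA + nB), r_max = 20,
                        shell_width = 2)
  expect_true(all(g$g >= 0))
  expect_lt(mean(abs(g$g - 1)), 0.15)
  expect_equal(mean(g$g), 1, tolerance = 0.10)
  # single fixed pair at 5.3 A: one count in its shell, hand-normalized
  c2 <- array(0, c(1, 2, 3)); c2[1, 2, 1] <- 0.53
  tr2 <- trajectory(1, c2, box_length = box,
                    molecules = list(A = 1L, B = 2L),
                    topology = make_beads(matrix(0, 2, 3)))
  g2 <- pair_correlation(tr2, 1, 2, r_max = 10, shell_width = 1)
  k <- findInterval(5.3, seq(0, 10, 1))
  rc <- pepmpc:::ang_to_nm(g2$r_centers[k])
  hand <- 1 / (4 * pi * rc^2 * 0.1 * (1 / box^3))
  expect_equal(g2$g[k], hand, tolerance = 1e-9)
  expect_true(all(g2$g[-k] == 0))
  expect_error(pair_correlation(tr2, 1, 2, r_max = 30), "box/2")
})

test_that("hbond_count applies distance and angle criteria", {
  # ideal linear bond at 2.8 A: D at 0, H at 1 A, A at 2.8 A along +x
  b <- make_beads(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.28, 0, 0)))
  donors <- data.frame(D = 1L, H = 2L)
  expect_identical(hbond_count(b, donors, 3L), 1L)
  # too far
  b2 <- make_beads(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.5, 0, 0)))
  expect_identical(hbond_count(b2, donors, 3L), 0L)
  # 90-degree geometry at 2.8 A fails the angle filter
  b3 <- make_beads(rbind(c(0, 0, 0), c(0.1, 0, 0), c(0.1, 0.28, 0)))
  expect_identical(hbond_count(b3, donors, 3L), 0L)
  expect_error(hbond_count(b, data.frame(D = 1L, H = NA), 3L), "hydrogen")
})

test_that("rmsd with superposition matches the quaternion-method oracle", {
  expect_equal(rmsd(diag(3), diag(3)), 0)
  set.seed(81)
  A <- matrix(rnorm(30), 10, 3)
  # rigidly transformed copy superposes to zero
  R <- quat_to_matrix(quat_random())
  B <- sweep(A %*% t(R), 2, c(1, -2, 0.5), "+")
  expect_lt(rmsd(A, B, superpose = TRUE), 1e-6)
  expect_gt(rmsd(A, B, superpose = FALSE), 1)
  # random pairs: Kabsch equals Horn's quaternion method to 1e-9
  for (i in 1:5) {
    X <- matrix(rnorm(24), 8, 3)
    Y <- X + matrix(rnorm(24, 0, 0.3), 8, 3)
    expect_equal(rmsd(X, Y, superpose = TRUE), horn_rmsd(X, Y),
                 tolerance = 1e-9)
  }
  expect_error(rmsd(A, A[1:5, ]), "mismatched")
})

test_that("gromos_cluster recovers generator families and is monotone", {
  expect_identical(
    gromos_cluster(replicate(6, diag(3) * 0.1, simplify = FALSE),
                   cutoff = 0.1)$sizes, 6L)
  g <- gen_conformer_chain(generator_spec(
    "conformer_chain", dt = 100, n_frames = 300, seed = 91,
    switch_rate = 0.5, noise_sigma = 0.3), "HWDDD")
  frames <- lapply(seq_len(300), function(f)
    frame_coords(g$trajectory, f, "peptide"))
  cl <- gromos_cluster(frames, cutoff = 0.15)
  truth_sizes <- sort(table(g$truth$conformer_labels), decreasing = TRUE)
  expect_gte(length(cl$sizes), 2)
  expect_equal(sum(cl$sizes), 300L)
  # the two dominant clusters match the generator family sizes within 2%
  expect_equal(sort(cl$sizes, decreasing = TRUE)[1:2],
               as.integer(truth_sizes[1:2]), tolerance = 0.02,
               ignore_attr = TRUE)
  # membership respects the generator labels
  # cluster count non-increasing as the cutoff grows
  counts <- sapply(c(0.05, 0.1, 0.2, 0.4, 0.8),
                   function(cc) length(gromos_cluster(frames, cc)$sizes))
  expect_true(all(diff(counts) <= 0))
  expect_error(gromos_cluster(frames, cutoff = 0), "cutoff")
})

test_that("native_contact_map follows chain geometry", {
  h3 <- build_peptide("HHHWDDD", c("extended", "horseshoe"))
  # fully extended: minimum |i-j| >= 3 distance is 11.4 A > 6.5 A
  m_ext <- native_contact_map(h3$conformers[[1]],
                              list(bead_coords(h3$conformers[[1]])))
  expect_identical(nrow(m_ext$pairs), 0L)
  expect_true(is.na(m_ext$Q))
  # horseshoe holds the (1,6)-type terminal contact; Q(reference) = 1
  m_h <- native_contact_map(h3$conformers[[2]],
                            list(bead_coords(h3$conformers[[2]])))
  expect_true(any(m_h$pairs$i == 1 & m_h$pairs$j == 6))
  expect_equal(m_h$Q, 1)
  # an extended frame loses those contacts
  m_x <- native_contact_map(h3$conformers[[2]],
                            list(bead_coords(h3$conformers[[1]])))
  expect_equal(m_x$Q, 0)
  expect_error(native_contact_map(h3$conformers[[2]],
                                  list(bead_coords(h3$conformers[[2]])),
                                  seq_sep = 0), "seq_sep")
})
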