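test_that("com is the mass-weighted mean", {
  expect_equal(com(rbind(c(0, 0, 0), c(2, 0, 0))), c(1, 0, 0))
  expect_equal(com(c(4, 5, 6)), c(4, 5, 6))
  expect_equal(com(rbind(c(0, 0, 0), c(4, 0, 0)), masses = c(1, 3)),
               c(3, 0, 0))
  expect_error(com(rbind(c(0, 0, 0)), masses = 0), "total mass")
})

test_that("association_profile reproduces geometry and matches brute force", {
  # static pair 16 Angstrom apart along z
  n <- 20
  coords <- array(0, c(n, 2, 3))
  coords[, 1, 3] <- 1.6
  tr <- trajectory(seq_len(n), coords,
                   molecules = list(peptide = 1L, cluster = 2L))
  pr <- association_profile(tr)
  expect_equal(pr$d_com, rep(16, n))
  expect_equal(pr$theta, rep(0, n))
  # unit vector along +x
  coords2 <- array(0, c(1, 2, 3)); coords2[1, 1, 1] <- 1
  pr2 <- association_profile(trajectory(1, coords2,
    molecules = list(peptide = 1L, cluster = 2L)))
  expect_equal(pr2$theta, pi / 2)
  expect_equal(pr2$phi, 0)
  # coincident COMs flag NaN angles
  coords3 <- array(0, c(1, 2, 3))
  pr3 <- association_profile(trajectory(1, coords3,
    molecules = list(peptide = 1L, cluster = 2L)))
  expect_true(is.nan(pr3$theta))
  # synthetic staged trajectory: per-stage means within 0.5 A of truth,
  # and the distance equals the brute-force per-frame norm
  g <- gen_staged_association(generator_spec(
    "staged_association", dt = 10, n_frames = 2700, seed = 21,
    stage_distances = c(25, 17, 16), stage_frames = c(900, 900, 900),
    tau_frames = 20))
  pr4 <- association_profile(g$trajectory)
  for (s in 1:3)
    expect_equal(mean(pr4$d_com[g$truth$stage_labels == s]),
                 c(25, 17, 16)[s], tolerance = 0.5 / 16)
  brute <- sapply(seq_len(n_frames(g$trajectory)), function(f) {
    X <- frame_coords(g$trajectory, f)
    10 * sqrt(sum((X[1, ] - X[2, ])^2))
  })
  expect_equal(pr4$d_com, brute, tolerance = 1e-12)
})

test_that("segment_stages matches the exhaustive oracle and finds stages", {
  set.seed(31)
  # constant series + noise -> one segment
  y0 <- rnorm(120, 10, 0.3)
  expect_identical(segment_stages(y0)$n_segments, 1L)
  # 25 -> 17 -> 16 step series, sigma 0.5: breakpoints within 2%
  y <- c(rnorm(60, 25, 0.5), rnorm(60, 17, 0.5), rnorm(80, 16, 0.5))
  sg <- segment_stages(y, max_segments = 3, min_len = 5)
  expect_identical(sg$n_segments, 3L)
  expect_lt(abs(sg$breakpoints[1] - 61), 0.02 * length(y))
  expect_lt(abs(sg$breakpoints[2] - 121), 0.02 * length(y))
  expect_equal(sg$means, c(25, 17, 16), tolerance = 0.05)
  # equality with the brute-force oracle for series <= 200 frames
  for (rep_ in 1:3) {
    z <- c(rnorm(40, 0, 1), rnorm(50, 3, 1), rnorm(60, 1.5, 1))
    got <- segment_stages(z, max_segments = 3, min_len = 5)
    oracle <- brute_segment(z, got$n_segments, 5)
    expect_equal(got$rss, oracle$rss, tolerance = 1e-9)
    expect_identical(got$breakpoints, as.integer(oracle$bp))
  }
  expect_error(segment_stages(rnorm(10), max_segments = 3, min_len = 5),
               "too short")
})

test_that("Shrake-Rupley SASA matches analytic and dense-quadrature oracles", {
  # isolated bead r = 2 A, probe 1.4 A -> 4 pi 3.4^2
  b <- make_beads(c(0, 0, 0), radius = 0.2)
  expect_equal(sasa(b, probe_radius = 1.4), 4 * pi * 3.4^2,
               tolerance = 0.01)
  # two distant beads are additive
  b2 <- make_beads(rbind(c(0, 0, 0), c(10, 0, 0)), radius = 0.2)
  expect_equal(sum(sasa(b2)), 2 * 4 * pi * 3.4^2, tolerance = 0.01)
  # overlapping pair vs an independent dense Monte-Carlo quadrature
  b3 <- make_beads(rbind(c(0, 0, 0), c(0.25, 0, 0)),
                   radius = c(0.2, 0.15))
  got <- sum(sasa(b3, n_sphere_points = 960))
  set.seed(12)
  rr <- c(0.2, 0.15) + 0.14
  centers <- rbind(c(0, 0, 0), c(0.25, 0, 0))
  mc <- 0
  for (i in 1:2) {
    u <- matrix(rnorm(3 * 2e4), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    pts <- sweep(u * rr[i], 2, centers[i, ], "+")
    j <- 3 - i
    free <- rowSums(sweep(pts, 2, centers[j, ], "-")^2) >= rr[j]^2
    mc <- mc + mean(free) * 4 * pi * (10 * rr[i])^2
  }
  expect_equal(got, mc, tolerance = 0.02)
  expect_error(sasa(b, n_sphere_points = 5), "n_sphere_points")
})

test_that("radius_of_gyration and end_to_end follow their closed forms", {
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(0.4, 0, 0))), 2)
  expect_equal(radius_of_gyration(c(1, 2, 3)), 0)
  # unit tetrahedron vs direct sum
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  m <- c(1, 2, 3, 4)
  cm <- colSums(tet * m) / sum(m)
  oracle <- 10 * sqrt(sum(m * rowSums(sweep(tet, 2, cm)^2)) / sum(m))
  expect_equal(radius_of_gyration(tet, m), oracle, tolerance = 1e-12)

  p <- build_peptide("HWDDD", c("extended", "horseshoe"))
  # extended: 4 x 3.8 A CA spacing + 2 x 1.3 A termini offsets
  expect_equal(end_to_end(p$conformers[[1]]), 4 * 3.8 + 2 * 1.3,
               tolerance = 1e-9)
  expect_lt(end_to_end(p$conformers[[2]]), end_to_end(p$conformers[[1]]))
  # coincident termini
  b <- p$conformers[[1]]
  b[b$name == "CT", c("x", "y", "z")] <- b[b$name == "NT", c("x", "y", "z")]
  expect_equal(end_to_end(b), 0)
  expect_error(end_to_end(make_beads(c(0, 0, 0))), "NT/CT")
})

test_that("dihedral follows the IUPAC sign convention", {
  # planar trans (zigzag in a plane)
  expect_equal(abs(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
                            c(1, -1, 0))), pi)
  # planar cis
  expect_equal(dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0)), 0)
  # chirality: mirroring flips the sign
  p4 <- c(1, 0.5, 0.7)
  a <- dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), p4)
  b <- dihedral(c(0, 1, 0) * c(1, 1, -1), c(0, 0, 0), c(1, 0, 0),
                p4 * c(1, 1, -1))
  expect_equal(a, -b)
  expect_error(dihedral(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)),
               "collinear")
})

test_that("distribution normalizes and counts modes", {
  set.seed(41)
  d1 <- distribution(rnorm(1e4), n_bins = 40)
  expect_identical(d1$mode_count, 1L)
  expect_equal(sum(d1$density * diff(d1$bin_edges)), 1, tolerance = 1e-6)
  d2 <- distribution(c(rnorm(5e3, -2, 0.3), rnorm(5e3, 2, 0.3)),
                     n_bins = 40)
  expect_identical(d2$mode_count, 2L)
  # circular angles wrap
  ang <- c(rnorm(2e3, pi - 0.1, 0.2), rnorm(2e3, -pi + 0.1, 0.2))
  dc <- distribution(ang, circular = TRUE)
  expect_equal(sum(dc$density * diff(dc$bin_edges)), 1, tolerance = 1e-6)
  expect_identical(dc$mode_count, 1L)  # one mode across the wrap
  expect_error(distribution(numeric(0)), "empty")
})

test_that("msd reproduces ballistic, static and diffusive motion", {
  t <- 0:999
  # ballistic r = v t
  v <- c(0.01, 0.02, -0.005)
  pos <- outer(t, v)
  res <- msd(pos, t, lags = seq(10, 200, by = 10))
  expect_equal(res$alpha, 2, tolerance = 1e-6)
  expect_equal(res$msd, 100 * sum(v^2) * res$lags^2, tolerance = 1e-9)
  # static particle
  res0 <- msd(matrix(0, 100, 3), 0:99)
  expect_true(all(res0$msd == 0))
  expect_error(msd(pos, c(0:998, 1000.5)), "uniform")
  # free diffusion at the configured peptide coefficient, 5% recovery
  reps <- lapply(1:5, function(r)
    com_series(gen_free_diffusion(generator_spec(
      "free_diffusion", dt = 1, n_frames = 1e5, seed = 50 + r,
      D_trans = 0.27e-5))$trajectory))
  em <- ensemble_msd(reps, times = 0:(1e5 - 1),
                     lags = seq(10, 1000, by = 10),
                     fit_window = c(10, 1000))
  expect_equal(em$D_fit, 0.27e-5, tolerance = 0.05)
})

test_that("rotational diffusion fitting recovers generator truth", {
  # frozen orientation -> D = 0, correlation 1 at all lags
  qs <- matrix(rep(c(1, 0, 0, 0), each = 500), 500, 4)
  fit0 <- fit_rotational_diffusion(qs, 0:499)
  expect_equal(fit0$D_rot, 0)
  expect_equal(fit0$corr[1], 1)
  # generator recovery within 10%
  qlist <- lapply(1:3, function(r)
    gen_rotational_diffusion(generator_spec(
      "rotational_diffusion", dt = 0.1, n_frames = 5e4, seed = 60 + r,
      D_rot = 30.7e-5))$quats)
  fit <- fit_rotational_diffusion(qlist, seq(0, by = 0.1,
                                             length.out = 5e4))
  expect_equal(fit$D_rot, 30.7e-5, tolerance = 0.10)
  expect_error(fit_rotational_diffusion(qs * 2, 0:499), "unit norm")
})
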