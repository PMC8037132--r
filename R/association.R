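# Per-frame association observables (COM distance and spherical angles,
# stage segmentation), shape descriptors (SASA, distributions), MSD and
# diffusion fitting. Interface units: Angstrom / Angstrom^2 / cm^2/s;
# radians internally for angles.

#' Centre-of-mass association profile
#'
#' Per frame: the COM-COM distance between the two molecules (minimum
#' image under the periodic box) and the spherical angles of the
#' COM-COM vector in the cluster frame (`theta = acos(z/d)`,
#' `phi = atan2(y, x)`). Frames with coincident COMs get NaN angles.
#'
#' @param traj a `trajectory` containing both molecules
#' @param peptide,cluster molecule names in `traj$molecules`
#' @param masses_peptide,masses_cluster optional per-bead masses
#' @return an object of class `association_profile`: list with `times`
#'   (ps), `d_com` (Angstrom), `theta`, `phi` (rad), `stage_labels`
#'   (NA until [segment_stages()] is applied)
#' @export
association_profile <- function(traj, peptide = "peptide",
                                cluster = "cluster",
                                masses_peptide = NULL,
                                masses_cluster = NULL) {
  for (m in c(peptide, cluster))
    if (!m %in% names(traj$molecules))
      stop("trajectory lacks molecule: ", m)
  cp <- com_series(traj, peptide, masses_peptide)
  cc <- com_series(traj, cluster, masses_cluster)
  dv <- min_image(cp - cc, traj$box_length)
  d <- sqrt(rowSums(dv^2))
  theta <- ifelse(d > 1e-12, acos(pmin(1, pmax(-1, dv[, 3] / d))), NaN)
  phi <- ifelse(d > 1e-12, atan2(dv[, 2], dv[, 1]), NaN)
  structure(list(times = traj$times, d_com = nm_to_ang(d),
                 theta = theta, phi = phi,
                 stage_labels = rep(NA_integer_, length(d))),
            class = "association_profile")
}

#' Piecewise-constant stage segmentation of a series
#'
#' Exact least-squares segmentation into at most `max_segments`
#' piecewise-constant pieces (dynamic programming over all admissible
#' breakpoints, so the optimum for each segment count is global), with
#' the number of segments selected by BIC.
#'
#' @param series numeric vector (e.g. a COM-distance track)
#' @param max_segments maximum number of segments (>= 1)
#' @param min_len minimum frames per segment
#' @return list with `n_segments`, `breakpoints` (first frame index of
#'   segments 2..k; empty when one segment), `means` (per segment),
#'   `labels` (per-frame segment id), `rss`, `bic` (per candidate k)
#' @export
segment_stages <- function(series, max_segments = 3, min_len = 5) {
  y <- as.numeric(series)
  n <- length(y)
  if (max_segments < 1) stop("max_segments must be >= 1")
  if (n < max_segments * min_len)
    stop("series too short for requested segmentation")
  S1 <- c(0, cumsum(y)); S2 <- c(0, cumsum(y^2))
  segcost <- function(i, j) {  # cost of segment i..j (1-based, inclusive)
    m <- j - i + 1
    (S2[j + 1] - S2[i]) - (S1[j + 1] - S1[i])^2 / m
  }
  # DP: C[k, j] = min RSS of y[1..j] in k segments
  kmax <- max_segments
  C <- matrix(Inf, kmax, n)
  B <- matrix(NA_integer_, kmax, n)  # start index of last segment
  for (j in min_len:n) C[1, j] <- segcost(1, j)
  if (kmax > 1) for (k in 2:kmax) {
    for (j in (k * min_len):n) {
      i_cand <- ((k - 1) * min_len + 1):(j - min_len + 1)
      vals <- C[k - 1, i_cand - 1] + segcost(i_cand, j)
      b <- which.min(vals)
      C[k, j] <- vals[b]; B[k, j] <- i_cand[b]
    }
  }
  rss_k <- C[, n]
  # BIC with k means + (k-1) breakpoints as parameters
  ks <- seq_len(kmax)
  bic <- n * log(pmax(rss_k, 1e-12) / n) + (2 * ks - 1) * log(n)
  k_best <- ks[which.min(bic)]
  # backtrack
  bp <- integer(0); j <- n
  for (k in rev(seq_len(k_best))) {
    if (k == 1) break
    i <- B[k, j]
    bp <- c(i, bp)
    j <- i - 1
  }
  starts <- c(1L, bp); ends <- c(bp - 1L, n)
  labels <- integer(n); means <- numeric(k_best)
  for (s in seq_len(k_best)) {
    labels[starts[s]:ends[s]] <- s
    means[s] <- mean(y[starts[s]:ends[s]])
  }
  list(n_segments = k_best, breakpoints = bp, means = means,
       labels = labels, rss = rss_k[k_best], bic = bic)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Test points on each bead's probe-expanded sphere (Fibonacci lattice);
#' a point is accessible when it is not buried inside any neighbour's
#' expanded sphere. Per-bead SASA is the accessible fraction times
#' `4 pi (r + probe)^2`.
#'
#' @param beads a bead table (radii in nm)
#' @param probe_radius probe radius, Angstrom
#' @param n_sphere_points quadrature points per bead (>= 10)
#' @return numeric vector of per-bead SASA, Angstrom^2
#' @export
sasa <- function(beads, probe_radius = 1.4, n_sphere_points = 960) {
  if (n_sphere_points < 10) stop("n_sphere_points must be >= 10")
  probe <- ang_to_nm(probe_radius)
  xyz <- bead_coords(beads)
  rr <- beads$radius + probe
  n <- nrow(xyz)
  pts0 <- fibonacci_sphere(n_sphere_points)
  out <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(pts0 * rr[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_sphere_points)
    for (j in seq_len(n)) {
      if (j == i) next
      dij <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (dij >= rr[i] + rr[j]) next
      d2 <- rowSums(sweep(pts, 2, xyz[j, ], "-")^2)
      acc <- acc & (d2 >= rr[j]^2)
      if (!any(acc)) break
    }
    out[i] <- mean(acc) * 4 * pi * nm_to_ang(rr[i])^2
  }
  out
}

#' Histogram/density summary of a series
#'
#' Normalized histogram plus a kernel-smoothed mode count: modes are
#' local maxima of the smoothed density exceeding `prominence` times
#' the global maximum. Circular series are wrapped onto (-pi, pi] and
#' smoothed with periodic replication; their mean and spread are the
#' circular mean and circular SD.
#'
#' @param series numeric vector (non-empty)
#' @param n_bins histogram bins
#' @param circular logical, treat values as angles
#' @param prominence mode threshold as a fraction of the density maximum
#' @return list with `bin_edges`, `density` (integrates to 1),
#'   `mode_count`, `mean`, `spread`
#' @export
distribution <- function(series, n_bins = 50, circular = FALSE,
                         prominence = 0.10) {
  x <- as.numeric(series)
  if (!length(x)) stop("empty series")
  if (circular) {
    x <- ((x + pi) %% (2 * pi)) - pi
    edges <- seq(-pi, pi, length.out = n_bins + 1)
    xs <- c(x - 2 * pi, x, x + 2 * pi)
    den <- stats::density(xs, n = 1024, from = -pi, to = pi)
    den$y <- den$y * 3  # renormalize for the replication
    mu <- atan2(mean(sin(x)), mean(cos(x)))
    R <- sqrt(mean(sin(x))^2 + mean(cos(x))^2)
    spread <- sqrt(pmax(0, -2 * log(R)))
  } else {
    rng <- range(x)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
    den <- stats::density(x, n = 1024, from = rng[1], to = rng[2])
    mu <- mean(x); spread <- stats::sd(x)
  }
  h <- graphics::hist(x, breaks = edges, plot = FALSE)
  dens <- h$density
  y <- den$y
  thr <- prominence * max(y)
  is_max <- which(diff(sign(diff(y))) == -2) + 1
  mode_count <- max(1L, sum(y[is_max] >= thr))
  if (length(unique(x)) == 1) mode_count <- 1L
  list(bin_edges = edges, density = dens, mode_count = mode_count,
       mean = mu, spread = spread)
}

#' Time-averaged mean squared displacement with diffusion fit
#'
#' \eqn{MSD(\tau) = \langle |r(t+\tau) - r(t)|^2 \rangle} over all valid
#' time origins. `D_fit` comes from a through-origin linear fit
#' `MSD = 6 D tau` over `fit_window`; `alpha` is the log-log slope over
#' the same window (1 = normal diffusion, < 1 subdiffusive).
#'
#' @param positions n x 3 matrix of COM positions, nm
#' @param times frame times, ps (must be uniformly spaced)
#' @param lags lag times to evaluate, ps; default an ~100-point grid up
#'   to a quarter of the trajectory
#' @param fit_window `c(min, max)` lag range for the fits, ps; default
#'   10--25% of the largest evaluated lag
#' @return an object of class `msd_result`: list with `lags` (ps),
#'   `msd` (Angstrom^2), `D_fit` (cm^2/s), `alpha`, `fit_window`
#' @export
msd <- function(positions, times, lags = NULL, fit_window = NULL) {
  x <- matrix(positions, ncol = 3)
  n <- nrow(x)
  if (n < 2) stop("need >= 2 frames")
  dt <- diff(times)
  if (any(abs(dt - dt[1]) > 1e-9 * max(abs(dt))))
    stop("msd requires uniformly spaced times")
  dt <- dt[1]
  if (is.null(lags)) {
    max_lag <- max(1, floor((n - 1) / 4))
    lag_frames <- unique(round(seq(1, max_lag, length.out = min(100, max_lag))))
    lags <- lag_frames * dt
  } else {
    lag_frames <- unique(round(lags / dt))
    lag_frames <- lag_frames[lag_frames >= 1 & lag_frames < n]
    if (!length(lag_frames)) stop("no valid lags")
    lags <- lag_frames * dt
  }
  m <- vapply(lag_frames, function(L) {
    d <- x[(1 + L):n, , drop = FALSE] - x[1:(n - L), , drop = FALSE]
    mean(rowSums(d^2))
  }, numeric(1))
  m_ang2 <- m * 100  # nm^2 -> Angstrom^2
  .msd_fit(lags, m_ang2, fit_window)
}

# fit D and alpha from an MSD curve (lags ps, msd Angstrom^2)
.msd_fit <- function(lags, msd_ang2, fit_window = NULL) {
  if (is.null(fit_window))
    fit_window <- c(0.10, 0.25) * max(lags)
  sel <- lags >= fit_window[1] & lags <= fit_window[2]
  if (sum(sel) < 2) sel <- rep(TRUE, length(lags))
  slope <- sum(lags[sel] * msd_ang2[sel]) / sum(lags[sel]^2)
  D_fit <- ang2_per_ps_to_cm2_per_s(slope / 6)
  pos <- sel & msd_ang2 > 0
  alpha <- if (sum(pos) >= 2)
    unname(stats::coef(stats::lm(log(msd_ang2[pos]) ~ log(lags[pos])))[2])
  else NA_real_
  structure(list(lags = lags, msd = msd_ang2, D_fit = D_fit,
                 alpha = alpha, fit_window = fit_window),
            class = "msd_result")
}

#' Ensemble MSD over replicate trajectories
#'
#' Averages the per-replica time-averaged MSD curves at common lags and
#' fits D and alpha on the ensemble curve.
#'
#' @param positions_list list of n x 3 position matrices, nm
#' @param times common frame times, ps
#' @inheritParams msd
#' @return an `msd_result` for the ensemble-averaged curve
#' @export
ensemble_msd <- function(positions_list, times, lags = NULL,
                         fit_window = NULL) {
  res <- lapply(positions_list, msd, times = times, lags = lags,
                fit_window = fit_window)
  curves <- vapply(res, `[[`, numeric(length(res[[1]]$msd)), "msd")
  .msd_fit(res[[1]]$lags, rowMeans(curves), fit_window)
}

#' Rotational diffusion coefficient from an orientation series
#'
#' Fits the body-axis orientation autocorrelation to
#' `exp(-2 D_r tau)` (through-origin fit of `log C` against lag over
#' the window where `C > corr_floor`). The autocorrelation is averaged
#' over all three body axes via the relative-quaternion trace identity
#' `C(tau) = (4 (q(t) . q(t+tau))^2 - 1) / 3 = Tr R_rel / 3`, whose
#' expectation for isotropic rotational diffusion equals the single-axis
#' `exp(-2 D_r tau)` with three times the statistics.
#'
#' @param quats n x 4 matrix of unit quaternions (w, x, y, z), or a list
#'   of such matrices (replicas; autocorrelations are averaged)
#' @param times frame times, ps (uniform spacing)
#' @param n_lags number of lag points evaluated
#' @param corr_floor smallest autocorrelation used in the fit
#' @return list with `D_rot` (rad^2/ps), `lags` (ps), `corr`
#' @export
fit_rotational_diffusion <- function(quats, times, n_lags = 100,
                                     corr_floor = 0.4) {
  if (!is.list(quats)) quats <- list(quats)
  n <- nrow(quats[[1]])
  if (n < 100) stop("need >= 100 frames")
  dt <- diff(times)[1]
  lag_frames <- unique(round(seq(1, floor((n - 1) / 2),
                                 length.out = n_lags)))
  corr_all <- matrix(0, length(lag_frames), length(quats))
  for (r in seq_along(quats)) {
    q <- quats[[r]]
    if (any(abs(rowSums(q^2) - 1) > 1e-6))
      stop("quaternions must be unit norm")
    corr_all[, r] <- vapply(lag_frames, function(L) {
      dq <- rowSums(q[(1 + L):n, , drop = FALSE] *
                      q[1:(n - L), , drop = FALSE])
      mean((4 * dq^2 - 1) / 3)
    }, numeric(1))
  }
  corr <- rowMeans(corr_all)
  lags <- lag_frames * dt
  sel <- corr > corr_floor
  if (sum(sel) < 2) stop("autocorrelation decays too fast for the lag grid")
  D <- -sum(lags[sel] * log(corr[sel])) / sum(lags[sel]^2) / 2
  list(D_rot = D, lags = lags, corr = corr)
}
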