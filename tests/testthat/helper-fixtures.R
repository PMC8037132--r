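# Shared fixture builders. Everything is generated in code; no binary
# fixtures.

# a bare bead table with positions (nm) and optional charges
make_beads <- function(pos, charge = 0, name = "X", element = "generic",
                       residue_index = NULL, radius = 0.15) {
  pos <- matrix(pos, ncol = 3)
  n <- nrow(pos)
  if (is.null(residue_index)) residue_index <- seq_len(n)
  bead_df(seq_len(n), rep_len(name, n), residue_index,
          rep_len("UNK", n), rep_len(element, n), pos,
          charge = charge, radius = radius)
}

# trajectory of a single molecule from an [frames x beads x 3] array or a
# frames x 3 matrix (one bead)
make_traj <- function(coords, dt = 1, box_length = NULL, topology = NULL,
                      molecules = NULL) {
  if (length(dim(coords)) == 2)
    coords <- array(coords, c(nrow(coords), 1, 3))
  trajectory((seq_len(dim(coords)[1]) - 1) * dt, coords,
             box_length = box_length, molecules = molecules,
             topology = topology)
}

# two-molecule (peptide bead + cluster with terminal N sites) trajectory
# with prescribed per-frame terminal-N positions. term_pos: list per frame
# of n_lig x 3 matrices; pep_pos: frames x 3 matrix.
make_contact_traj <- function(pep_pos, term_pos, dt = 1, box_length = NULL) {
  nf <- nrow(pep_pos); nl <- nrow(term_pos[[1]])
  pep_top <- bead_df(1, "CA", 1, "GLY", "C", matrix(0, 1, 3))
  clus_top <- bead_df(seq_len(nl), rep("NT", nl), 1 + seq_len(nl),
                      rep("LIG", nl), rep("N", nl), term_pos[[1]],
                      charge = 1, radius = 0.16)
  top <- rbind(pep_top, clus_top)
  top$serial <- seq_len(nrow(top))
  class(top) <- c("bead_df", "data.frame")
  coords <- array(0, c(nf, 1 + nl, 3))
  for (f in seq_len(nf)) {
    coords[f, 1, ] <- pep_pos[f, ]
    coords[f, 2:(1 + nl), ] <- term_pos[[f]]
  }
  trajectory((seq_len(nf) - 1) * dt, coords, box_length = box_length,
             molecules = list(peptide = 1L, cluster = 2:(1 + nl)),
             topology = top)
}

# independent quaternion-method (Horn) RMSD oracle, superposed
horn_rmsd <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); B <- sweep(B, 2, colMeans(B))
  M <- t(B) %*% A
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd_val <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  10 * sqrt(max(0, msd_val))  # nm -> Angstrom
}

# brute-force exhaustive piecewise-constant segmentation (<= 3 segments)
brute_segment <- function(y, k, min_len) {
  n <- length(y)
  sse <- function(v) sum((v - mean(v))^2)
  if (k == 1) return(list(rss = sse(y), bp = integer(0)))
  best <- list(rss = Inf, bp = integer(0))
  if (k == 2) {
    for (b in (min_len + 1):(n - min_len + 1)) {
      r <- sse(y[1:(b - 1)]) + sse(y[b:n])
      if (r < best$rss) best <- list(rss = r, bp = b)
    }
  } else if (k == 3) {
    for (b1 in (min_len + 1):(n - 2 * min_len + 1))
      for (b2 in (b1 + min_len):(n - min_len + 1)) {
        r <- sse(y[1:(b1 - 1)]) + sse(y[b1:(b2 - 1)]) + sse(y[b2:n])
        if (r < best$rss) best <- list(rss = r, bp = c(b1, b2))
      }
  } else stop("k <= 3 only")
  best
}
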