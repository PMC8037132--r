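# Ligand-peptide contact statistics, pair correlation, hydrogen bonds,
# GROMOS conformational clustering and Go-model native contacts.

#' Select bead indices of a trajectory by attribute
#'
#' @param traj a `trajectory` with a topology
#' @param molecule optional molecule name
#' @param name optional bead name filter
#' @param residue_index optional residue index filter
#' @param element optional element class filter
#' @return integer vector of bead indices (into the full bead set)
#' @export
select_beads <- function(traj, molecule = NULL, name = NULL,
                         residue_index = NULL, element = NULL) {
  top <- traj$topology
  if (is.null(top)) stop("trajectory has no topology")
  idx <- seq_len(nrow(top))
  if (!is.null(molecule)) {
    if (!molecule %in% names(traj$molecules))
      stop("unknown molecule: ", molecule)
    idx <- intersect(idx, traj$molecules[[molecule]])
  }
  if (!is.null(name)) idx <- idx[top$name[idx] %in% name]
  if (!is.null(residue_index))
    idx <- idx[top$residue_index[idx] %in% residue_index]
  if (!is.null(element)) idx <- idx[top$element_class[idx] %in% element]
  idx
}

# terminal amine N sites of the cluster molecule, with their ligand ids
.terminal_sites <- function(traj, cluster) {
  idx <- select_beads(traj, molecule = cluster, name = "NT", element = "N")
  if (!length(idx)) stop("no ligand terminal-N sites tagged in molecule '",
                         cluster, "'")
  # ligand id convention: cluster residue 1 is the core, ligand l sits in
  # residue l + 1
  list(idx = idx, ligand_id = traj$topology$residue_index[idx] - 1L)
}

#' Ligand-peptide contact table
#'
#' For every frame, the distance from each ligand terminal amine N to
#' every peptide bead (minimum image); a ligand is "in contact" in a
#' frame when its closest approach is `<= cutoff` (inclusive). The
#' per-ligand contact probability P is the fraction of frames with at
#' least one contact.
#'
#' @param traj a `trajectory` with peptide and cluster molecules and a
#'   topology carrying the terminal-N tags
#' @param cutoff Angstrom, inclusive
#' @param peptide,cluster molecule names
#' @return an object of class `contact_table`: list with `cutoff`, `P`
#'   (named by ligand id), `contact_matrix` (frames x ligands logical),
#'   `ligand_ids`, and `details` (frame, ligand_id, peptide_site serial,
#'   distance in Angstrom for each contact event)
#' @export
ligand_contacts <- function(traj, cutoff = 3.0, peptide = "peptide",
                            cluster = "cluster") {
  ts <- .terminal_sites(traj, cluster)
  pep_idx <- traj$molecules[[peptide]]
  if (is.null(pep_idx)) stop("trajectory lacks molecule: ", peptide)
  nf <- n_frames(traj)
  nl <- length(ts$idx)
  cut_nm <- ang_to_nm(cutoff)
  cm <- matrix(FALSE, nf, nl)
  det <- list()
  for (f in seq_len(nf)) {
    X <- frame_coords(traj, f)
    r <- .cdist_pbc(X[ts$idx, , drop = FALSE],
                    X[pep_idx, , drop = FALSE], traj$box_length)
    dmin <- apply(r, 1, min)
    hit <- dmin <= cut_nm
    cm[f, ] <- hit
    if (any(hit)) {
      j <- apply(r[hit, , drop = FALSE], 1, which.min)
      det[[length(det) + 1L]] <- data.frame(
        frame = f, ligand_id = ts$ligand_id[hit],
        peptide_site = traj$topology$serial[pep_idx[j]],
        distance = nm_to_ang(dmin[hit]))
    }
  }
  P <- colMeans(cm)
  names(P) <- ts$ligand_id
  colnames(cm) <- ts$ligand_id
  structure(list(cutoff = cutoff, P = P, contact_matrix = cm,
                 ligand_ids = ts$ligand_id,
                 details = if (length(det)) do.call(rbind, det) else
                   data.frame(frame = integer(0), ligand_id = integer(0),
                              peptide_site = integer(0),
                              distance = numeric(0))),
            class = "contact_table")
}

#' Ligand-ligand simultaneous contact counts
#'
#' Entry (a, b): number of frames in which ligands a and b both contact
#' the peptide; the diagonal holds per-ligand contact frame counts.
#'
#' @param table a `contact_table`
#' @return symmetric integer matrix, dimnames = ligand ids
#' @export
simultaneous_contact_matrix <- function(table) {
  cm <- table$contact_matrix
  if (!nrow(cm)) stop("empty contact table")
  out <- crossprod(cm * 1L)
  storage.mode(out) <- "integer"
  out
}

#' Inter-ligand terminal-N distance series
#'
#' @param traj a `trajectory`
#' @param ligand_ids >= 2 ligand ids
#' @param cluster molecule name
#' @return list with `distances` (frames x pairs matrix, Angstrom,
#'   columns "a-b"), `pair_means`, `pair_sd`, `pooled_mean`
#' @export
inter_ligand_distances <- function(traj, ligand_ids, cluster = "cluster") {
  if (length(ligand_ids) < 2) stop("need >= 2 ligand ids")
  ts <- .terminal_sites(traj, cluster)
  pos <- match(ligand_ids, ts$ligand_id)
  if (anyNA(pos)) stop("unknown ligand id(s): ",
                       paste(ligand_ids[is.na(pos)], collapse = ", "))
  sites <- ts$idx[pos]
  pairs <- utils::combn(seq_along(sites), 2)
  nf <- n_frames(traj)
  D <- matrix(0, nf, ncol(pairs))
  for (f in seq_len(nf)) {
    X <- frame_coords(traj, f)[sites, , drop = FALSE]
    d <- min_image(X[pairs[1, ], , drop = FALSE] -
                     X[pairs[2, ], , drop = FALSE], traj$box_length)
    D[f, ] <- sqrt(rowSums(d^2))
  }
  D <- nm_to_ang(D)
  colnames(D) <- paste(ligand_ids[pairs[1, ]], ligand_ids[pairs[2, ]],
                       sep = "-")
  list(distances = D, pair_means = colMeans(D),
       pair_sd = apply(D, 2, stats::sd), pooled_mean = mean(D))
}

#' Pair correlation function g(r) between two site sets
#'
#' Histogram of A-B minimum-image distances normalized per A site by the
#' ideal-gas shell count `4 pi r^2 dr rho_B`, averaged over frames.
#' Requires `r_max < box/2` (minimum-image validity).
#'
#' @param traj a `trajectory` with a periodic box
#' @param selector_A,selector_B integer bead indices (see
#'   [select_beads()])
#' @param r_max largest distance, Angstrom
#' @param shell_width bin width, Angstrom
#' @return an object of class `radial_distribution`: list with
#'   `r_centers` (Angstrom), `g`, `shell_width`, `reference_pair`
#' @export
pair_correlation <- function(traj, selector_A, selector_B,
                             r_max = 10, shell_width = 0.5) {
  if (is.null(traj$box_length)) stop("pair_correlation requires a box")
  box <- traj$box_length
  if (ang_to_nm(r_max) >= box / 2)
    stop("r_max must be < box/2 for minimum-image distances")
  A <- selector_A; B <- selector_B
  if (!length(A) || !length(B)) stop("empty selector")
  edges_nm <- seq(0, ang_to_nm(r_max), by = ang_to_nm(shell_width))
  nb <- length(edges_nm) - 1
  counts <- numeric(nb)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    X <- frame_coords(traj, f)
    r <- .cdist_pbc(X[A, , drop = FALSE], X[B, , drop = FALSE], box)
    # drop self pairs when the selectors overlap
    same <- outer(A, B, "==")
    rv <- r[!same]
    counts <- counts + graphics::hist(rv[rv < edges_nm[nb + 1]],
                                      breaks = edges_nm,
                                      plot = FALSE)$counts
  }
  rho_B <- length(B) / box^3
  shell_vol <- 4 * pi * ((edges_nm[-1] + edges_nm[-(nb + 1)]) / 2)^2 *
    diff(edges_nm)
  g <- counts / (nf * length(A) * shell_vol * rho_B)
  structure(list(r_centers = nm_to_ang((edges_nm[-1] +
                                          edges_nm[-(nb + 1)]) / 2),
                 g = g, shell_width = shell_width,
                 reference_pair = list(A = A, B = B)),
            class = "radial_distribution")
}

#' Geometric hydrogen-bond count in one frame
#'
#' A donor-acceptor pair is counted when the donor-acceptor distance is
#' `<= d_cut` and the D-H...A angle (at the hydrogen) is `>= angle_cut`
#' (180 degrees = linear).
#'
#' @param beads a bead table (one frame)
#' @param donors data.frame with columns `D` and `H`: bead row indices
#'   of each donor heavy atom and its hydrogen
#' @param acceptors integer vector of acceptor bead row indices
#' @param d_cut Angstrom
#' @param angle_cut degrees
#' @return integer count
#' @export
hbond_count <- function(beads, donors, acceptors, d_cut = 3.5,
                        angle_cut = 120) {
  if (!all(c("D", "H") %in% names(donors))) stop("donors needs D and H")
  if (anyNA(donors$H)) stop("donor missing hydrogen")
  X <- bead_coords(beads)
  cnt <- 0L
  for (k in seq_len(nrow(donors))) {
    d_i <- donors$D[k]; h_i <- donors$H[k]
    for (a in acceptors) {
      if (a == d_i) next
      dda <- nm_to_ang(sqrt(sum((X[d_i, ] - X[a, ])^2)))
      if (dda > d_cut) next
      v1 <- X[d_i, ] - X[h_i, ]; v2 <- X[a, ] - X[h_i, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang >= angle_cut) cnt <- cnt + 1L
    }
  }
  cnt
}

#' GROMOS conformational clustering
#'
#' Greedy neighbour-count clustering on superposed RMSD: the frame with
#' the most neighbours within `cutoff` becomes the representative of the
#' first cluster, its members are removed, and the scheme iterates.
#' Ties break deterministically to the lowest frame index.
#'
#' @param frames list of n x 3 coordinate matrices (nm), or a
#'   `trajectory` (optionally with `molecule`)
#' @param cutoff RMSD cutoff in nm (the field convention for this
#'   clustering; 0.1 nm = 1 Angstrom)
#' @param molecule molecule name when `frames` is a trajectory
#' @param stride frame subsampling stride
#' @param max_frames guard on the distance-matrix size
#' @return an object of class `cluster_assignment`: list with `cutoff`,
#'   `sizes`, `representatives` (frame indices), `membership` (per-frame
#'   cluster id), `frame_index` (original indices after striding)
#' @export
gromos_cluster <- function(frames, cutoff = 0.1, molecule = NULL,
                           stride = 1, max_frames = 3000) {
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (inherits(frames, "trajectory")) {
    traj <- frames
    frames <- lapply(seq_len(n_frames(traj)), function(f)
      frame_coords(traj, f, molecule))
  }
  keep <- seq(1, length(frames), by = stride)
  frames <- frames[keep]
  n <- length(frames)
  if (n < 1) stop("need >= 1 frame")
  if (n > max_frames)
    stop("too many frames for a full RMSD matrix; increase stride")
  cut_ang <- nm_to_ang(cutoff)
  D <- matrix(0, n, n)
  if (n > 1)
    for (a in 1:(n - 1)) for (b in (a + 1):n)
      D[a, b] <- D[b, a] <- rmsd(frames[[a]], frames[[b]], superpose = TRUE)
  remaining <- seq_len(n)
  membership <- integer(n)
  sizes <- integer(0); reps <- integer(0)
  k <- 0L
  while (length(remaining)) {
    k <- k + 1L
    nb <- colSums(D[remaining, remaining, drop = FALSE] <= cut_ang)
    rep_i <- remaining[which.max(nb)]
    members <- remaining[D[rep_i, remaining] <= cut_ang]
    membership[members] <- k
    sizes <- c(sizes, length(members))
    reps <- c(reps, rep_i)
    remaining <- setdiff(remaining, members)
  }
  structure(list(cutoff = cutoff, sizes = sizes, representatives = reps,
                 membership = membership, frame_index = keep),
            class = "cluster_assignment")
}

#' Go-model native-contact map and per-frame Q
#'
#' Native pairs are C-alpha pairs of the reference with sequence
#' separation `|i - j| >= seq_sep` and distance `<= cutoff`. Per frame,
#' Q is the fraction of native pairs within `1.2 * cutoff`.
#'
#' @param reference a peptide bead table (the native structure)
#' @param frames list of bead coordinate matrices with the reference's
#'   topology (nm), or a `trajectory` (optionally with `molecule`)
#' @param cutoff Angstrom
#' @param seq_sep minimum residue separation (>= 1)
#' @param molecule molecule name when `frames` is a trajectory
#' @param tol_factor contact tolerance applied per frame
#' @return an object of class `native_contact_map`: list with `pairs`
#'   (data.frame i, j of residue indices), `cutoff`, `seq_sep`, `Q`
#'   (per frame; NA when the map is empty)
#' @export
native_contact_map <- function(reference, frames, cutoff = 6.5,
                               seq_sep = 3, molecule = NULL,
                               tol_factor = 1.2) {
  if (seq_sep < 1) stop("seq_sep must be >= 1")
  ca_rows <- which(reference$name == "CA")
  if (!length(ca_rows)) stop("reference has no CA beads")
  res <- reference$residue_index[ca_rows]
  ref_xyz <- bead_coords(reference)[ca_rows, , drop = FALSE]
  pr <- utils::combn(seq_along(ca_rows), 2)
  sep_ok <- abs(res[pr[1, ]] - res[pr[2, ]]) >= seq_sep
  d_ref <- sqrt(rowSums((ref_xyz[pr[1, ], , drop = FALSE] -
                           ref_xyz[pr[2, ], , drop = FALSE])^2))
  native <- sep_ok & (nm_to_ang(d_ref) <= cutoff)
  pairs <- data.frame(i = res[pr[1, native]], j = res[pr[2, native]])
  if (nrow(pairs)) {
    sw <- pairs$i > pairs$j
    tmp <- pairs$i[sw]; pairs$i[sw] <- pairs$j[sw]; pairs$j[sw] <- tmp
  }
  if (inherits(frames, "trajectory")) {
    traj <- frames
    frames <- lapply(seq_len(n_frames(traj)), function(f)
      frame_coords(traj, f, molecule))
  }
  pi_ <- pr[1, native]; pj <- pr[2, native]
  Q <- vapply(frames, function(X) {
    if (!nrow(pairs)) return(NA_real_)
    Xc <- X[ca_rows, , drop = FALSE]
    d <- sqrt(rowSums((Xc[pi_, , drop = FALSE] -
                         Xc[pj, , drop = FALSE])^2))
    mean(nm_to_ang(d) <= tol_factor * cutoff)
  }, numeric(1))
  structure(list(pairs = pairs, cutoff = cutoff, seq_sep = seq_sep, Q = Q),
            class = "native_contact_map")
}

# minimum-image aware cross-distance matrix (nm)
.cdist_pbc <- function(A, B, box_length = NULL) {
  if (is.null(box_length)) return(.cdist(A, B))
  n <- nrow(A); m <- nrow(B)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(A[, k], B[, k], "-")
    d <- min_image(d, box_length)
    out <- out + d^2
  }
  sqrt(out)
}
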