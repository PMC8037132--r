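# Coarse peptide models: one backbone bead per residue (plus optional
# interpolated backbone beads) with explicit charge/contact sites -- the
# two Asp carboxylate oxygens, and zwitterionic N-/C-terminal sites.

.aa1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

.aa3 <- c(A="ALA", R="ARG", N="ASN", D="ASP", C="CYS", Q="GLN", E="GLU",
          G="GLY", H="HIS", I="ILE", L="LEU", K="LYS", M="MET", F="PHE",
          P="PRO", S="SER", T="THR", W="TRP", Y="TYR", V="VAL")

# Side-chain formal charges at neutral pH; His kept neutral (side-chain
# pKa < 7, standard protonation state at pH 7).
.aa_charge <- c(D = -1, E = -1, K = +1, R = +1)

.CA_SPACING  <- 0.38   # nm, consecutive backbone beads
.TERM_OFFSET <- 0.13   # nm, terminal sites beyond the terminal CA
.HORSESHOE_ARC <- 320 * pi / 180  # arc swept by the folded template

#' Net formal charge of a peptide sequence
#'
#' Sums side-chain formal charges at neutral pH (D, E: -1; K, R: +1;
#' H: 0 -- the imidazole is kept neutral as its pKa lies below 7) plus
#' the termini contribution (zwitterionic: +1 - 1 = 0; capped: 0).
#'
#' @param sequence one-letter amino-acid string
#' @param termini `"zwitterionic"` or `"capped"`
#' @return integer net charge, e
#' @examples
#' formal_charge("HWDDD")    # -3
#' formal_charge("HHHWDDD")  # -3
#' @export
formal_charge <- function(sequence, termini = c("zwitterionic", "capped")) {
  termini <- match.arg(termini)
  aa <- strsplit(toupper(sequence), "")[[1]]
  if (length(aa) < 1) stop("sequence must be non-empty")
  bad <- setdiff(aa, .aa1)
  if (length(bad))
    stop("invalid residue letter(s): ", paste(unique(bad), collapse = ", "))
  side <- sum(.aa_charge[aa], na.rm = TRUE)
  as.integer(side)  # both termini conventions contribute net 0
}

#' Counterions needed to neutralize a system
#'
#' Monovalent ions only: a system of net charge q needs `max(0, -q)`
#' Na+ or `max(0, +q)` Cl-; never both.
#'
#' @param total_system_charge integer net charge, e
#' @return named integer vector `c(n_Na =, n_Cl =)`
#' @examples
#' counterion_count(-3)   # 3 Na+
#' counterion_count(60)   # 60 Cl-
#' counterion_count(57)   # 57 Cl-
#' @export
counterion_count <- function(total_system_charge) {
  q <- total_system_charge
  if (length(q) != 1 || !is.finite(q) || q != round(q))
    stop("total system charge must be a single integer")
  q <- as.integer(q)
  c(n_Na = max(0L, -q), n_Cl = max(0L, q))
}

# Backbone template: positions of the n_res CA beads plus the two terminal
# sites, as points along either a straight line (extended) or a circular
# arc (horseshoe, termini approaching). Returns list(ca = n x 3, nt, ct).
.chain_template <- function(n_res, geometry_mode) {
  s_ca <- .CA_SPACING * (seq_len(n_res) - 1)
  if (geometry_mode == "extended") {
    pos <- function(s) cbind(s, 0, 0)
    tan0 <- c(-1, 0, 0); tan1 <- c(1, 0, 0)
    ca <- pos(s_ca)
  } else {  # horseshoe: arc of .HORSESHOE_ARC, termini pulled together
    contour <- max(.CA_SPACING * (n_res - 1), .CA_SPACING)
    R <- contour / .HORSESHOE_ARC
    ang <- s_ca / R
    ca <- cbind(R * cos(ang), R * sin(ang), 0)
    tan0 <- c(sin(0), -cos(0), 0)                    # -d(pos)/ds at s=0
    a1 <- ang[n_res]
    tan1 <- c(-sin(a1), cos(a1), 0)                  # +d(pos)/ds at end
  }
  nt <- ca[1, ] + .TERM_OFFSET * tan0
  ct <- ca[n_res, ] + .TERM_OFFSET * tan1
  list(ca = ca, nt = nt, ct = ct)
}

# one conformer as a bead table
.peptide_conformer <- function(aa, geometry_mode, beads_per_residue, termini) {
  n_res <- length(aa)
  tpl <- .chain_template(n_res, geometry_mode)
  rows <- list()
  serial <- 0L
  add <- function(name, ri, elem, pos, charge, radius) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = name, residue_index = ri,
      residue_name = unname(.aa3[aa[ri]]), element_class = elem,
      x = pos[1], y = pos[2], z = pos[3],
      charge = charge, radius = radius, stringsAsFactors = FALSE)
  }
  term_q <- if (termini == "zwitterionic") c(nt = +1, ct = -1) else c(nt = 0, ct = 0)
  add("NT", 1L, "N", tpl$nt, term_q[["nt"]], 0.16)
  for (ri in seq_len(n_res)) {
    add("CA", ri, "C", tpl$ca[ri, ], 0, 0.23)
    if (beads_per_residue > 1 && ri < n_res) {
      for (k in seq_len(beads_per_residue - 1)) {
        f <- k / beads_per_residue
        p <- (1 - f) * tpl$ca[ri, ] + f * tpl$ca[ri + 1, ]
        add(paste0("B", k), ri, "C", p, 0, 0.17)
      }
    }
    up <- c(0, 0, 1); side <- c(0, 1, 0); base <- tpl$ca[ri, ]
    if (aa[ri] %in% c("D", "E")) {
      # carboxylate oxygens, -0.5 e each, offset off-plane from CA
      onm <- if (aa[ri] == "D") c("OD1", "OD2") else c("OE1", "OE2")
      add(onm[1], ri, "O", base + 0.18 * up + 0.10 * side, -0.5, 0.15)
      add(onm[2], ri, "O", base + 0.18 * up - 0.10 * side, -0.5, 0.15)
    } else if (aa[ri] %in% c("K", "R")) {
      # cationic side-chain nitrogen, +1 e
      add("NZ", ri, "N", base + 0.25 * up, +1, 0.16)
    }
  }
  add("CT", n_res, "C", tpl$ct, term_q[["ct"]], 0.17)
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  class(df) <- c("bead_df", "data.frame")
  validate_beads(df)
}

#' Build a coarse peptide model
#'
#' One backbone bead per residue at 0.38 nm spacing plus explicit charge
#' sites: two carboxylate oxygens (-0.5 e each) per Asp, and zwitterionic
#' terminal sites NT (+1 e) and CT (-1 e). One conformer is generated per
#' entry of `geometry_mode`; all conformers share bead ordering.
#'
#' @param sequence one-letter amino-acid string (20 standard codes)
#' @param geometry_mode character vector of conformer templates, each
#'   `"extended"` (straight chain) or `"horseshoe"` (folded arc with
#'   approaching termini)
#' @param beads_per_residue backbone beads per residue (>= 1)
#' @param termini `"zwitterionic"` or `"capped"`
#' @return an object of class `peptide_model`: list with `sequence`,
#'   `conformers` (list of bead tables), `net_charge`, `termini`, `modes`
#' @examples
#' p <- build_peptide("HWDDD")
#' p$net_charge  # -3
#' @export
build_peptide <- function(sequence,
                          geometry_mode = c("extended", "horseshoe"),
                          beads_per_residue = 1,
                          termini = c("zwitterionic", "capped")) {
  termini <- match.arg(termini)
  geometry_mode <- match.arg(geometry_mode, c("extended", "horseshoe"),
                             several.ok = TRUE)
  if (beads_per_residue < 1 || beads_per_residue != round(beads_per_residue))
    stop("beads_per_residue must be a positive integer")
  net <- formal_charge(sequence, termini)  # also validates the alphabet
  aa <- strsplit(toupper(sequence), "")[[1]]
  conformers <- lapply(geometry_mode, function(mode)
    .peptide_conformer(aa, mode, beads_per_residue, termini))
  # identical topology across conformers
  ref <- conformers[[1]][, c("serial", "name", "residue_index")]
  for (cf in conformers)
    stopifnot(identical(cf[, c("serial", "name", "residue_index")], ref))
  stopifnot(isTRUE(all.equal(sum(conformers[[1]]$charge), net)))
  structure(list(sequence = toupper(sequence), conformers = conformers,
                 net_charge = net, termini = termini,
                 modes = geometry_mode),
            class = "peptide_model")
}

#' @export
print.peptide_model <- function(x, ...) {
  cat(sprintf("peptide_model: %s (%d residues, net charge %+d e, %s)\n",
              x$sequence, nchar(x$sequence), x$net_charge, x$termini))
  cat(sprintf("  %d conformer(s): %s; %d beads each\n",
              length(x$conformers), paste(x$modes, collapse = ", "),
              nrow(x$conformers[[1]])))
  invisible(x)
}
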