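---
title: "Models and methods behind pepmpc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pepmpc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepmpc)
```

## The system and the questions

pepmpc models the association of short anionic catalytic peptides
(HWDDD and HHHWDDD: a His head, a Trp fluorescent probe, and an Asp
tail) with a cationic gold monolayer-protected cluster (Au-MPC), an
Au144 core passivated by 60 S(CH2)8NH3+ thiolate ligands. Binding of
the peptide to the monolayer is a prerequisite for the conjugate's
esterase-like activity, so the quantities of interest are: where and
how strongly the peptide docks, how its conformation changes upon
adsorption, how its mobility changes (normal vs confined diffusion),
and which monolayer ligands form the persistent binding patch.

The package is a desk-scale toolkit: it does not attempt microsecond
atomistic MD. It implements (i) coarse structure building with charge
accounting, (ii) flexible Brownian-dynamics (BD) docking with a
three-term interaction energy, and (iii) the complete trajectory
analysis suite such studies use, exercised against synthetic
trajectories whose ground truth is known exactly.

## Coarse models and charge accounting

Peptides are built with one backbone bead per residue at 0.38 nm
spacing plus explicit charge/contact sites: two carboxylate oxygens
(−0.5 e each) per Asp/Glu, a cationic side-chain nitrogen for Lys/Arg,
and zwitterionic terminal sites (+1/−1 e). His is kept neutral (its
side-chain pKa lies below 7, so at pH 7 the neutral tautomer
dominates). Both HWDDD and HHHWDDD therefore carry net −3 e, which is
exactly what the counterion bookkeeping requires: 3 Na+ for the free
peptide, 60 Cl− for the free +60 cluster, 57 Cl− for the complex.

The nanocluster is idealized: a neutral spherical core of radius
0.9 nm with 60 thiolate anchors on a Fibonacci lattice, each carrying
a straight chain ending in a terminal amine nitrogen of charge +1 e.
The Au144 staple motif is intentionally not reproduced — no analysis in
scope depends on it, only on the positions and charges of the terminal
amines and the overall monolayer geometry.

Two conformer templates are generated per peptide: *extended*
(straight chain) and *horseshoe* (a 320° circular arc with approaching
termini). The arc angle was fixed once so that the folded 7-residue
template carries the (1,6)-type terminal native contact at the
standard 6.5 Å Go cutoff; a consequence is that the template's termini
are closer together than the ~7–10 Å bound-state end-to-end distances
observed in long MD, which are ensemble averages, not templates. The
horseshoe template is a stylized end point of folding, not a fit to
any published histogram.

Units: the model layer (beads, poses, trajectories) is nm/ps/kT (GRO
convention); analysis interfaces quote Å, Å², and cm²/s because that
is how the field reports cutoffs, SASA, MSD, and diffusion
coefficients. PDB/XYZ files carry Å, GRO carries nm; conversions occur
only at these boundaries.

## The docking energy

The total interaction energy is a plain sum of three terms,

U_repr = U_EP + U_dse + U_dsh,

held as an `energy_breakdown` whose identity is asserted to 1e-9 kT on
every pose the docking emits.

* **U_EP** — screened electrostatics over effective charge sites
  (ligand terminal N, Asp carboxylate O, termini):
  `U_EP = sum_ij q_i q_j l_B exp(-kappa r_ij)/r_ij` in kT, with the
  Bjerrum length `l_B = e^2/(4 pi eps0 eps_s kB T)` (0.714 nm at
  eps 78, 300 K) and Debye constant from the ionic strength (10 mM
  gives a 3.0 nm screening length). This analytic Debye–Hückel form
  replaces grid-based electrostatic potentials: the acceptance surface
  (energy aggregation identities, BD statistics) does not require a
  grid, and the analytic form has an exact brute-force oracle.
* **U_dse** — electrostatic desolvation, a penalty for burying charges
  near the other solute's low-dielectric body:
  `a_dse * sum_i q_i^2 sum_j exp(-r_ij/lambda)`, lambda = 3 Å,
  applied in both directions. Always ≥ 0, → 0 at separation.
* **U_dsh** — non-polar desolvation, `a_dsh` (negative) times the
  number of nonpolar bead pairs within 4.5 Å. Always ≤ 0.

The desolvation functional forms are this package's own (the
literature defers them to solver internals); their coefficients default
to values giving contact-scale magnitudes of order +9 / −11 kT, the
scale of published docking tables, and **no quantitative acceptance
target depends on their absolute values**.

## Brownian-dynamics docking

The peptide moves in the cluster frame with relative diffusion
coefficients (D_rel = D_pep + D_cluster; rotation with the peptide's
D_rot) under the Ermak–McCammon update
`dr = D_rel F dt + xi`, `xi ~ N(0, 2 D_rel dt)` per axis, and the
analogous angular update composed onto a unit quaternion. Forces come
from the analytic gradients of U_EP and U_dse; the discrete contact
count U_dsh is energy-only (nondifferentiable), and steric overlap is
handled by rejecting trial moves that bring any bead pair below 0.9
times the sum of radii.

Protocol defaults follow the published docking setup: runs start at
100 Å separation with random orientation; dt = 1 ps below 50 Å,
growing linearly (1 ps per 10 Å of extra separation, capped at 20 ps)
beyond it; runs end at 500 ns or at a 300 Å escape radius; 5000 runs;
a bounded store keeps the 1000 lowest-energy poses, any two of which
differ by > 1 Å peptide-bead RMSD. The store RMSD is computed without
re-superposition because poses share the cluster frame and the
binding-site location must distinguish poses. Conformer exchange
(Metropolis on ΔU_repr, circular adjacent proposal) is attempted every
20 steps; the exchange period and the treatment of "500 ns" as a
per-run cap are this package's resolutions of ambiguities in the
protocol description. Tests and the bundled pipeline scale n_runs and
run_length down by 2–4 orders of magnitude — explicitly, in their
configs — so the suite completes in minutes; the physics parameters are
never rescaled.

Pose clustering follows the GROMOS greedy neighbour-count scheme per
conformer (cutoff 2 Å on pose RMSD), emitting relative populations
(percent of that conformer's poses, summing to 100 with the residual
row), the representative's energy breakdown, and the spread (mean
member–representative RMSD) — the structure of published docking
tables. Contact residues use the strict < 3.5 Å criterion; ligand
contacts in trajectories use the inclusive ≤ 3.0 Å criterion. The two
cutoffs are deliberately distinct named parameters with different
boundary semantics.

## Trajectory analyses

* **Association profile**: per-frame COM–COM distance (minimum image)
  and spherical angles of the separation vector.
* **Stage segmentation**: exact dynamic-programming piecewise-constant
  least squares with BIC model selection (`n log(RSS/n) + p log n`,
  p = 2k−1). The published stage boundaries were read by eye; change-
  point detection makes them reproducible. The DP optimum is verified
  against exhaustive enumeration on short series.
* **SASA**: Shrake–Rupley with a 960-point Fibonacci quadrature and a
  1.4 Å probe (the algorithm choice is ours; the source delegates it
  to analysis software). Checked against the analytic sphere and an
  independent dense Monte-Carlo quadrature.
* **MSD and diffusion**: time-averaged MSD over all origins;
  `D = slope/6` from a through-origin fit over a configurable lag
  window (default 10–25% of the largest lag); the anomalous exponent
  alpha is the log-log slope over the same window. alpha ≈ 1 means free
  diffusion; alpha < 0.9 is the package's operational flag for the
  confined, bound state.
* **Rotational diffusion**: the body-axis autocorrelation is fitted to
  `exp(-2 D_r tau)`. The correlation is averaged over all three body
  axes using `C(tau) = (4 (q.q')^2 - 1)/3 = Tr(R_rel)/3`, which has the
  same expectation as the single-axis correlation but three times the
  statistics; at the acceptance trajectory length (10 replicas of
  ~6 correlation times) this brings the estimator's scatter from ~10%
  to ~1.5%. The estimator was chosen against generator truth, never
  against a published value.
* **Distributions**: normalized histograms with kernel-smoothed mode
  counting; a mode must exceed 10% of the density maximum (the
  prominence criterion is the package's own; the source shows
  histograms only). Circular series use wrapped smoothing and circular
  mean/SD.
* **Pair correlation** g(r): minimum-image shell histogram normalized
  by the ideal-gas shell count; requires r_max < box/2.
* **Conformational clustering**: GROMOS scheme on superposed
  (Kabsch) RMSD with cutoffs quoted in nm (0.1/0.2 nm conventions),
  deterministic lowest-index tie-break, and a stride parameter as the
  memory guard for the full distance matrix.
* **Go native contacts**: Cα pairs with |i−j| ≥ 3 within 6.5 Å of the
  reference; per-frame Q uses a 1.2 tolerance factor. These
  "standard" thresholds are recorded as config defaults because the
  source names but does not quantify them.
* **Hydrogen bonds**: geometric criterion, D···A ≤ 3.5 Å and
  D–H···A ≥ 120°; chosen because the source names no criterion.
* **"Central Asp"** for g(r) is resolved as the middle residue of the
  Asp run (residue 4 of HWDDD, residue 6 of HHHWDDD).

## Synthetic data: a stated world

Each generator is deterministic under its seed and returns its ground
truth alongside the trajectory:

* free translational diffusion at the configured coefficients
  (0.27e−5 cm²/s peptide, 0.11e−5 cluster — the docking-configuration
  values, which are inputs, unlike the "~" fitted values quoted from
  MD);
* isotropic rotational diffusion (30.7e−5 rad²/ps peptide);
* staged association with per-stage distance means 25/17/16 Å —
  the three approach stages — with Ornstein–Uhlenbeck fluctuation
  (sd 0.5 Å, relaxation 100 frames by default) rather than white
  noise, so segmentation faces realistic autocorrelation;
* two-state extended/horseshoe conformer switching via a Markov chain;
* a bound complex: peptide COM tethered by a 3D OU process (stationary
  sd set by the confinement radius, default 2 Å) above a designated
  ligand patch whose terminal amines are pinned within contact range
  of the peptide's anionic sites, while non-patch terminal amines are
  kept outside a 4.5 Å exclusion range — the generator enforcing its
  own ground-truth labels. Confinement makes the long-lag MSD plateau
  near 2R² and alpha fall well below 0.9 by construction.

What a green test establishes: that the estimators recover the
generating parameters (D within 5%, D_rot within 10%, stage means
within 0.2 Å, patch identity exactly, occupancies within 2%) under
OU/Gaussian statistics. What it does not establish: agreement with
atomistic MD observables (cluster sizes, stage times in ns, the
16 Å adsorption distance as an emergent quantity, histogram shapes) —
those derive from microsecond simulations outside desk scale and are
covered only qualitatively (e.g. bound alpha < free alpha).

## Numerical choices and degenerate inputs

Energies are capped at a configurable U_max when sites overlap
(< 0.5 Å), with a clash flag rather than an exception; coincident COMs
give NaN angles for that frame; the GROMOS tie-break is the lowest
frame index; the pose store replaces a within-threshold neighbour only
by a lower-energy pose; quaternions are renormalized every step;
the exchange proposal is circular (the "adjacent conformer" wording
leaves this open).

## The published docking tables as data

The two docking tables ship as plain text
(`docking_reference_tables()`) and serve as *inputs* to the energy-
aggregation identity U_repr = U_EP + U_dse + U_dsh. Two rows are
internally inconsistent as printed — B1 (components sum 0.100 kT above
the printed total) and C5 (0.999 kT above) — and are flagged via
`identity_consistent` rather than corrected; the identity holds to
±0.002 kT on every other row and to ±0.001 kT on rows A5, C2, D2, E4.

## Known limitations

No atomistic force field, water, or staple-motif geometry; desolvation
terms are qualitative; BD forces omit the U_dsh gradient; the docking
energies are not comparable in absolute value to published table
energies (which came from grid electrostatics over atomistic
structures); rotational diffusion of the cluster is folded into the
relative translational update only through its translational part; the
CLI is a thin wrapper over the R API rather than a full workflow
engine.
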