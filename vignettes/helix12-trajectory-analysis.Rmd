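---
title: "Methods: tracking helix-12 conformational adaptation in LBD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracking helix-12 conformational adaptation in LBD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

The ligand-binding domain (LBD) of a nuclear receptor such as the
progesterone receptor switches between an antagonistic "open" and an
agonistic "closed" arrangement of its mobile C-terminal helix (helix 12).
Molecular-dynamics trajectories of such systems are analysed with a
standard battery: a two-reference state metric, per-residue flexibility,
essential-dynamics PCA, conformational clustering, configurational entropy,
hydration-shell and bridging-water statistics, and interaction energetics.
`lbdtraj` implements that battery as composable functions over a plain
trajectory container (topology + coordinate frames in nm + times in ps),
plus a synthetic-trajectory generator that supplies exact ground truth for
every stage.

# The two-reference state metric

For a frame $x$ and reference structures $O$ (open) and $C$ (closed), the
state metric is

$$\Delta\mathrm{RMSD}(x) = \mathrm{RMSD}(x, C) - \mathrm{RMSD}(x, O),$$

with both terms Kabsch-optimal alpha-carbon RMSDs. The operand order is a
convention we fix so that closed-like frames come out negative; the
customary closed-state criterion, $\Delta\mathrm{RMSD} \le -0.1$ nm, then
applies with its published sign. Frames are labelled `closed` at or below
$-0.1$ nm, `open` at or above $+0.1$ nm, and `semi-open` between. Two
choices deserve note:

* The $+0.1$ nm open threshold is symmetric by choice; only the closed
  criterion has a conventional value. The semi-open band is therefore an
  operationalisation, and reports label it as such.
* Boundary inclusivity (`<=` / `>=`) is documented but immaterial at float
  resolution.

Superposition uses the SVD form of the Kabsch algorithm with the
determinant correction that forbids reflections; collinear correspondence
sets (rank < 2) are rejected rather than silently fit. The superposition
mask and the measurement mask default to the same alpha-carbon selection;
region-wise RMSD profiles measure regional deviations after *global*
superposition (both modes are available — whether published region profiles
re-fit per region is generally unstated, and global-fit/regional-measure is
the default here).

RMSF is computed about the iteratively converged mean structure (superpose
all frames to a reference, average, repeat until the mean moves less than
$10^{-6}$ nm), not about frame 1 — the common convention when none is
stated. For validation ensembles that are already aligned, fitting can be
disabled.

# Essential dynamics

Two PCA routes are provided because they answer different questions:

* **Distance-feature PCA** (`distance_feature_matrix()` + `md_pca()`): the
  upper-triangle alpha-carbon pairwise distances of every `stride`-th frame.
  Distances are invariant under rigid motion, so no superposition enters,
  and the projections are reproducible to numerical precision under any
  rigid transformation of the frames (a property the tests assert at
  $10^{-10}$).
* **Cartesian PCA** (`cartesian_pca()`): coordinates after superposition to
  the converged mean. Only this route decomposes eigenvectors into per-atom
  3-vectors, so per-residue mode amplitudes — the usual essential-dynamics
  porcupine picture — come from here. A distance-matrix PCA does not
  natively yield per-atom vectors, so pipelines that report them must have
  used a Cartesian decomposition; we expose both routes rather than guess
  further.

Eigenvector signs are fixed by making each component's largest-magnitude
loading positive, so projections and plots do not flip between runs. The
default analysis cadence is every 100 ps expressed in frames.

# Quasi-harmonic configurational entropy

The estimator assumes the ensemble samples a harmonic multivariate
distribution of the $3N$ selected coordinates. With $\lambda_i$ the
eigenvalues of the mass-weighted covariance (amu nm² internally, converted
to SI for the mode sum), each retained mode gets a frequency
$\omega_i = \sqrt{k_B T / \lambda_i}$ and

$$S = R \sum_i \left[ \frac{x_i}{e^{x_i}-1} - \ln\!\left(1-e^{-x_i}\right) \right],
  \qquad x_i = \frac{\hbar\omega_i}{k_B T}.$$

The Schlitter variant
$S = \tfrac{R}{2} \sum_i \ln\!\left(1 + \frac{k_B T e^2}{\hbar^2}\lambda_i\right)$
is computed from the same spectrum and is an upper bound, mode by mode; the
quasi-harmonic form is the default because it is the canonical
quasi-harmonic mode sum. Modes with $\lambda_i$ below $10^{-8}$ amu nm²
(rigid-body remnants after superposition, numerically null directions) are
discarded; the tolerance is configurable. A warning is issued when fewer
than $3N+1$ frames back a $3N$-mode spectrum.

Validation leans on `make_gaussian_ensemble()`: it samples the *exact*
generative model with a prescribed spectrum, so the closed-form mode sum of
that spectrum is ground truth, not an approximation. At 20,000 frames the
sampled-covariance estimate agrees with the closed form to well within 2%
(relative sampling error of a variance at $n$ frames scales as
$\sqrt{2/n} \approx 1\%$). For these ensembles superposition is disabled:
they are generated aligned, and fitting would absorb prescribed variance
into the removed rigid-body modes.

Whether published LBD entropies used all heavy atoms or alpha carbons only
is typically unstated, and values from microsecond trajectories are not
reproducible at desk scale in any case; the package therefore validates the
estimator's correctness and the apo-above-bound *ordering* (doubling every
mode's standard deviation must raise $S$ in every replicate), not any
particular printed number.

# Gromos clustering

`gromos_cluster()` implements the greedy medoid algorithm: count, for every
frame, its neighbours within the RMSD cutoff (0.2 nm default for
domain-scale conformers); the frame with the most neighbours seeds a
cluster, it and its neighbours are removed, repeat. The original algorithm
description leaves ties unspecified; we break them toward the lowest frame
index, which makes assignments deterministic and lets an independent
brute-force transcription reproduce them exactly — the equivalence the
acceptance suite checks at three cutoffs, with duplicated frames planted to
force ties.

# Solvation

Hydration counts follow the first-shell convention: a water is in the shell
when its oxygen lies within 0.5 nm (the ~5 Å first-shell radius) of any
solute atom. Distances are measured to the solute atoms the caller selects
(heavy atoms by convention, since the synthetic systems carry no
hydrogens). The boundary is inclusive — a distance exactly equal to the
cutoff counts — and the same rule is used everywhere in the package. The
neighbour search runs on a cell grid with a brute-force fallback; the two
must agree exactly, and that equivalence is asserted rather than assumed.
Periodic boxes are orthorhombic throughout (box lengths only): every
distance the analyses need is a minimum-image distance in a rectangular
cell, so general triclinic support would add complexity without a consumer.

A bridging water satisfies the two-site criterion — oxygen within 0.35 nm
of *both* site atoms — in a frame. For the conserved tryptophan/valine
bridge the site atoms are the tryptophan side-chain nitrogen (`NE1`) and
the valine backbone nitrogen (`N`), fixed by standard PDB nomenclature.
Maximal runs of consecutive bridging frames become residence intervals; a
`gap_tolerance` (default 0, the strict continuous-occupancy reading) can
merge runs separated by short absences, because frame striding fragments
genuine residences. An interval's duration is `end - start` plus one frame
spacing, so a single-frame visit has one frame's duration rather than zero.
Water identity is the (chain, residue) pair; the oxygen atom is the
distance proxy.

# Interactions and electrostatics

Hydrogen bonds use standard-practice geometric criteria — donor-acceptor
distance $\le$ 0.35 nm and, when a hydrogen is given,
donor-hydrogen-acceptor angle $\ge 120°$ — because published analyses of
this kind rarely state their thresholds. Occupancy is the fraction of
frames satisfying the criterion, invariant under frame reordering.

Charge centers are unweighted centroids of rule-selected side-chain charged
atoms (Lys NZ; Arg CZ; Glu/Asp carboxylate midpoints; His ring-nitrogen
midpoint). For the progesterone-receptor LBD surface centers two published
residue lists disagree (positive center K733/R740 versus K731/K734/K740);
both presets ship, the former is the default, and the conflict is surfaced
in the documentation rather than resolved by fiat. Which atoms define the
centers (backbone vs side chain) is likewise unstated in the literature;
side-chain charged-atom centroids are the documented choice.

The screened Coulomb energy defaults to the physical potential
$E = k_C q_1 q_2 / (\varepsilon d)$ with
$k_C = 138.935458$ kJ mol⁻¹ nm e⁻² and $\varepsilon = 80$ for fully
solvent-exposed pairs. Some papers print the formula with $d^2$ in the
denominator — dimensionally a force law; an `as_printed` mode reproduces
that form for comparison, flagged non-standard in its output metadata.
Published "~2.5 kJ/mol" energy-change figures are not used as oracles: the
same value has been quoted for two different distance changes, which no
single formula reproduces simultaneously, so validation rests on the
constant-based point value and the $1/d$ scaling law instead.

# The synthetic generator — what it emulates and what it does not

`make_references()` builds a four-helix alpha-carbon bundle (60 residues
default) whose terminal segment plays helix 12; the open reference rotates
that segment about a hinge, with the hinge angle solved so the
whole-bundle RMSD between references equals `state_separation` (0.6 nm
default — a domain-scale open/closed separation comfortably beyond the
−0.1 nm criterion). Two pseudo side-chain atoms play the
tryptophan-NE1/valine-N bridge sites: 0.5 nm apart in the closed reference
(bridgeable at the 0.35 nm two-site criterion) and far apart in the open
one.

`make_transition_trajectory()` interpolates open to closed through a
three-stage schedule (fast approach, fast patching, slow final adjustment)
with independent Gaussian noise (0.02 nm default) on every coordinate. The
middle stage is routed through the state fraction at which the noise-free
$\Delta$RMSD equals the closed threshold — found by root-finding on the
interpolation path, never assumed — so the crossing lands at a chosen
fraction of the trajectory (40% default, i.e. frame 400 of 1000). The
recorded ground truth is the measured noise-free crossing frame.

Scripted solvent (`plant_solvent()`) places waters by schedule: inside the
shell, exactly at the shell cutoff (the inclusive-boundary probe), bridging
both sites, or ~100 nm away. Ground-truth counts and residence intervals
come from the schedule itself.

What the generator does **not** emulate: force-field physics, side-chain
rotamers, explicit hydrogens beyond planted probes, realistic solvent
dynamics, or physical time (frame spacing is a label, 100 ps by default).
Passing tests therefore demonstrate that the *analysis operations* are
correct on data whose answer is known exactly — they do not demonstrate
anything about real LBD simulations, whose microsecond-scale observables
(absolute entropies, occupancies, free-energy gaps) are far beyond desk
scale. Problem sizes were chosen so the whole battery stays comfortable on
a laptop: 60-residue bundles, 100–1000-frame trajectories, up to 1000
scripted waters, 20,000-frame Gaussian ensembles.

# Numerical choices collected

* Internal unit is nm; PDB I/O converts Å↔nm at the boundary and writes
  3-decimal Å (ties round-half-even via C formatting). Author residue
  numbering is preserved verbatim, so residues keep their literature names.
* Crystallographic waters are read and kept; whether they enter an analysis
  is a selection decision, not a reader decision.
* Kabsch degeneracy: fewer than 3 points or collinear sets are errors.
* RMSF/mean-structure iteration: tolerance $10^{-6}$ nm, cap 50 iterations.
* PCA sign: largest-magnitude loading positive. Eigenvalues are descending;
  their sum equals total feature variance.
* Entropy rigid-body tolerance: $10^{-8}$ amu nm²; temperature must be
  positive; Schlitter uses the same mass-weighted spectrum (the per-mode
  $k_B T e^2 m \sigma^2/\hbar^2$ form written with a plain covariance is
  the identical quantity).
* Gromos ties: lowest frame index wins.
* Inclusive boundaries everywhere a cutoff appears.
* Pipeline determinism: a fixed config (which seeds all randomness) gives
  byte-identical reports; disabling one stage never changes another's
  numbers.

# Limitations

Only multi-model PDB is parsed natively (orthorhombic `CRYST1` cells;
first alternate locations; no insertion-code semantics, no mmCIF); binary
trajectory formats should be converted upstream or read with an external
reader into the plain containers. Clustering materialises the full pairwise
RMSD matrix, which is fine at the hundreds-of-frames scale it is meant for
and quadratic beyond it. The entropy estimator inherits every caveat of the
quasi-harmonic approximation — anharmonic and multimodal ensembles are
summarised optimistically — and the semi-open band of the state classifier
is a working definition awaiting experimental calibration.
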