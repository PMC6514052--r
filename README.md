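# lbdtraj

Trajectory analysis of nuclear-receptor helix-12 conformational
transitions, in R.

The ligand-binding domain (LBD) of receptors like the progesterone
receptor encodes its pharmacology in the position of its mobile C-terminal
helix (helix 12): "open" arrangements are antagonistic, "closed"
(agonistic) arrangements form the co-activator surface. Molecular-dynamics
studies of ligand-induced switching all lean on the same analysis battery,
and `lbdtraj` implements it for people who want those analyses scriptable,
tested and reproducible in R:

* **Two-reference state metric** — for frame *x* and open/closed reference
  structures *O*, *C*:
  `ΔRMSD(x) = RMSD(x, C) − RMSD(x, O)` (Kabsch-optimal, Cα), with frames
  classified closed at `ΔRMSD ≤ −0.1 nm`, open at `≥ +0.1 nm`, semi-open
  between, plus onset detection for the open→closed transition.
* **Flexibility and essential dynamics** — RMSF about the converged mean
  structure; PCA on Cα pairwise-distance features (rigid-motion invariant)
  or on superposed Cartesian coordinates (per-residue mode amplitudes).
* **Quasi-harmonic configurational entropy** — from the mass-weighted
  covariance spectrum λᵢ, mode frequencies ωᵢ = √(k_BT/λᵢ) and
  `S = R Σᵢ [xᵢ/(eˣⁱ−1) − ln(1−e^(−xᵢ))]`, x = ħω/k_BT, with the Schlitter
  upper-bound variant from the same spectrum.
* **Gromos clustering** — greedy medoid clustering at an RMSD cutoff
  (0.2 nm default), deterministic tie-breaking.
* **Solvation** — first-hydration-shell counts (0.5 nm, inclusive
  boundary; cell-list search that exactly matches brute force), block
  averaging, and bridging-water residence intervals at a two-atom site
  (0.35 nm to both, e.g. Trp-NE1 / Val-N).
* **Interactions** — hydrogen-bond occupancy (0.35 nm / 120°),
  salt-bridge minimum N–O distances, surface charge-center geometry and
  dielectric-screened Coulomb energies (ε = 80).
* **Synthetic ground truth** — a generator that builds toy helix-bundle
  reference pairs, staged open→closed transitions with a planted
  ΔRMSD-crossing frame, Gaussian ensembles with prescribed entropy, and
  scripted solvent — so every analysis is validated against exact answers.

Everything runs on plain containers (a `topology` data frame + coordinate
frames in nm + times in ps) read from multi-model PDB, with a small atom
selection grammar (`alphacarbon`, `protein`, `water`, `name`, `resid`,
`chain`, `and`/`or`).

## Worked example

Generate the default synthetic transition (1000 frames, open→closed with
the noise-free crossing planted at 40% of the run, 0.02 nm noise), track
the state metric, and detect the closed-state onset:

```r
library(lbdtraj)

spec   <- synthetic_spec(seed = 1)
refs   <- make_references(spec)          # 60-residue four-helix bundle
bundle <- make_transition_trajectory(spec, refs)

dr     <- delta_rmsd_series(bundle$trajectory, refs$pair)
states <- classify_states(dr)
onset  <- detect_closed_onset(dr)
```

Printed results (these are the numbers the example produces):

```
reference pair: 60 CA atoms, open/closed RMSD 0.6000 nm
planted noise-free crossing: frame 401 (40000 ps)
detected closed onset:       frame 400 (39900 ps)
states
   closed semi-open      open
      597       114       289
```

The references are 0.6 nm apart, so ΔRMSD starts near +0.6 nm (open),
falls through the −0.1 nm closed criterion at the planted frame, and the
detector recovers that onset to within one frame despite the noise. The
same bundle feeds the rest of the battery; `analysis/01…05` run it end to
end and print, e.g.:

```
distance-feature PCA: PC1 99.9%, PC2 0.1% of variance
PC1 sign recovers the planted state labels for 100.0% of frames
gromos clustering (0.2 nm cutoff): 2 clusters, sizes 100/100
closed-form quasi-harmonic entropy: 260.33 J/mol/K
estimate from 20000 sampled frames: 260.42 J/mol/K (0.035% off)
apo-like entropy exceeded bound-like in 20/20 replicates (mean 256.0 vs 187.6 J/mol/K)
hydration counts match planted truth in 100/100 frames
bridging waters: 2 intervals, mean residence 5500 ps, max 9100 ps
```

The `analysis/` directory is the narrative workflow (one numbered script
per stage, results under `results/`); the package functions underneath are
the API.

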