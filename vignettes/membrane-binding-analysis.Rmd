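---
title: "Methods: contact-based membrane-binding analysis of helical hairpins"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: contact-based membrane-binding analysis of helical hairpins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memhairpin)
```

## The problem

ESCRT-III-superfamily proteins such as IM30/Vipp1 bind and remodel
membranes through a conserved α-helical hairpin. Simulation studies of
such systems release the hairpin fragment above a lipid bilayer of
varying anionic (PG) content and ask: how fast does it bind, through
which residues, and how does its conformation differ between the bound
and unbound state? Fluorescence titrations of the same constructs ask
how tightly it binds. This package implements that analysis chain as
reusable, tested components, together with synthetic generators that
provide ground truth for every stage.

Units are nanometres and nanoseconds throughout; converters live only at
the I/O boundaries (PDB ångströms are divided by ten on read).

## Contacts

A contact is a (protein heavy atom, membrane heavy atom) pair within a
cutoff of 0.4 nm. Conventions worth stating explicitly:

* **Pairs, not atoms.** `count_contacts()` counts pairs; one protein
  atom touching two lipid atoms contributes two. Residue-level analysis
  instead uses the boolean "any contact" flag per residue, which is the
  quantity occupancy is defined on. Whether multiple membrane partners
  should be deduplicated is a genuine ambiguity of pair-based contact
  extraction; the pair definition is kept and documented.
* **Closed boundary.** A pair at exactly the cutoff counts.
* **Periodicity.** The minimum image is applied in x and y only;
  membranes here are z-oriented slabs and z is never wrapped. Full
  triclinic boxes are out of scope.
* **Exactness.** Pairs are found by spatial binning with cells at least
  one cutoff wide, so counts equal an all-pairs scan *exactly*; the
  test suite asserts integer equality against a brute-force oracle on
  randomized configurations. The reported per-frame minimum distance
  falls back to a full scan when no pair lies within the binned
  neighbourhood, because a cell list is only complete up to its cutoff.

## Binding kinetics

Binding is operationally defined as a sustained contact level: at least
`min_contacts = 5` pairs maintained for at least `bind_dwell = 5` ns.
This is deliberately conservative — transient grazes of the surface
should not count as binding events. After a binding event, a run below
the threshold lasting at least `unbind_dwell = 0.5` ns unbinds the
replica; unbinding is never recognised before the first binding event.

Two conventions required a decision:

* **Run duration.** A run of k frames counts as `k * dt` ns. The frame
  stride of the source data is unknown in general, so `dt` is a
  required trajectory property with no default; at `dt = 0.5` ns the
  0.5-ns unbinding dwell is one frame, at finer strides it is several.
* **Event time.** The binding time is the time of the *first* frame of
  the qualifying run (the first time sustained contact occurred), not
  the frame at which the dwell criterion is finally satisfied.

`first_binding_cdf()` sorts the per-replica first-binding times into a
non-decreasing step function whose plateau is the number of replicas
that ever bind, bounded by the number of replicas.

## Residue occupancy and the BCa bootstrap

Fractional occupancy of residue r is the fraction of analysed frames in
which r has at least one membrane contact. Each replica yields one
occupancy value per residue; the profile reports the mean over replicas.
Whether one should pool frames across replicas before dividing, or
average per-replica ratios, is ambiguous in pair-based protocols; the
per-replica average is the default here because it is the quantity the
bootstrap resamples, and the pooled variant is available via
`pooled = TRUE`. (The two coincide when replicas have equal length.)

Confidence intervals are bias-corrected accelerated (BCa) bootstrap
intervals over the replica-level values: 1000 resamples, level 0.95.
Replicas — not frames — are the resampling unit, because frames within a
replica are strongly autocorrelated and frame-level resampling would
fabricate precision. The bias term z0 is the probit of the fraction of
bootstrap means below the point estimate (clamped away from 0/1 so the
probit stays finite); the acceleration a is the jackknife skewness.
When all jackknife values are equal, a is undefined and the plain
percentile interval is returned with a notice; identical inputs give a
zero-width interval. The implementation is cross-checked in the tests
against an independent BCa implementation and by a Monte-Carlo coverage
experiment (Normal mean, n = 20, 500 repetitions, coverage required to
sit in [0.91, 0.985] at nominal 0.95).

## Essential-dynamics PCA

`fit_pca()` concatenates the frames of one condition, fits each frame to
a reference by Kabsch superposition (SVD route, reflections corrected so
the rotation is always proper), and diagonalises the covariance of the
fitted backbone coordinates. Decisions:

* **Reference.** The original protocols fit "concatenated and fitted"
  trajectories without naming the reference. The default here is the
  standard essential-dynamics choice: iterative refinement of the mean
  structure until it moves by less than 1e-6 nm RMSD; a single-pass fit
  to the first frame is available (`fit = "first_frame"`).
* **Atom subset.** Backbone N, CA, C, O of the residues up to
  `pca_last_residue` of the `fragment_spec()` — by default 26–151 of the
  26–156 hairpin fragment, excluding the highly mobile C-terminal
  stretch 152–156 whose fluctuations would otherwise dominate.
* **Training condition.** By convention the mixed 1:1 PC:PG replicas
  train the model and all conditions are projected onto its PC1; the
  package leaves the choice of training set to the caller.
* **Sign.** Eigenvector signs are fixed by making the largest-magnitude
  component positive, so projections are reproducible across runs.

The eigenvalue sum equals the covariance trace, training projections
have mean zero and variance equal to their eigenvalue, and eigenpairs
match a dense eigendecomposition — all asserted in the tests.

## Helix assignment

The helicity observable is the number of residues in α-helical
conformation per frame. Hydrogen bonds are scored with the
Kabsch–Sander energy E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)
kcal/mol (distances in Å), bonded when E < −0.5; a residue is α-helical
when it lies in a stretch supported by two consecutive i→i+4 turns.
Prolines never donate. Missing amide hydrogens are rebuilt 0.1 nm from N
along the preceding residue's O→C direction, the DSSP convention.

Only the α class counts as "helical" by default, because the observable
of interest is residues in α-helical conformation; DSSP variants that
fold 3₁₀/π helices into a generic "helix" class will report slightly
higher counts. On the deterministic ideal-helix fixtures the counts
here equal a reference DSSP implementation exactly (frozen in the test
suite: 18 of 20 and 22 of 24 residues).

## SASA

Shrake–Rupley with a 0.14 nm probe: each atom's van der Waals sphere is
expanded by the probe radius and sampled with a Fibonacci lattice of
960 quasi-uniform points (configurable; 960 trades ~0.5% quadrature
error against cost); the accessible fraction times the expanded-sphere
area is the atom's contribution. Radii are Bondi values; other SASA
codes ship their own tables, so absolute values can differ by a few
percent between programs — the meaningful comparisons (bound vs unbound,
residue vs residue) are internal. The analytic checks (isolated sphere
4π(0.29)² ≈ 1.0568 nm², two-sphere caps, additivity, monotonicity under
approach) hold within 1%.

## Conditioned distributions

Structural observables (helicity, SASA, PC1 projections) are split by
the bound/unbound state labels and summarised by Gaussian KDEs with the
Scott bandwidth sd·n^(−1/5) — the scipy/seaborn rule; base R's `bw.nrd`
carries an extra 1.06 factor, so the rule is computed explicitly. For
the discrete helicity counts a bandwidth multiplier of 2 smooths the
violin representation; it is a display convention, not an inference
choice. KDEs are normalized to unit area; an empty partition yields no
KDE and is flagged rather than erroring.

## Spectroscopy

* **GP.** GP = (I440 − I490)/(I440 + I490). Intensities at 440/490 nm
  are taken from the nearest sampled wavelength within 1 nm, else
  linearly interpolated — measurement grids vary and are rarely stated.
* **Emission normalization.** Spectra are divided by the mean apo
  intensity over the inclusive 333–337 nm window, so the apo spectrum
  is ≈ 1 near its Trp emission maximum.
* **Melt normalization.** The 222 nm ellipticity trace is mapped
  affinely so the 20 °C anchor is −1 and the 96 °C anchor is 0.
* **Hill fits.** Bounded Levenberg–Marquardt (minpack.lm) on
  GP0 + ΔGP·[P]ⁿ/(K_Dⁿ + [P]ⁿ), initialised at GP0 = GP at the lowest
  concentration, ΔGP = the GP range, K_D = the geometric-median
  concentration, n = 1, with K_D > 0 and n ∈ [0.25, 8]. Whether n
  should float or be fixed is protocol-dependent and both modes are
  provided (`fix_n`). The loss is unweighted by default (replicates are
  typically averaged upstream); a `weight` column enables weighted
  fits. Degenerate inputs — flat curves, too few points, a
  half-saturation outside the measured range, K_D with a relative
  standard error above 1 — set `low_confidence` instead of throwing;
  the apparent cooperativity is reported but never interpreted
  mechanistically. Fits are equivariant under concentration rescaling
  (K_D rescales, the other parameters do not).

## Surface coverage

`lipids_per_protein()` turns a bound-protein footprint into the
lipid-to-protein ratio needed to adsorb all protein: footprint area per
area-per-head-group, rounded per leaflet, times the leaflets counted
(10 × 2 nm² on 0.75 nm² gives 26.67 → 27 per leaflet → 54 total; the
unrounded value is co-reported). The rounding-then-doubling order
matches the convention of quoting "≈ 27 (1:54 total)".

`rsa_coverage()` is an exploratory random-sequential-adsorption
simulator: rectangles inserted at random positions (and orientations)
into a periodic square box, rejected on overlap (separating-axis test
with minimum-image displacement, which is why the box must exceed two
rectangle diagonals), stopping after a run of consecutive failures.
Literature coverage bounds for adsorbing particles (e.g. ≈ 20% for
elongated rectangles) come from richer kinetic models, so the simulator
output is context, not a reproduction target; for aligned unit squares
long runs approach the known jamming density ≈ 0.562 from below, and
the tests assert the band [0.53, 0.59] reached by finite runs.

## The synthetic generators

The generators exist to give every analysis stage inputs with known
ground truth; they emulate the *statistics* of a binding study, not its
physics.

* **Structures.** `build_ideal_helix()` places backbone atoms by
  internal-coordinate construction at given (φ, ψ, ω) with standard
  bond geometry; recomputing the dihedrals from the coordinates returns
  the inputs to 1e-4°. `build_hairpin()` joins two antiparallel ideal
  helices (a 180° rotation about an in-plane axis) with an extended
  linker — the α1–α2 hairpin topology in its coarsest geometric form.
  `build_membrane_slab()` is a jittered lattice of lipid bead stacks at
  0.75 nm² per head group, with `round(pg_fraction · n)` lipids
  labelled DOPG by seeded shuffle, and a uniform head-height jitter of
  ±0.18 nm emulating head-group roughness (real bilayers undulate on
  this scale; a perfectly flat bead plane would make the contact count
  an implausibly sharp step function of height).
* **Dynamics.** `simulate_binding_trajectory()` moves the peptide as a
  rigid body whose gap above the mean head-group plane follows
  overdamped Brownian motion (D_z = 0.1 nm²/ns, a realistic peptide
  diffusivity) in an exponential attraction well of depth
  `well_depth · pg_fraction` kT and range 0.3 nm, with reflecting
  boundaries at a 0.02 nm minimum gap and near the box top, plus
  0.02 nm per-atom Gaussian wobble. PG content enters *only* through
  the monotone well-depth scaling — the point is the qualitative
  anionic-lipid dependence of binding, not electrostatics. Frames are
  saved every 0.5 ns, 400 frames = 200 ns, the production length of a
  typical replica; the release height is 2 nm. The integrator substeps
  at ≤ 0.01 ns because the well is stiff on the frame-saving timescale
  (a plain Euler step at 0.5 ns overshoots the well and ejects the
  peptide). The peptide is laid with its long axis in the membrane
  plane — the binding-competent orientation — so orientational search is
  not part of the emulation; an initial tilt is configurable but
  orientational diffusion is not modelled.
* **Abstract series.** `generate_contact_series()` samples a two-state
  Markov chain with Poisson counts per state and returns the latent
  labels; over-dispersion is deliberately out of scope.
  `generate_binding_curve()` evaluates the Hill expression on the
  0.125–16 μM doubling series plus Gaussian noise.

All generators are pure functions of their parameters and seed.

**What passing tests do and do not show.** The emulator produces
trajectories whose binding statistics respond monotonically to the
attraction strength, and the pipeline recovers that ordering (median
first-binding time strictly decreasing over well depths 0, 2, 5 kT,
with 20 seeds per depth). That validates the analysis chain, not any
force field: real lipid chemistry, peptide flexibility on binding,
orientational kinetics and electrostatics are absent, so quantitative
agreement with all-atom MD observables is not implied. Conversely,
because ground truth is known, the latent-state recovery requirement
(≥ 95% frame-label agreement when bound/unbound count levels are well
separated and dwells far exceed the thresholds) is a genuine
correctness bound on the classifier, not a statement about easy data.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen
as the smallest sizes at which each property is sharply testable: a
19–27-residue hairpin over an 8 × 8-lipid slab for trajectory work (60
simulated replicas of 200 ns for the depth ordering), 100 randomized
configurations for the contact oracle, 500 Monte-Carlo repetitions for
bootstrap coverage, 200 seeds for the Hill noise calibration, and a
20 × 20 box for the RSA convergence study. Full-scale studies (131
residues, thousands of lipids, 20 replicas per condition) use the same
code paths; only the inputs grow.

## Known limitations

* Orthorhombic boxes only; minimum image in x,y.
* The α-only helicity count will sit slightly below DSSP variants that
  include 3₁₀/π helices.
* SASA absolute values depend on the radii table (Bondi here).
* The per-residue contact flag ignores how many pairs a residue forms;
  strongly and marginally bound residues with the same flag pattern get
  the same occupancy.
* The dynamics emulator is one-dimensional and rigid; it cannot produce
  conformational changes upon binding, so conformation analyses on
  emulated data exercise correctness, not biology.
* GRO parsing is fixed-column and expects well-formed files; PDB input
  goes through bio3d.
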