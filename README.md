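# memhairpin

Trajectory and binding-curve analysis for peptide–membrane association
studies of ESCRT-III-type α-helical hairpins (IM30/Vipp1-like membrane
binders). The package is aimed at simulators and spectroscopists who
need the full chain from raw coordinates to binding statistics:

* **Contact analysis** — heavy-atom protein–membrane contacts within a
  0.4 nm cutoff, counted pairwise with a periodic (x,y) minimum-image
  cell list; per-frame pair counts, minimum distances and per-residue
  contact flags.
* **Binding kinetics** — the sustained-contact operational definition of
  binding: ≥ 5 heavy-atom contacts maintained for ≥ 5 ns switch a
  replica to *bound*; after a binding event, < 5 contacts for ≥ 0.5 ns
  switch it back. First-binding times are summarised as a cumulative
  step function over replicas.
* **Residue occupancy** — per residue, the fraction of frames with at
  least one membrane contact (P_contact), averaged over replicas, with
  bias-corrected accelerated (BCa) bootstrap confidence intervals
  (1000 resamples, level 0.95; replicas are the resampling unit).
* **Conformation** — Kabsch superposition, essential-dynamics PCA of
  fitted backbone coordinates (with the mobile C-terminal residues
  excludable via `fragment_spec()`), Kabsch–Sander α-helix assignment,
  Shrake–Rupley SASA (probe 0.14 nm) for the whole protein and single
  tracked residues, and bound/unbound-conditioned KDE summaries (Scott
  bandwidth, ×2 for helicity violins).
* **Spectroscopy** — Laurdan generalized polarization
  GP = (I440 − I490)/(I440 + I490), emission-spectrum normalization to
  the apo 333–337 nm window, thermal-melt normalization to [−1, 0], and
  Hill binding-curve fits
  GP = GP0 + ΔGP·[P]ⁿ/(K_Dⁿ + [P]ⁿ)
  by bounded nonlinear least squares with apparent K_D and
  cooperativity n.
* **Surface coverage** — footprint → lipid-to-protein arithmetic (a
  10 × 2 nm² hairpin on 0.75 nm² head groups needs ≈ 27 lipids per
  leaflet, 1 : 54 total) and an exploratory random-sequential-adsorption
  simulator for rectangular footprints in a periodic box.
* **Synthetic data** — ideal helices, helical hairpins, PC/PG lipid
  slabs, Brownian-dynamics binding trajectories with a PG-scaled
  attraction well, two-state contact series with latent ground truth,
  and noisy Hill curves, so that every stage is testable end to end.

All user-facing functions take data frames (or the package's light
trajectory containers) and return tibbles; fitted objects have
`tidy()`/`glance()` methods and result types have `autoplot()` methods.

## Worked example

Six replicas of a hairpin released 2 nm above a pure-PG slab, analysed
for binding kinetics and residue occupancy, plus a Hill fit of a noisy
synthetic titration:

```r
library(memhairpin)
library(dplyr)

pep <- build_hairpin(12, 3, 12)
mem <- build_membrane_slab(8, 8, pg_fraction = 1, seed = 1, box_height = 3.5)
replicas <- lapply(1:6, function(i)
  simulate_binding_trajectory(pep, mem, well_depth = 5, pg_fraction = 1,
                              replica_id = i, seed = i))
contacts <- lapply(replicas, contact_series)
states   <- lapply(contacts, classify_states)

first_binding_cdf(states)
#> # A tibble: 6 × 2
#>    time cumulative
#>   <dbl>      <int>
#> 1   0            0
#> 2  16            1
#> 3  17.5          2
#> 4  20            4
#> 5  31            5
#> 6  53.5          6
```

All six replicas bind within 54 ns; the step function is the
first-binding-time CDF (plateau = number of replicas that ever bind).

```r
residue_occupancy(contacts, seed = 42) |>
  as_tibble() |> arrange(desc(p_contact)) |> head(3)
#> # A tibble: 3 × 4
#>   residue p_contact ci_low ci_high
#>     <int>     <dbl>  <dbl>   <dbl>
#> 1      36     0.735  0.631   0.78
#> 2      32     0.695  0.611   0.745
#> 3      37     0.619  0.545   0.666
```

The membrane-facing residues of helix 1 spend ~60–75% of frames in
contact; the interval is the replica-level BCa bootstrap.

```r
curve <- generate_binding_curve(gp0 = 0.05, delta_gp = 0.30, kd = 2.0,
                                n_hill = 1.5, noise_sd = 0.01, seed = 7)
fit <- fit_hill(curve)
fit
#> <mh_hillfit> KD = 2.271 +/- 0.27 uM, n = 1.68, GP0 = 0.0598, dGP = 0.289
glance(fit)
#> # A tibble: 1 × 6
#>      kd     n      rss converged low_confidence  nobs
#>   <dbl> <dbl>    <dbl> <lgl>     <lgl>          <int>
#> 1  2.27  1.68 0.000640 TRUE      FALSE              8

lipids_per_protein()
#> # A tibble: 1 × 5
#>   per_leaflet_ratio total_ratio per_leaflet_exact footprint_nm2 area_per_lipid
#>               <int>       <int>             <dbl>         <dbl>          <dbl>
#> 1                27          54              26.7            20           0.75
```

With 1% GP noise on an 8-point doubling series (0.125–16 μM) the
apparent K_D of 2.0 μM is recovered as 2.27 ± 0.27 μM.

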