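# aquapore

Channel-pore, crystal-water and lattice-defect analysis for
aquaporin-family membrane-protein structures, with trajectory statistics
for the substrate and water dynamics inside the channel.

## The problem

Aquaporin-family channels conduct small uncharged solutes — water,
glycerol, silicic acid Si(OH)₄ — through a ~30 Å pore whose narrowest
point, the aromatic/arginine selectivity filter (ar/R SF), sets substrate
specificity. High-resolution crystal structures of these channels resolve
the ordered water molecules that line the pore, and those waters carry the
mechanism: their hydrogen-bond network, their single-file (or broken)
connectivity, and the sub-sites they mark for a permeating substrate.
`aquapore` packages the computations that turn such a structure (plus MD
trajectories of it) into quantitative statements:

* **Lattice-translocation defect (LTD) correction.** Some membrane-protein
  crystals grow as two identical lattices offset by a fractional
  translation `t_d`, with population fractions `κ` and `1 − κ`. The
  observed intensity of reflection `h` is then modulated as

  ```
  I_total(h) = [(2κ² − 2κ + 1) + 2κ(1 − κ) cos(2π h·t_d)] · I_unit(h)
  ```

  `correction_factor()`, `correct_intensities()` and `estimate_defect()`
  model, invert, and estimate `(t_d, κ)` from a reflection table alone, by
  binning reflections on the phase `h·t_d mod 1` and fitting the cosine
  modulation at reflection-level least squares.

* **Pore profiling.** `compute_profile()` computes the HOLE-style
  maximal-inscribed-sphere radius `r(z)` along a channel axis with a
  deterministic planar grid + pattern-search optimiser (no simulated
  annealing, bit-reproducible), and `profile_with_wall_waters()` repeats
  the calculation with chosen ordered waters treated as part of the
  channel wall — the narrowing they cause is part of the selectivity
  argument.

* **Water networks.** `detect_hbonds()` (distance-only criteria, suited to
  structures without deposited hydrogens), `classify_waters()`
  (channel/vestibule/bulk census), `exclusive_pairs()` (sites too close to
  be simultaneously occupied, merged into exclusion groups),
  `single_file_segments()` (where the water wire is single-file,
  multi-file, or broken) and `infer_orientation()` (which way a water's
  oxygen points, from its donated hydrogen bonds).

* **Substrate placement.** `silicic_template()` builds an ideal Si(OH)₄
  tetrahedron (d(Si–O) = 1.63 Å, 109.47°); `fit_to_waters()` and
  `enumerate_placements()` superpose its hydroxyl oxygens onto subsets of
  channel-water positions (Kabsch over all injective assignments) to
  propose substrate sub-sites, scored by RMSD and steric clashes.

* **MD statistics.** `site_occupancy()`, `exchange_time()`,
  `count_permeations()`, `channel_counts()` and `axial_density()` compute
  site occupancy fractions, mean residence times τ, full channel-crossing
  events, per-frame in-channel counts and axial density bottlenecks from
  multi-frame trajectories.

* **Structure bookkeeping.** `read_structure()` (PDB/mmCIF via bio3d, tidy
  atom tibbles out), `count_entities()`, `mean_b_factor()`,
  `extract_sequence()`, `npa_spacing()` (the Asn-Pro-Ala motif pair and
  its spacing) and `superpose()` (sequence-aligned Cα Kabsch RMSD).

Every analysis has a seeded synthetic generator (`make_toy_pore()`,
`make_defect_reflections()`, `make_two_state_trajectory()`,
`make_permeation_trajectory()`, `make_count_trajectory()`) so the whole
pipeline is testable without downloading anything.

## Worked example

```r
library(aquapore)

# -- lattice-translocation defect: estimate (t_d, kappa) blind ------------
gen <- make_defect_reflections(5000, defect_model(c(1/3, 0, 1/3), 0.30),
                               noise_sd = 20, seed = 42)
fit <- estimate_defect(gen$observed)
fit
#> <ltd_fit> t_d = (0.333333, 0, 0.333333), kappa = 0.304  [3 phase classes, R^2 = 0.1591]

intensity_r_factor(gen$truth, gen$observed)$r_factor          # before
#> [1] 0.490
intensity_r_factor(gen$truth,
                   correct_intensities(gen$observed, fit$model))$r_factor
#> [1] 0.345
```

The generator hid `t_d = (1/3, 0, 1/3)`, `κ = 0.30` in the intensities;
the estimator recovers the translocation vector exactly and `κ` to 0.004,
and dividing out the fitted modulation drops the intensity R-factor
against the noise-free truth from 0.49 to 0.35 (the residual is the
injected measurement noise).

```r
# -- pore profile of a toy hourglass channel ------------------------------
hour <- make_toy_pore(function(z) 3.45 + 0.4 * abs(z), z_range = c(-12, 12),
                      ring_spacing = 0.5,
                      waters = data.frame(z = c(-2.6, 0.8, 2.8),
                                          lateral = c(0.9, 1.1, 0.8)))
ax <- channel_axis(c(0, 0, 0), c(0, 0, 1), c(-10, 10))
min_constriction(compute_profile(hour, ax, step = 0.25))
#>       z diameter
#> 1     0      3.5
min_constriction(profile_with_wall_waters(hour, ax, step = 0.25,
                                          water_labels = 1002))
#>       z diameter
#> 1   0.5     1.44
```

The wall rings prescribe a 3.5 Å constriction at z = 0 and the profiler
measures exactly that; promoting the ordered water near the constriction
to wall narrows the open diameter to 1.4 Å — the geometric footprint of a
water acting as part of the channel lumen.

```r
# -- two-state site occupancy and exchange time ---------------------------
ts <- make_two_state_trajectory(8000, p_occ = 0.94, dwell = 20, seed = 1)
st <- site_occupancy(ts$traj, ts$site, ts$candidates)
st
#> <occupancy_stats 'site'> occupancy 0.944 over 8000 frames
exchange_time(st, gap_tolerance = 0)
#>     tau n_episodes mean_frames
#> 1  2.13        355        21.3
```

A stably bound site (stationary occupancy 0.94, mean dwell 20 frames at
0.1 ns/frame) is recovered at 0.944 occupancy with a mean residence of
21.3 frames (τ = 2.13 ns) over 355 residence episodes.

Result objects are tidyverse-native: `tidy()`/`glance()` give tibbles,
`autoplot()` gives ggplots (`autoplot(fit)` draws the per-phase bin means
against the fitted cosine; `autoplot(profile)` the diameter profile).
`run_pipeline()` chains the structure stages (census → axis → profile →
waters → placements) and writes TSV/JSON outputs plus a run manifest;
`inst/exec/aquapore` is a thin command-line wrapper around it.

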