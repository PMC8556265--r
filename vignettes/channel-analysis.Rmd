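---
title: "Methods: channel, water and defect analysis in aquapore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: channel, water and defect analysis in aquapore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aquapore)
```

This vignette records the models, the tunable parameters, and the design
decisions behind each analysis stage, in the order a study would run them.
It states no numbers the test suite or `scripts/acceptance.R` do not
themselves compute.

## Structures as tidy atom tables

A structure is a tibble with one row per atom (author chain, residue
number and insertion code, atom name, element, coordinates in Å, isotropic
B in Å², occupancy) plus entry-level attributes (identifier, space group,
cell). Two conventions hold everywhere:

* **Author numbering is canonical.** Residues are always addressed by the
  numbers the depositors assigned; sequence indices are never exposed.
  This keeps every residue mention comparable with the literature on the
  structure.
* **One conformer per atom.** When alternate locations are present, the
  highest-occupancy conformer is flagged `primary` (ties: first in file
  order) and all analyses use primary conformers only. Hydrogens, when
  present, are excluded from censuses and B-factor means, matching how
  deposition tables count non-H atoms.

`superpose()` aligns two chains globally with identity scoring (match +1,
mismatch −1, linear gap −2, all configurable) before the Cα Kabsch fit.
The scoring hardly matters between homologous aquaporins — any sensible
scheme produces the same Cα pairing — which is why a substitution matrix
is not the default. RMSD is computed over a single monomer's aligned Cα
pairs with no outlier rejection by default; one round of rejection (pairs
beyond 2 × RMSD, then re-fit) is available because published RMSDs do not
always state their rejection policy, and the tolerance used when comparing
to literature values should absorb that ambiguity.

`npa_spacing()` reports the number of residues strictly between the two
Asn-Pro-Ala motifs. When a sequence contains more than two NPA matches,
the pair whose spacing falls in a 60–200 residue window and whose midpoint
is most central is selected; several equally central admissible pairs are
an error rather than a guess, because a silent wrong pairing would corrupt
a number that is compared across channel families.

## Lattice-translocation defect correction

The defect model: two identical lattices, translated by a fractional
vector `t_d` and populated with fractions κ and 1 − κ, diffract as one
crystal. The observed intensity is the single-lattice intensity times

$$ f(\mathbf h) = (2\kappa^2 - 2\kappa + 1) +
   2\kappa(1-\kappa)\cos(2\pi\,\mathbf h\cdot\mathbf t_d), $$

bounded in $[(1-2\kappa)^2, 1]$, equal to 1 whenever
$\mathbf h\cdot\mathbf t_d$ is an integer, and invariant under
$\kappa \to 1-\kappa$ — hence κ is reported in $[0, 0.5]$.

**Correction** divides intensities (and sigmas, as σ/f) by $f$.
Propagating σ/f is a choice: the alternative of re-estimating sigmas from
bin scatter conflates measurement error with modulation misfit, so the
simpler scaling is used and stated. Reflections with $f$ below a floor
(default 0.05) are corrected but flagged rather than silently amplified,
because noise amplification grows as $1/f$.

**Estimation** considers candidate vectors with components over rational
fractions of denominator ≤ 4 (translocation vectors in real crystals are
low-order rational; the list is a parameter). For each candidate,
reflections are grouped by the discrete phase $\mathbf h\cdot\mathbf t_d
\bmod 1$ and the cosine model is fitted by least squares over κ (grid step
0.005 on $[0, 0.5]$, then local refinement), with the intensity scale
profiled out analytically. Two details matter:

* Candidates are compared by **reflection-level** residuals, not bin-mean
  residuals. A wrong candidate that merges distinct phase classes can fit
  its few bin means perfectly while leaving the within-bin spread
  unexplained; only the reflection-level objective penalises the merge.
* A candidate that yields a single phase class carries no information and
  is skipped; if every candidate degenerates this way the defect is
  declared non-identifiable instead of returning an arbitrary answer.

Under the null (κ = 0) the fitted κ of the winning candidate is a maximum
over many candidates of small-sample fluctuation, so it is biased slightly
above zero at moderate reflection counts; the tests characterise this at a
problem size (20 000 reflections) where the fluctuation is well below the
effect sizes of interest.

The synthetic generator draws unit intensities from an exponential
(Wilson-like acentric) law — the simplest positive heavy-tailed model, and
sufficient because the estimator only consumes class means — applies the
modulation, and optionally adds Gaussian noise. With zero noise the
modulate→correct round trip is exact by algebra, and the tests assert it
at machine precision.

## Pore profiling

The pore radius at axial position $z$ is the radius of the largest sphere
centred in the plane normal to the channel axis that touches no wall
atom: $r(c) = \min_i(\lVert c - a_i\rVert - w_i)$ over wall atoms $i$ with
van der Waals radii $w_i$ (Bondi-style table, configurable; wall = polymer
non-H atoms by default, ordered waters opt-in). The centre is optimised
deterministically: a coarse grid (0.2 Å) over the search disc, then a
shrinking 8-direction pattern search down to 0.02 Å. Reproducibility is
the reason there is no simulated annealing; the optimiser is checked
against an exhaustive 0.05 Å grid in the tests.

The in-plane search disc is capped at 3 Å off-axis by default. A wider
cap (the first implementation used 8 Å) lets the globally optimal sphere
sit *outside* the channel wall wherever the wall is thin or the pore
flares — the optimiser then reports the exterior, not the pore. A 3 Å cap
keeps the probe near the axis, which is correct for aquaporin-like pores
whose centreline wanders little; the cap is exposed for channels that
need more.

Axis definition: origin at the midpoint of the two NPA asparagine
side-chain amide nitrogens; direction from the least-squares line through
labelled channel-water oxygens when at least four are available (they
trace the pore directly), otherwise from the anchor pair. The sign
convention — extracellular side at negative z — is a choice and is echoed
in output metadata, since published profile plots do not always state
theirs. Axial step 0.25 Å by default, finer than needed to resolve a
~3.5 Å constriction.

`pore_length()` reports the contiguous z-extent around the constriction
where the radius stays below a bulk threshold (default 5 Å). On toy pores
with atomically thin walls the measured extent overshoots the nominal
narrow span by a few Å on each side, because the probe stays small for as
long as the lip ring is within reach; solid-walled real proteins do not
show this artefact.

## Water networks

With no deposited hydrogens at 1.8 Å resolution, hydrogen bonds are
called on heavy-atom distance alone: O/N (S optional) pairs at ≤ 3.4 Å
bond, ≤ 2.8 Å are "typical" strong bonds. Both cutoffs are inclusive —
stated explicitly because verbal definitions ("shorter than", "more
than") leave the equality case open. Pairs within one residue are
excluded as covalent neighbours. No angular term is applied; that is a
documented limitation, acceptable at this resolution and standard for
water-network analyses of such structures.

Region classification is a calibration, not a measurement: the channel is
a z-interval on the axis (a water belongs if additionally within the
local pore radius + 1.4 Å margin, one water radius), vestibules are
flanking z-intervals with a 10 Å lateral cap, everything else is bulk.
The interval endpoints are knobs stored in the `region_spec` and echoed
in outputs; census counts are meaningful only together with the spec that
produced them.

Exclusion analysis: water-water distances below 2.5 Å mark pairs that
cannot be simultaneously occupied; transitively linked pairs merge into
exclusion groups modelling one molecule hopping between alternative
sites. The 2.5 Å cutoff sits strictly between the alternating-pair
distances observed in such structures (~2.3 Å) and the typical hydrogen
bond (2.8 Å), so the two regimes cannot be confused.

Single-file segmentation sorts channel waters by z, breaks the chain at
neighbour distances above the hydrogen-bond limit (3.4 Å — a broken wire
is exactly a gap no hydrogen bond spans), and classifies each remaining
run as single-file unless two of its waters are coeval (within half the
gap limit in z) yet more than 2 Å apart laterally, which makes the run
multi-file. Orientation inference uses a two-acceptor rule: a water
donating two bonds to acceptor-only partners (backbone carbonyl O,
carboxylate/amide side-chain O, or a hydroxyl committed as donor
elsewhere) that both lie on the wall side points its hydrogens at the
wall and its oxygen into the channel; anything weaker is reported
ambiguous, always with a rationale string, because a silent wrong
orientation would overstate what a hydrogen-free structure can show.

## Silicic acid placement

The substrate template is an ideal tetrahedron: Si at the centre, four
oxygens at 1.63 Å with all O–Si–O angles 109.47°, giving an O–O edge of
2.662 Å. An idealised geometry (rather than a small-molecule database
entry) keeps the package free of licensed data; the deviation from the
experimental small-molecule geometry is below 0.02 Å and irrelevant at
the 0.2–0.9 Å displacement scale the placements are read at.

`fit_to_waters()` tries every injective assignment of template oxygens to
the given 2–4 waters (≤ 24 Kabsch fits — the search *is* brute force, and
is additionally cross-checked against an independent enumeration in the
tests) and returns the best by (RMSD, clash count). Two geometric facts
shape the interface:

* With two waters the rotation about the water–water axis is unresolved
  by the fit; it is fixed by scanning the spin angle (5° default) and
  preferring fewer clashes, then more hydrogen-bond partners.
* With three waters the free oxygen has two mirror-related completions,
  both exact; the fit returns one, and consumers should treat the free
  oxygen as a tetrahedron completion, not an identified site.

`enumerate_placements()` generates z-contiguous windows of 2–4 channel
waters (the axial ladder a permeating substrate traverses; a full
combinatorial mode would be quadratic-to-quartic and is deliberately not
the default), keeps placements with RMSD ≤ 1 Å and zero clashes (clash =
protein atom within vdW sum − 0.4 Å of Si or O, the usual modelling
tolerance), ranks by (more oxygens mapped, smaller RMSD), and collapses
placements whose Si atoms sit within 2 Å — below any physically
meaningful separation of distinct sites. Hydroxyl hydrogens are not
modelled; every hydroxyl is assumed donor-capable, the same resolution at
which the structural reasoning operates. Note that three *collinear*
waters cannot be fitted by the 2.662 Å oxygen triangle better than
~1.56 Å RMSD — a geometric bound worth knowing when a ladder of strictly
on-axis waters returns no 3-water placements.

## Trajectory statistics

A trajectory is a frames × atoms × 3 array with per-atom metadata and a
frame time `dt` (ns). Statistics:

* **Site occupancy**: a frame is occupied when any candidate atom is
  within the site radius (default 1.4 Å, one water radius — "occupying a
  cavity" is not standardised, so the radius is a visible knob) of the
  site centre; the occupant is the nearest such atom.
* **Exchange time τ**: mean duration of residence episodes — maximal runs
  of one occupant identity, with vacant interruptions up to
  `gap_tolerance` frames (default 1) bridged to suppress single-frame
  flicker. τ is the mean episode length × dt; the episode count is always
  reported so the uncertainty (≈ mean/√episodes for geometric dwells) can
  be judged.
* **Permeation events**: a molecule crosses the entry plane and later the
  exit plane without re-crossing its entry plane in between; partial
  entries are discarded. With a periodic box, axial coordinates are
  unwrapped by minimum image before crossing detection. Time-reversing a
  trajectory swaps "in" and "out" labels, and a test asserts it.
* **Channel counts / axial density**: per-frame counts in the calibrated
  region (mean and population SD reported), and mean counts per axial
  bin. Bottlenecks are interior bin runs below 0.25 × median density
  flanked by higher density on both sides; the fraction is a parameter
  and 0 disables detection.

The two-state generator drives occupancy with a Markov chain: geometric
occupied/vacant dwells (the discrete analogue of exponential residence),
stationary occupancy `p`, mean occupied dwell `m` frames, hence mean
vacant dwell `m(1-p)/p` — which must be ≥ 1 frame, so high occupancy
requires proportionally long dwells (a 0.94-occupancy site cannot have a
15-frame dwell in a two-state chain; the generator refuses the
combination rather than silently producing a different process). Occupant
identity is resampled on re-entry. The closed-form estimator variance
$p(1-p)/n \cdot (1+\lambda)/(1-\lambda)$ with
$\lambda = 1 - 1/m - 1/m_\text{vac}$ gives the standard errors the tests
check against.

## What the generators do and do not emulate

The synthetic fixtures realise the *statistical* structure each estimator
consumes: cosine-modulated Wilson intensities; rings of pseudo-atoms with
prescribed inscribed radii; waters at scripted axial/lateral offsets;
Markov occupancy; scripted crossings with jitter. They do not emulate
real diffraction beyond the modulation model, protein force fields,
correlated water dynamics, or crystallographic symmetry. Green tests
therefore establish that the estimators recover known ground truth under
their stated models — not that any particular biological structure obeys
those models. The deposition-anchored checks that would close that gap
require the deposited coordinate files, which are too large to ship as
fixtures; the acceptance suite names the entries it needs and fails
honestly when they are absent.

Problem sizes in the tests and acceptance script (5000-reflection
estimates, 5000–30000-frame chains, ≤ 1200-atom toys) were chosen so each
stage's sampling error sits well below the tolerances being asserted
while the whole suite stays interactive.

## Known limitations

* mmCIF reading covers the coordinate (`atom_site`) content exposed by
  bio3d; esoteric categories are ignored.
* H-bond detection is distance-only; donor/acceptor assignment is
  rule-based and emits rationales instead of certainties.
* The pore optimiser has no continuity constraint between slices; the
  off-axis cap substitutes for it and must be loosened consciously for
  wandering pores.
* Water labels (Wat1…) are positional conventions of a given analysis,
  not identities carried in deposition files; mappings are reported, not
  assumed.
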