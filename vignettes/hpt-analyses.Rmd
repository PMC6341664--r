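---
title: "Models and methods behind hptkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hptkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hptkit)
```

hptkit bundles the four computational analyses used to study the conserved
*H + 4* glycine of histidine phosphotransfer (HPt) proteins: a family-wide
residue census anchored on the phospho-accepting histidine, dissociation
constant estimation from fluorescence titrations under ligand depletion,
percent-of-wild-type quantification of phosphotransfer gels, and structural
superposition/RMSD/clash analysis of mutant versus wild-type coordinates.
This vignette records the models, their assumptions, the tunable parameters,
and the design choices taken where a published protocol leaves the details
open.

## The anchor-relative conservation census

The census answers: across a protein family alignment, which residue sits
`k` positions downstream of the conserved phosphorylatable histidine? The
pipeline is `removeRedundancy()` → `findAnchorColumn()` →
`countOffsetResidues()` → `percentTable()`.

**Identity and redundancy.** Family databases over-represent well-sequenced
clades, so near-duplicate rows are collapsed before counting. Published
protocols typically say only "redundancy removed at 98% identity"; the two
unstated details are fixed here as follows.

* *Identity definition*: matches divided by the number of mutually aligned
  positions — columns where both rows carry a residue and neither is the
  unknown letter `X` — computed on the master alignment without
  realignment. This matches common alignment-viewer semantics; identity is 0
  when two rows share no usable column.
* *Clustering rule*: a single greedy pass in input row order. Each row joins
  the first existing cluster whose representative (the cluster's founding
  row) is at least `threshold` identical to it, else it founds a new
  cluster. The rule is deterministic, order-stable, and reproduces the
  planted grouping on generated data; the test suite checks it against an
  exhaustive all-pairs oracle. Because membership is judged against
  representatives only, the kept count can never decrease when the threshold
  is raised.

**Anchor detection.** The anchor is the column maximizing the fraction of
rows carrying the anchor residue (`H` by default), ties resolved to the
lowest index, with a 50% floor below which the family simply has no
conserved anchor and an error is raised. Rows lacking the anchor residue at
that column are removed, mirroring the usual "sequences lacking the
conserved histidine were removed" step.

**Offset in sequence coordinates.** `H + k` is measured in *ungapped*
coordinates: the census residue is the k-th residue after the anchor in that
row's sequence, skipping gap columns, because "four residues from the
histidine" is a statement about the polypeptide, not about alignment
columns (G68 = H64 + 4 in Ypd1 numbering). Rows whose chain ends before
`H + k` are tallied separately (`nShort`) and excluded from the percent
denominator.

**Percent table.** Percents are `100 · count / total` with half-up rounding
to 2 decimals, the convention used in printed census tables; on the
published H+4 family counts (total 10,073) this reproduces every printed
percent, e.g. glycine 86.94% and serine 10.43%, and a combined G+S+A share
that rounds to 98%. Non-standard letters (B, Z, J, U, O) are normalized to
`X` on input; `X` tallies are kept in the denominator by default (the more
conservative choice) and can be dropped with `excludeX = TRUE`.

**Logo information content.** `logoMatrix()` computes, per column, the
gap-excluded residue frequencies, Shannon entropy `H`, and information
content `log2(20) − H` bits, clamped at zero and optionally reduced by the
small-sample correction `(20 − 1)/(2 n ln 2)`. A pure column carries
`log2 20 ≈ 4.32` bits, a uniform column 0; letter heights are
`freq × info`. The numbers, not WebLogo's graphical styling, are the
product.

**Alignment handling.** Stockholm insert states (lowercase letters, `.`
gaps) are normalized to the same alphabet as match states and all columns
are treated uniformly; a census computed on a Pfam *full* alignment with
match-state-only semantics could therefore differ slightly. Columns are
1-based everywhere, as is idiomatic in R. Live family-database retrieval is
out of scope: family alignments are version-dependent, so published absolute
counts are treated as an input table, and the pipeline's correctness is
established on generated alignments with known composition.

## The ligand-depletion binding fit

In the fluorescence assay the labelled receptor is held at
`R_T ≈ 15.8 nM` (30 pmol in 1.9 mL) while the titrant spans 10 nM – 6 µM,
so at the low end of the titration a substantial fraction of added ligand is
bound: the free-ligand ≈ total-ligand shortcut of the hyperbolic isotherm is
invalid. `complexConcentration()` instead solves the mass-action quadratic
exactly,

$$[RL] = \frac{(R_T + L_T + K_d) - \sqrt{(R_T + L_T + K_d)^2 - 4 R_T L_T}}{2},$$

evaluated as `2·R_T·L_T / (b + sqrt(b² − 4·R_T·L_T))` with
`b = R_T + L_T + Kd`, which avoids catastrophic cancellation in the
stoichiometric limit (`Kd → 0` returns `min(R_T, L_T)` to machine
precision).

The observed signal is modelled two-state: after `F/F₀` normalization and
subtraction of the matched buffer-only series, the free-state fluorescence
cancels and

$$\delta(L_T) = A \cdot \frac{[RL]}{R_T},$$

with a single signed amplitude `A` (the fractional fluorescence change at
saturation). Choices fixed where the protocol is silent:

* **Dilution.** Cumulative dilution from titrant additions is assumed
  cancelled by the buffer subtraction (both series follow the same addition
  schedule). No per-point dilution correction is applied by default.
* **Drift.** An optional linear-in-`L_T` drift nuisance term is available
  (`fitBinding(..., drift = TRUE)`) but defaults to off; the buffer series
  already removes drift common to both series.
* **Weights.** Unweighted least squares by default; per-point weights are
  accepted.
* **Parameterization and bounds.** `Kd` is fitted as `log Kd`, keeping it
  positive and making the optimizer's steps scale-free across the nM–mM
  range; bounds are `Kd ∈ [1e-12, 1e-2]` M. Starting values are `Kd₀` = the
  `L_T` nearest the half-maximal response and `A₀` = the largest-magnitude
  response. The engine is Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  tight (1e-14) tolerances; standard errors come from the curvature at the
  optimum, the `Kd` error mapped back from the log scale by the delta
  method.
* **Degenerate data.** A constant response (e.g. zero amplitude) is an
  error, not a silent zero-information fit; fewer than 4 points is an
  error; a response set that does not bracket its own midpoint triggers a
  warning.

On noise-free synthetic curves the fit recovers `(Kd, A)` to better than
1e-6 relative across the experimentally observed span (0.5, 0.94, 2.9 µM).
Under the generator's 1% multiplicative noise with 20 points, single-fit
spread at the top of that span is roughly ±20%, which is why replicate
titrations are summarized (`summarizeReplicateFits()` reports the mean and
sample SD across replicates, the convention used for published binding
constants) and why simulation checks use the median over 100 seeded
replicates, which sits within a few percent of truth.

## Gel quantification

`percentOfWildtype()` normalizes each lane to the wild-type lane *of the
same replicate* (`100·I_x/I_WT`), then averages across replicates with a
sample (n−1) SD. Per-replicate normalization makes the statistic exactly
invariant to exposure differences between gels, which the test suite checks
by property. Densitometry itself (image → intensity) is upstream of the
package; an optional `background` column is subtracted before normalization
when supplied. Published percent-of-wild-type tables derive from raw gel
intensities that are not deposited, so the recoverable quantity is the
statistic, validated on generated lanes with planted activity levels.

## Structural comparison

`readPDB()` (via bio3d) keeps the first MODEL, resolves alternate locations
to the highest occupancy (ties prefer the blank/`'A'` conformer), and flags
waters/hetero records rather than dropping them. `matchAtoms()` pairs atoms
by (chain, residue number, insertion code, atom name) over the intersection
of the two structures, optionally through a chain map; insertion codes
participate in matching, and hetero atoms are excluded from superposition.

`kabschSuperpose()` is the standard SVD solution for the least-squares
proper rotation (reflections excluded by the determinant sign correction);
collinear inputs are rejected since the rotation about the line is
undetermined. "All residues" RMSD defaults to Cα atoms over the residue
intersection — published RMSDs rarely state their atom selection, and Cα is
the common default — with backbone and all-heavy-atom selections available.

**Global frame versus local fit.** `regionRmsd()` supports two readings of
"the RMSD of region R":

* `global_frame` — superpose on the full matched set, then measure R without
  refitting. This is how a statement like "the N-terminal helix shifts 1.7 Å
  while the active site moves 0.2 Å" is meant: deviation relative to the
  rest of the bundle.
* `local_fit` — superpose on R itself, measuring only internal deformation;
  a rigidly displaced helix scores ≈ 0 here. `local_fit ≤ global_frame`
  always.

One numerical caveat is worth stating because it affects how planted
displacements are validated: when a fraction *f* of the superposed atoms is
rigidly displaced by *d*, the full-set superposition absorbs part of the
shift and the naive global-frame RMSD of the region comes out near
`(1 − f)·d` (plus a rotation contribution). For an 11-residue helix in a
167-residue chain (*f* ≈ 6.6%) that is a ~7–15% underestimate. When the
question is "how far did this region move relative to the unperturbed
scaffold", the frame should be fitted on the complement of the moving
region, which `regionRmsd(..., fitRegion = )` supports; with that frame the
generator's planted 1.7 Å and 0.2 Å offsets are recovered within 5% (2%
coordinate noise included). The package keeps whole-set fitting as the
`global_frame` default because that is the conventional reported number.

`clashScan()` flags atom pairs whose van der Waals overlap
`r_a + r_b − d` exceeds 0.4 Å (the common severe-clash convention), using a
built-in Bondi-style radius table (C 1.70, N 1.55, O 1.52, S 1.80 Å;
unknown elements fall back to carbon) with hydrogens excluded by default.
The structures must already share a frame — the intended workflow for
questions like "does the mutant side chain occupy the partner's lysine
site" is: superpose the mutant onto the matching chain of the complex with
`kabschSuperpose()`/`applySuperposition()`, then scan the substituted
residue against the partner selection. Two carbons 2.0 Å apart overlap by
exactly 1.4 Å, the worked reference case in the tests. Comparing deposited
crystal structures requires their coordinate files locally; no retrieval is
performed by the package.

## What the generators emulate — and what they do not

All generators are pure functions of their design arguments and a `seed`
(`withr::with_seed`, so the session RNG is untouched).

* `generateAlignment()` plants an anchor column, an exact `H + k`
  composition, i.i.d. uniform background residues, per-column gaps at
  `gapRate` (default 0.1, the window `anchor..anchor+k` kept gap-free except
  in designed "too short" rows), near-duplicates within the 98% identity
  envelope, and anchor dropouts. Real family alignments are
  phylogenetically correlated, have position-specific conservation beyond
  the anchor window, and gap in blocks; passing census tests on generated
  data therefore demonstrates the bookkeeping (clustering, anchor logic,
  coordinate maps, tallies), not robustness to evolutionary structure.
* `generateTitration()` uses the default assay conditions (15.8 nM receptor,
  20 log-spaced points over 10 nM – 6 µM) with multiplicative Gaussian noise
  (default 1%, instrument-like) and an optional common drift ramp. Real
  titrations also carry correlated drift, pipetting error on `L_T`, and
  photobleaching, none of which are modelled.
* `generateGelLanes()` draws per-replicate exposure (log-normal, 10%) and
  per-lane activity noise in percentage points around the target means.
* `generateStructurePair()` builds a Cα trace on a regular helix
  (2.3 Å radius, 1.5 Å rise, 100°/residue — non-degenerate and
  protein-like in scale, default 167 residues to match an HPt monomer) and
  rigidly translates designated regions by designed offsets (seeded random
  direction) plus isotropic coordinate noise. It makes no attempt at real
  tertiary geometry or side chains.

## Problem sizes and numerical conventions

The shipped tests and the reproduction script use: a 1,000-template census
alignment (plus duplicates/dropouts/short rows) for the end-to-end pipeline
with the exhaustive clustering oracle run at ≤ 50 sequences; 100 seeded
replicate titrations per Kd for recovery medians; 167-residue structure
pairs (500 residues where the whole-set global frame itself is validated);
and 50-atom random selections for the clash oracle. These sizes give
sub-minute runs while leaving every statistic well away from its tolerance.

Conventions: alignment columns and residue positions are 1-based; percents
round half-up; greedy clustering follows input order; anchor ties break to
the lowest column; `which.max` semantics are relied on nowhere else.
Identity between rows with no usable shared column is 0. All counts,
frequencies and RMSDs are plain doubles — no unit objects — with molar
concentrations and Ångströms assumed in the interfaces.

## Known limitations

* No mmCIF parsing; PDB fixed-column format only, first MODEL only.
* The census treats all alignment columns uniformly (no Pfam match-state
  distinction) and cannot reproduce version-dependent absolute counts from
  live databases.
* Single-curve fits only; no global multi-curve analysis, anisotropy or
  FRET models.
* Clash scanning is a rigid-geometry screen: it knows nothing about
  rotamer relaxation, so a reported overlap is a statement about the static
  superposed models, not about the energetics of the complex.
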