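---
title: "Models and methods behind probekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind probekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probekit)
```

`probekit` packages the quantitative workflows used to characterize a
small-molecule chemical probe of a SAM-dependent methyltransferase: a
structure-based survey of how extensively an inhibitor contacts the bound
cofactor, rigid-body superposition and clash analysis, dose-response and
mechanism-of-action inference, thermal-shift and SPR binding analysis, and
ChIP-qPCR enrichment quantitation. This vignette records the models, the
defaults, and the numerical conventions, including the decisions taken where
more than one sensible convention exists.

## Structures and chemistry

### Parsing and the atom table

`parse_structure()` wraps the bio3d PDB and mmCIF readers and flattens their
output into a single atom table (one row per atom: names, element, location,
coordinates, occupancy, hetero/hydrogen flags). Two normalizations are
applied at parse time:

* **Alternate locations.** Within each (component, chain, residue, atom name)
  group only one conformer is retained: the highest occupancy, with ties
  broken by the lexicographically first altloc identifier. Distance tallies
  need a single deterministic conformer; averaging altlocs would fabricate
  geometry that exists in no conformer.
* **Element inference.** Legacy PDB files may lack the element column.
  Elements are then inferred from atom names: digits and primes stripped,
  two-letter symbols (FE, ZN, CL, ...) preferred when consistent with the
  component, while names on standard amino acids (CA, CD, CE, ...) resolve to
  their single-letter elements.

Coordinates are always in Å, and only the asymmetric unit as deposited is
used — no symmetry expansion or assembly building. A survey over deposited
coordinates measures the deposited interfaces; generating symmetry mates
would add contacts the depositors did not model as the biological complex.

### Component roles and the deny list

Every residue or heteroatom group becomes a component with exactly one role:
SAM/SAH are cofactors, polymer residues are polymer, heteroatom components
on a configurable deny list are excluded, and all remaining heteroatom
components are candidate ligands. The shipped deny list holds common ions
(NA, CL, MG, ZN, CA, K, MN, ...), buffer and cryoprotectant components (GOL,
EDO, PEG, PG4, ACT, DMS, MPD, TRS, ...) and waters. It is the package's
explicit, extensible approximation of the manual curation a human expert
would apply to a PDB-wide ligand list; it can never fully substitute for
expert curation of exotic components, which is why survey outputs carry the
rejection reason per record.

### Bonds, rings, hydrogens

Covalent bonds are perceived geometrically: atoms *i,j* are bonded when
*d(i,j)* < scale × (*r*<sub>cov</sub>(*i*) + *r*<sub>cov</sub>(*j*)), with
consensus covalent radii and a default scale of 1.3 — loose enough to bridge
the spread of real bond lengths, tight enough not to fuse nonbonded contacts.
Hydrogens bond only to their single nearest heavy atom. A component
"has a ring" when its heavy-atom bond graph contains a cycle (edges
exceeding nodes minus connected components); no aromaticity perception is
attempted, because the survey filter only asks whether a ligand is ring-
containing at all.

`add_hydrogens(mode = "geometric")` is a deterministic standard-valence
builder. For each heavy C/N/O/S atom the number of missing hydrogens follows
from the element's valence and a hybridization call made from local
geometry: wide angles (> 115°) or short conjugated bonds (mean < 1.45 Å for
C, < 1.42 Å for N) indicate sp², near-linear arrangements sp, everything
else sp³. The bond-length criterion matters in five-membered aromatic rings,
whose ~105° internal angles would otherwise masquerade as sp³. Hydrogens are
placed at standard bond lengths (C–H 1.09, N–H 1.01, O–H 0.96, S–H 1.34 Å)
along idealized directions; terminal sp² groups (e.g. exocyclic amines) are
placed in the plane of the neighbor's substituents. Polymer chains are
protonated as whole bonded units so peptide bonds are respected, and
deny-listed components — notably waters — are skipped entirely.

Known limitations of the builder, accepted deliberately: ring nitrogens with
two heavy neighbors never receive a hydrogen (correct for pyridine- and
imidazole-type nitrogens, wrong for pyrrole-type N–H); no formal-charge
model (carboxylates stay unprotonated because their C–O bonds are short,
amines get two hydrogens rather than an ammonium's three). An alternative
engine (`mode = "openbabel"`) shells out to the Open Babel command-line tool
when it is available, as an independently developed placement configuration;
`mode = "none"` gives heavy-atom-only analysis, which is clearly
non-canonical for the survey (the reference protocol protonates first) but
useful for sensitivity analysis.

## The interface survey

For one cofactor and one ligand, `tally_interface()` counts the ligand atoms
lying strictly within the cutoff (default 4.0 Å) of *any* cofactor atom, and
symmetrically the cofactor atoms within the cutoff of any ligand atom. The
comparison is strict (`<`), evaluated on unrounded coordinates, so an atom
at exactly 4.0 Å does not count. Hydrogens count on both partners once
modeled — both tallies are taken after protonation.

`run_survey()` enumerates every (cofactor instance, candidate ligand
instance) pair in every entry, rejects ring-less ligands (`no_ring`) and
empty interfaces (`zero_interface`) with reasons (deny-listed components are
never tallied at all), and deduplicates: among surviving records sharing the
same (ligand component, cofactor component) pair across entries, the one
with the largest combined tally is kept and the rest are flagged
`duplicate`. Output is sorted by descending combined tally. Fold-class and
target-atom annotations are expert metadata supplied via a table, never
computed — assigning a methyltransferase fold is a judgment the package
should not fake.

The tally engine is validated against a brute-force all-pairs double loop on
100 seeded random fixtures (exact agreement required), and by its
invariances: monotone in the cutoff, invariant under rigid motion of the
whole complex, heavy-atom tallies never exceeding protonated tallies.
A PDB-wide survey (1311 SAM/SAH entries in a 2019 snapshot, manually curated
to 97 unique pairs in the original analysis) is out of desk-scale reach —
it depends on a dated database snapshot and human curation — so the shipped
validation is fixture-based ground truth plus the single-entry check against
the deposited ternary complex when its coordinates are provided under
`inst/extdata/deposited/`.

## Superposition and clashes

`kabsch_superpose()` is the SVD solution of the orthogonal Procrustes
problem with the usual determinant correction that excludes reflections;
collinear coordinate sets are rejected as degenerate. Pairing is by atom
name (default Cα) under a residue-number offset or an explicit residue map,
dropping unmatched residues symmetrically. Optional trim cycles repeat the
fit after discarding pairs with residuals more than 2 SD above the mean —
the same refinement loop interactive alignment tools run — because a
published "overall" RMSD between two related structures is typically an
outlier-rejected value; both the raw and trimmed fits are available, and
pair counts are reported so the selection is explicit. Clashes use Bondi
van der Waals radii with a 0.4 Å overlap tolerance, the common steric-clash
convention; the threshold rule is recorded in the report.

## Dose-response and mechanism of action

`fit_4pl()` fits *y* = bottom + (top − bottom)/(1 + (*x*/IC50)^hill) by
Levenberg–Marquardt least squares, with IC50 parameterized on the log scale
(its natural scale; the standard error is mapped back by the delta method).
The Hill slope is free by default, fixable to 1 for sparse series.
Degenerate inputs (flat responses, inverted curves) yield a flagged
non-converged result rather than an exception, so batch pipelines can carry
on and report honestly.

`classify_moa()` regresses IC50 on the varied concentration. When per-point
standard errors accompany the IC50s — as they do when each point is itself
a fitted parameter — they are treated as *known*: the fit is weighted least
squares with weights 1/SE², the parameter covariance is (XᵀWX)⁻¹ without
rescaling by the residual variance, and the slope is tested with a
z-statistic. With only 3–5 concentrations in a typical series, estimating
the residual scale from the fit itself would leave 1–3 degrees of freedom
and badly miscalibrated intervals; propagating the known per-point errors is
the statistically appropriate choice. Without SEs an ordinary unweighted fit
with t-tests is used. A slope significantly above zero (two-sided, α = 0.05
by default) calls a competitive pattern, significantly below zero
uncompetitive, otherwise independent; for a competitive call on the
substrate axis the intercept and its SE are reported as K_i, per
IC50([S]) = K_i (1 + [S]/K_m).

## Thermal shift

`fit_boltzmann()` fits *F*(T) = F_pre + (F_post − F_pre)/(1 + exp((T_m −
T)/a)); T_m is by construction the temperature of the half-maximal
transition. Fits are flagged when the transition runs downhill (a melt must
gain signal with temperature) or when T_m falls outside the scanned range.
`thermal_shift()` reports ΔT_m = T_m(+ligand) − T_m(apo) and a binding call
against a threshold of 2 °C. Two comparison modes exist because two
conventions exist: the in-vitro screening rule is *strictly greater than*
2 °C, while cell-based engagement data are reported as binding at a shift of
exactly 2 °C, i.e. ≥; the mode is explicit in the result.

## SPR kinetics

The 1:1 Langmuir model is used in closed form: during association
R(t) = R_eq (1 − e^−(k_on·C + k_off)·t) with R_eq = R_max·k_on·C/(k_on·C +
k_off); after the association window R decays as e^−k_off·t. All traces
share k_on, k_off, R_max in a global fit, with rates parameterized on the
log scale. Initialization follows the classical two-stage route — per-trace
mono-exponential fits give k_obs per concentration, the k_obs-versus-C line
gives starting k_on (slope) and k_off (intercept), cross-checked against the
log-linear decay of the highest-concentration dissociation segment — which
makes the global fit converge to machine precision on noiseless data across
four orders of magnitude in both rates. Steady-state affinity
(R_eq = R_max·C/(K_d + C)) is fitted separately and warns when the sampled
concentrations show no curvature around K_d. Reference subtraction is
assumed done upstream; mass-transport limitation is not modeled.

## ChIP-qPCR enrichment

Enrichment of target over input chromatin is 2^−ΔCq with ΔCq = Cq_target −
Cq_input, so higher enrichment gives larger values. The propagated Cq-space
standard deviation is s = √(SD_input² + SD_target²), and because 2^−x is
convex, the symmetric ±s maps to *asymmetric* linear-scale limits
|2^−(ΔCq±s) − 2^−ΔCq|, upper strictly exceeding lower whenever s > 0 — the
implementation evaluates exactly this printed form. For H3 normalization
the package's convention (recorded in the output) is to propagate in log2
space: the ratio is 2^−(ΔCq_mark − ΔCq_H3), the two s values add in
quadrature, and the same limit form is applied to the ratio. Treatment
effects use a left-tailed two-sample t-test, pooled-variance or Welch per
flag, with the degenerate all-constant case returning p = 0.5 (the
symmetric null). Primer efficiency is not modeled; an optional additive Cq
offset handles percent-input dilution corrections.

## Synthetic data: what it emulates, and what it does not

Every generator is driven by a `synth_spec(seed, scenario, ...)` and is
byte-reproducible: the RNG stream is private to the call (the global seed is
saved and restored) and file output uses fixed-precision formatting. The
defaults are the study conditions of the assays the package models:

* **Dose–response** — 10 concentrations by 3-fold dilution from 50 µM
  (≈2.5 nM at the bottom), triplicate, truth bottom 0 / top 100 (percent of
  control) / IC50 80 nM / Hill 1, multiplicative log-normal noise with 5% CV.
  Multiplicative noise matches counting-type plate readouts, where error
  scales with signal.
* **IC50 series** — substrate axis: peptide at 1.25–20 µM (the assay's
  titration points) with K_i = 65 nM and K_m,peptide = 4 µM (the
  balanced-condition substrate concentration); cofactor axis: SAM at
  22–350 µM with K_m,SAM = 70 µM and the limiting constant chosen so the
  IC50 at saturating SAM matches the 80 nM potency. IC50 noise is
  log-normal (5% CV) with reported SE = CV × IC50.
* **Melt curves** — 30–70 °C in 0.5 °C steps, baselines 10/100, T_m 52 °C,
  transition width 1 °C, 2% multiplicative signal noise.
* **SPR traces** — five analyte concentrations from 1 µM by 0.33× dilution,
  60 s association, 120 s dissociation at 2 Hz, k_on = 1.2×10⁶ M⁻¹s⁻¹,
  k_off = 0.1 s⁻¹, R_max = 30 RU, additive 0.1 RU Gaussian noise.
* **Cq tables** — technical triplicates with additive normal Cq noise
  (SD 0.15 per well), a mark track whose ΔCq rises (enrichment falls) across
  inhibitor conditions and a constant H3 track.
* **Toy complexes** — an idealized SAM conformer (27 heavy atoms, computed
  small-molecule geometry with CCD atom names, shipped in source so ring
  perception is testable offline) plus a synthetic ringed ligand placed by a
  seeded search over anchor atoms and outward rays so that the brute-force
  tally equals the requested ground truth exactly; infeasible requests error.

What the generators deliberately do **not** emulate: real protein folds and
crystal-packing contacts, scintillation-bead physics, qPCR amplification
kinetics, instrument drift, or operator artifacts. Passing the recovery
tests therefore demonstrates that the estimators are correct and well
calibrated under their stated error models — it does not certify performance
on pathological real-world data, which is why the structure-based checks
against deposited entries are kept as separate integration tests.

## Problem sizes and numerical conventions used in the test suite

The shipped suite validates: exact oracle agreement of the tally engine on
100 random fixtures; Kabsch recovery of planted transforms to 10⁻⁶ on 20–100
atom sets; noiseless 4PL/Boltzmann recovery to 10⁻³ relative or better;
K_i coverage (within 2 SE in ≥ 90% of 200 seeded 5%-CV series); SPR rate
recovery within 1% at zero noise over 20 log-uniform rate draws (each with
concentrations spanning its K_d and time windows spanning its equilibration
— a well-designed experiment for each rate pair); type-I error of the MOA
slope test on 1000 flat series; and exact evaluation of the enrichment
limit formula against hand-computed values. These sizes keep the default
suite to a few seconds while leaving the statistical assertions
well-powered.

## Known limitations

* The geometric hydrogen builder is heuristic (see above); interface tallies
  involving unusual protonation states should be checked with the
  alternative engine.
* The deny list approximates expert curation and will misclassify rare
  components either way; survey records carry reasons so the decision is
  auditable.
* RMSD between two real structures depends on the atom selection; the
  package makes the selection explicit (pairing + trim cycles + counts)
  rather than promising a selection-free number.
* SPR fitting assumes reference-subtracted 1:1 binding; heterogeneous or
  transport-limited data will fit poorly and should be modeled elsewhere.
* ChIP quantitation assumes perfect primer efficiency (exact doubling per
  cycle), as the 2^−ΔCq form implies.
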