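---
title: "Designing chemogenomic screening libraries and calling hits from imaging screens"
author: "chemoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing chemogenomic screening libraries and calling hits from imaging screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemoscreen)
```

# The problem

A targeted ("chemogenomic") screening library is a compound collection
annotated with protein targets, assembled so that a phenotypic screen of
modest size still interrogates a wide target space. Building one from
public bioactivity extracts is a reduction problem: hundreds of
thousands of compound-target potency records must be curated down to
roughly one potent, structurally distinctive, purchasable compound per
target, without losing target coverage. The second half of the problem
is reading out the screen itself: imaging-based survival screens produce
nuclei counts per well, and hit calling needs a threshold that adapts to
each patient sample and concentration rather than a fixed cutoff.

`chemoscreen` implements both halves as composable, tested pieces, with
seeded synthetic-data generators that emulate the statistical structure
each stage assumes.

# Bioactivity curation and activity filters

The substrate is a long-format `BioactivityTable` of
(compound, target, assay type, value in nM) records, restricted to the
four multi-dose potency readouts IC50, EC50, Ki and Kd. Units are fixed
to nM in all files; there is no unit parsing. The filters run in a fixed
order (`designLibrary()` asserts the record count never grows):

1. **Replicate aggregation** (`aggregateReplicates`): multiple entries
   for the same (compound, target, assay type) collapse to their median.
2. **Potency cutoff** (`applyPotencyCutoff`): records above a liberal
   1000 nM default are dropped; the cutoff is inclusive, so a 1000 nM
   record survives.
3. **Target-specific filter** (`targetSpecificFilter`): per target, the
   pooled log10 potency distribution (assay types together) is z-score
   normalized and records strictly above the 80th percentile -- the
   least potent tail -- are removed. Because z-scoring is monotone this
   equals filtering on raw-value percentiles, which is exactly how the
   test oracle checks it.
4. **Global filter** (`globalActivityFilter`): log10 values are centered
   per target; the most variable target's 95th centered percentile
   becomes one global threshold applied to every target. Applying the
   removal on the *centered* scale (rather than raw values) is the
   design choice here: it makes the threshold a statement about spread
   around each target's own location, so a uniformly weak target is not
   wiped out wholesale.

Percentiles are linear interpolations between order statistics
throughout (the familiar type-7 rule); "within the threshold" is always
inclusive, matching the inclusive 1000 nM convention. Zero-variance
targets (single record, or all values identical) pass the percentile
filters unchanged, since normalization is degenerate there.

One caveat worth stating: the percentile filters are *not* idempotent.
Re-running one recomputes its percentile on the already-filtered data
and trims the new tail again. Only the absolute potency cutoff is a
fixed point of itself; the suite asserts exactly that, plus the subset
property for every filter.

# Structural similarity, deduplication, and the threshold scan

Fingerprints are abstract bit sets (`Fingerprint`, `FingerprintSet`)
compared with the conventional coefficient per kind: Dice for the
circular ECFP4/ECFP6 fingerprints, Tanimoto for 166-key MACCS.
Enumeration from SMILES goes through the ChemmineR/ChemmineOB
(OpenBabel) backend in `fingerprintCompounds()`; the backend's 4096-bit
circular fingerprints are OR-folded to the 2048-bit community default
(radius 2 and 3 for ECFP4/6). Everything downstream consumes bit sets
directly, so tests and the synthetic generator inject fingerprints
without any chemistry backend.

`dedupeNearDuplicates()` flags a pair as near-duplicate when **any** of
the held kinds reaches the cutoff (0.99 by default) -- the conservative
choice, since no combiner across the three kinds is prescribed -- then
clusters flagged pairs by transitive closure and keeps the *last*
compound of each cluster in input order. Keep-last mirrors the
convention that of a redundant pair the first-listed compound is the one
removed (the doxorubicin/epirubicin situation).

## Choosing the similarity cutoff

What similarity counts as "redundant" is data-dependent, so
`selectSimilarityThreshold()` chooses it by a grid scan resting on one
assumption: structurally similar compounds should have similar activity
distributions. For each of three seeded 10% compound subsamples, all
pairwise similarities are computed; for every grid threshold t (0.10 to
0.99, step 0.01) the pairs at similarity >= t are scored by the
two-sample Kolmogorov-Smirnov statistic D between the two compounds'
log10 activity value sets, and the threshold score is

    AIC(t) = m_t * ln(SS_t / m_t + 1e-12) + 2,

with m_t the evaluated pair count and SS_t the sum of squared D. This
treats the mean squared K-S distance among pairs called "similar" as the
residual error of a one-parameter model: the score is low when the
threshold admits many pairs whose members genuinely share activity
distributions. No closed formula is prescribed for this criterion in the
field, so the scoring function is a pluggable argument (`scoreFun`);
swapping in another information criterion does not touch the scan.
Numerical guards: pairs where either compound has fewer than 3 activity
values are skipped (K-S on tiny samples is degenerate); grid points with
fewer than `minPairs = 5` evaluated pairs are inadmissible; AIC ties are
broken towards the *largest* threshold (the least aggressive merge); the
final selection is the per-seed median, snapped back onto the grid.

# Target-space expansion and library assembly

`expandTargetSpace()` implements the two-hop network expansion: first
neighbors are proteins directly and physically interacting with a
cancer-associated seed target, influencers interact directly with a
first neighbor. Edges are symmetrized and self-loops dropped, so the
result is invariant to edge order and direction, and the three sets are
pairwise disjoint. Mutant target variants are modelled as distinct
targets carrying a `mutant_of` annotation and are treated independently
throughout -- representatives are chosen separately for a mutant and its
wild-type parent, since no sharing rule is prescribed.

`pickRepresentativePerTarget()` selects, per target, the record with the
lowest value in nM across all four assay types, which are deliberately
treated as equivalent (bioactivity extracts are too sparse to model
assay-type effects). Ties break deterministically: smaller compound id,
then assay type in the order IC50, EC50, Ki, Kd.
`substituteUnavailable()` then walks each unavailable representative's
target down the ascending-potency list to the first available compound;
targets with none become `uncoveredTargets`. Compounds with *unknown*
availability count as unavailable -- the conservative reading when the
point of the step is purchasability. `coverageSummary()` counts targets
per compound and compounds per target from records at or below the
potency cutoff, so "coverage" always means measured potent activity,
including off-target activity of the selected compounds.

# Imaging-screen analysis

Per plate, the survival fraction of a well is its nuclei count divided
by the mean nuclei count of the plate's DMSO wells; the z score is the
number of DMSO-derived standard deviations (sample sd) the survival
fraction sits from the DMSO mean. Profiles aggregate replicate wells by
mean. `doseAUC()` summarizes a profile by the trapezoid rule over log10
concentration, normalized by the log-concentration span so that a
constant response c has AUC = c -- the AUC shares the survival-fraction
scale and lower values mean a more active compound; the raw trapezoid
area is attached as an attribute for anyone preferring unnormalized
areas.

## Data-driven hit thresholds

Most compounds in a molecularly targeted library do nothing in any
given cell model, so the survival-fraction distribution of a (patient,
concentration) stratum is a heavy peak near 1 plus a small tail of
real responses. `fitBackgroundMixture()` models this as a two-component
Gaussian mixture fitted by EM: the background component initialized at
the anchor (1 for survival fractions, 0 for z scores) with weight 0.9
and the sample sd, the active component at the 5th percentile of the
data with weight 0.1. Convergence is declared when the log-likelihood
improves by less than 1e-6 (at most 500 iterations); the trace is kept
and asserted non-decreasing in every test that fits a mixture. If a
component collapses (sd < 1e-6 or weight < 1e-3) -- which happens
routinely on strata with no active compounds at all -- the fit falls
back to a single background Gaussian with a warning, which is the
correct model for that situation.

The activity threshold is the **analytic** quantile of the fitted
background component, mu_bg + z(p) * sigma_bg, not an empirical data
quantile: the percentile is a statement about the background model, and
the empirical 0.01th percentile of a few hundred values would be
nonsense anyway. "0.01 percentile" is read literally as the 0.01th
percentile, i.e. lower-tail probability 1e-4 (not the 1st percentile);
it is a `ScreenConfig` parameter, as is the readout (survival fraction
or z score) the mixtures and calls are based on. Mixtures are fitted
separately per patient and concentration, pooling all compounds.

A compound is a **strong hit** for a patient when its readout is
*strictly below* the (patient, concentration) threshold at every tested
concentration; equality is not "under" the threshold. The study-level
hit set is the union over patients, with per-patient calls retained so
stricter all-patient definitions can be recovered from the same output.

# What the synthetic generators emulate

`synthBioactivity()` plants the structure the similarity scan assumes.
Compounds belong to redundancy clusters; cluster members share a core
bit set plus member-specific unique bits, calibrated so every
within-cluster pairwise Dice similarity lies in [s*, s* + 0.035] while
compounds from different clusters share no bits at all. Members of a
cluster draw activities from identical per-target log-normal
distributions (4 targets per cluster, potency locations N(2, 1) in
log10 nM -- centered on 100 nM -- with a cluster shift of sd 0.5 and
replicate noise of sd 0.3). With this geometry the scan's AIC is flat
and minimal on every threshold at or below the weakest within-cluster
similarity and rises as soon as true cluster pairs are lost, so the
largest-threshold tie-break lands on the planted cutoff; the
construction caps the recovery error at about 0.035 by design, and the
suite requires a median error of at most 0.05 across planted cutoffs
0.5, 0.7 and 0.9. The defaults (500 compounds in 25 clusters of 20)
are sized so that a 10% subsample still contains comfortably more
within-cluster pairs than the scan's five-pair admissibility floor.

`synthScreen()` emulates the pilot-screen layout: 6 patients, four
10-fold concentrations 3--3000 nM, 16 DMSO and 8 positive-control wells
per plate, Poisson(2000) control nuclei counts. Inactive compounds draw
survival fractions from N(1, 0.05); planted hits (10% of compounds)
draw from N(0.3, 0.1) at every dose, with a mild monotone dose effect
(the active mean scales from 1.15x at the lowest to 0.85x at the
highest dose). Treated counts are the control mean scaled by the drawn
survival fraction and rounded, so re-derived survival fractions carry
realistic quantization and control-sampling noise. Ground-truth labels
ride along, which is what the sensitivity (>= 0.9) and null-specificity
(>= 95% of null-only screens with zero hits) checks are computed
against.

What the generators deliberately do **not** emulate: real chemistry (no
molecular structures behind the planted fingerprints), assay-type
biases, plate-position or edge effects, batch drift between plates, and
partially overlapping redundancy clusters. Passing tests therefore
demonstrate that the machinery is correct under its own model
assumptions, not that those assumptions hold for any particular real
screen.

# Problem sizes and reproducibility

The test suite and the acceptance script run everything at the
generator defaults: 12 synthetic libraries of 500 compounds for
threshold recovery, 2000-value mixtures for parameter recovery, and 30
full synthetic screens (10 with planted hits, 20 null) for the
operating characteristics -- sizes chosen so each stage's statistical
claims are testable with stable margins. All generators are pure
functions of (config, seed): they restore the caller's RNG state, and
identical seeds give byte-identical outputs.

# Known limitations

* The AIC-style threshold score is one defensible construction of an
  under-specified criterion; it is pluggable precisely because
  reasonable alternatives exist.
* Selectivity-aware fallbacks when a representative is unavailable
  (picking the most potent *and selective* alternative) are not
  modelled; substitution ranks by potency alone.
* No exact set-cover or multi-objective optimization: the per-target
  greedy selection is the deliberate, fast heuristic.
* SMILES is the only structure input; SDF chemistry, 3D and
  pharmacophore fingerprints, and scaffold analysis are out of scope.
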