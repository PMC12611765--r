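---
title: "Semi-targeted epilipidomics: methods and design notes"
author: "epilipidR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-targeted epilipidomics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epilipidR)
```

This vignette is the package's account of the science it implements: the
models and rules of each stage, the tunable parameters with their
defaults and rationale, the numerical choices, what the synthetic-data
generators do and do not emulate, and the known limitations.

## Mass and formula arithmetic

Every m/z in the package derives from an `ElementalFormula` (integer
counts over C, H, D, N, O, P, Na, S) and a pinned table of IUPAC
monoisotopic atomic masses, so all values are bit-stable across runs.
Deuterium is a first-class element symbol: isotope-labelled standards
such as hexadeuterated coenzyme Q10 (C59H84D6O4) carry exact masses.

Two electron-mass conventions are supported per adduct. The default
proton convention subtracts one electron mass per positive charge, so
`[M+H]+` adds m(H) − m(e). The hydrogen-atom convention omits the
electron correction; it exists because some acquisition software reports
product-ion m/z this way, and both conventions are needed to reproduce
published transition values at their printed precision. Within the
package the proton mass is *defined* as m(H) − m(e) (1.00727645 Da)
rather than the free-proton value (1.00727647 Da; the difference is the
hydrogen binding energy, 1.5e-8 Da) so that identities such as
m/z([M+H]+) − m/z([M−H]−) = 2 × proton hold exactly in floating point.
This is five orders of magnitude below any printed precision.

Species formulas are assembled as backbone/headgroup base plus free
fatty acid (or fatty alcohol, for ether/vinyl-ether chains) per radyl
chain, minus one water per condensation. SM and Cer use the d18:1
long-chain-base convention: printed totals include the base, and the
N-acyl is (C−18):(D−1). Oxidation modifications change composition by
`<OH>` +O, `<OOH>` +2O, `<oxo>` +O−2H, `<epoxy>` +O — the standard
shorthand semantics; double-bond counts in names are left unchanged.

The packaged transition table (`quinoneTransitionTable()`) stores
*formulas*, and computes m/z at load time. Published tables of this
panel occasionally contain transcription errors — for example, a CoQ8
multiple-reaction-monitoring table in circulation prints the `[M+H]+`
and `[M+NH4]+` precursor m/z swapped relative to what C49H74O4 implies.
Computing from formulas makes such errors non-propagating.

## In silico oxidation

`enumerateModificationSets()` enumerates all non-empty combinations of
OH/oxo/OOH/epoxy counts subject to per-modification caps, a site cap
(interpreted as *total modification groups per lipid*) and an
added-oxygen cap. The defaults (sites ≤ 2, O ≤ 3, OH ≤ 2, oxo ≤ 1,
OOH ≤ 1, epoxy = 0) produce seven sets. Eligibility for oxidation is at
least one double bond among the chains; no per-double-bond capacity
accounting is attempted (a lipid with one double bond may formally
receive two modification groups — the constraint caps, not
radical-chemistry site counting, are the model). Modifications are
tracked at species (sum-composition) level, because that is the level at
which oxidized species are reported and at which isomers are ultimately
collapsed; chain-resolved placement exists only transiently inside
fragment prediction.

Target selection takes the per-class top-N lipids by mean raw intensity
(defaults: 10 each for PC, P-PC, O-PC, PE, P-PE, O-PE; 20 each for TG
and CE) plus, optionally, the top 10 lipids positively Pearson-correlated
with a phenotype vector. Ties break by name so selection is
reproducible; the union is deduplicated by species identity, since the
intensity-top and correlation-top sets may overlap.

## Acquisition lists

Inclusion lists carry one entry per (species, adduct), deduplicated at
5 ppm and sorted by m/z; sodiated adducts are the default. Note that
isobaric modification sets (`<2OH>` vs `<OOH>`, both +2 O) necessarily
merge here — seven oxidized species of one parent give six m/z targets.

Iterative exclusion for deep profiling takes a prior run's fragmented
precursors and excludes them from the next run. Defaults: RT window
0.3 min, noise count 15, m/z window 0.02 Th, maximum RT 36 min. The
noise floor is implemented as "keep precursors whose intensity exceeds
the 15th-lowest recorded signal" — the wrapped tool's exact formula is
not public, so the parameter is interpreted as a rank-based floor and is
configurable. Merging is greedy in ascending m/z: a record joins a
cluster when within both windows of the cluster seed; each cluster keeps
its most intense member. Wider m/z windows can only merge more records,
so the list size is non-increasing in the m/z window (and in the noise
count).

## Identification

Fragment prediction places the species-level modification set on each
unsaturated chain in turn and emits, in positive mode (sodiated
oxTG/oxCE/oxDG): the intact oxidized fatty acid as `[oxFA+Na]+` and
`[oxFA+H]+`, their water losses, acyl neutral losses from the precursor,
and the cholestenyl headgroup diagnostic for CE; in negative mode
(oxPC/oxPE): `[oxFA−H]−`, its water loss, and unmodified acyl anions.

**Oxygen retention.** A fragment is evidence for a fatty-acid-specific
modification only if it retains at least one added oxygen. Water losses
from an oxidized acyl are debited against the added oxygens (dehydration
occurs at the modified position): `<OOH>` (+2 O) survives one water loss
with one oxygen retained, `<OH>` (+1 O) does not. Equivalently, for
fatty-acyl fragments, retention holds exactly when the neutral fragment
formula carries three or more oxygens — this formula-level accounting is
what the code computes and what an independent oracle re-derives in the
tests. Acyl neutral losses retain the oxygens iff the *lost* acyl is
unmodified.

**Scores.** The original acquisition software's score formulas are not
published, so the package defines three transparent scores on [0, 100]
and keeps the published thresholds (score > 60, isotope score > 80,
rank score > 40, all strict):

- *score*: mean of (fraction of predicted fragments matched) and
  (fraction of considered peak intensity explained by matches);
- *isotope score*: 100 × cosine similarity between the recorded MS1
  isotope envelope and a theoretical three-isotopologue envelope
  (dominated by 13C; 100 when no envelope was recorded);
- *rank score*: mean normalized intensity rank of matched peaks (the
  rank-score definition operates over fragments, not candidates — a
  local definition, flagged as such).

Peaks below 1 % of the base peak are ignored; precursor matching is
symmetric ±5 ppm; fragment matching ±20 ppm.

**Isomer collapse and evaluation.** Modification sets with identical
composition deltas produce byte-identical fragment m/z, so species-level
attribution between such isomers is undefined in principle. The
workflow therefore collapses identifications to unique m/z targets
(greedy 5 ppm grouping, best score kept), and the package's benchmark
metrics are computed at this collapsed level. On the default synthetic
benchmark (200 true + 200 decoy spectra, seed 1) precision and recall
are both 1.0.

**KMD–RT filter.** Within a homologous series (same class, modification
set and double-bond count) the Kendrick mass defect is linear in
retention time; members deviating by more than 3 studentized residuals
from a least-absolute-deviations fit are flagged as false positives.
LAD is fitted by Nelder–Mead from an OLS start; the residual scale is
1.4826 × MAD with a small relative floor so that exactly-collinear
series do not divide by zero. Groups with fewer than three members pass
unflagged. With a 3-residual threshold, Gaussian measurement noise will
occasionally push an extreme genuine member past the threshold
(about 3 % of ten-member series); the filter is a screen, not a proof,
and the flags carry the residuals so borderline cases can be reviewed.

## Quantification

Extracted ion chromatograms sum peak intensities within ±5 ppm per scan.
Peak areas are trapezoidal above a baseline drawn linearly between the
integration-window endpoints — a deterministic replacement for manual
curation; the window defaults to ±0.5 min around the expected retention
time. PRM transitions select scans whose recorded isolation window
(default width 1.2 Th) contains the precursor, then integrate the
product-ion trace; transitions with no matching isolation are flagged,
not fatal.

Normalizations are exact ratios (class internal standard, per-sample
protein), hence invariant to global intensity rescaling. Isotope
dilution multiplies the analyte/standard area ratio by the spiked
standard amount (2.5 pmol of CoQ10-d6 in the reference protocol).
Redox metrics: total = CoQ + CoQH2, reduced fraction = CoQH2/total, and
a mole ratio per neutral lipid when a neutral-lipid amount is supplied.
External calibration is an OLS line with reported R²; back-calculation
inverts it and flags extrapolation beyond the calibrated range.

## Statistics

The transformation pipeline is log10 followed by autoscaling (per-feature
mean 0, sd 1 with the n−1 denominator); zeros and missing raw values are
replaced by one fifth of the feature's minimum positive value (the
conventional small-value substitution) and recorded per cell. Tests are
Welch two-sided t-tests — the unequal-variance form is the safer default
when only "two-sided t-test" is specified — run on the autoscaled matrix
(scaling is per-feature affine, so t statistics equal those on log10
data), with Benjamini–Hochberg q-values. Fold changes are ratios of raw
group means, and volcano labels require strictly |FC| > 2 and q < 0.05.
Clustering is Ward (`ward.D2`) on Euclidean distances of autoscaled
profiles. Essentiality–metabolite correlation is plain Pearson with
pairwise-complete observations; constant or short metabolite vectors are
flagged rather than guessed.

The suite verifies calibration empirically: across 200 all-null
simulations (1000 features, n = 4 vs 4, the generator's 20 % CV) the
fraction of q < 0.05 features stays within Monte-Carlo error of the
nominal rate, and planted 4-fold effects are detected with power ≥ 0.9
under the dual thresholds.

## Kinetics

Inhibited-autoxidation traces have two phases: a lag (antioxidant
consumption) and a propagation phase. `lagTime()` intersects a baseline
tangent (OLS over the first 10 % of points) with a propagation tangent.
The propagation tangent is fitted by OLS over the points whose
baseline-subtracted, lightly smoothed signal lies in the 25–75 % band of
the total rise — for two-phase kinetics these points lie on the
propagation segment, so this is a tangent estimate that is far more
noise-stable than taking the single maximum windowed slope (whose
maximum-of-noisy-estimates bias is substantial at realistic noise).
Decision rules: a trace whose global linear fit explains > 98 % of the
variance with positive slope is uninhibited (lag 0; lags below ~2 % of
the observed span are reported as 0 by this rule); a trace whose excess
rise never exceeds five baseline noise SDs is censored (propagation not
observed). The estimator is invariant under affine signal rescaling, and
median lag error is below 5 % at signal-to-noise 20 across 100 simulated
traces with a 10,000 s breakpoint.

`propagationRate()` keeps the plain maximum-windowed-slope definition
(window width configurable). Under noise the maximum over many windows
is upward-biased; use wide windows (≈ 100 points at 30 s sampling) for
quantitative rates, or compare rates only between traces analysed with
identical settings.

## Synthetic data: what it emulates, and what it does not

The generators produce every input format the pipeline reads, seeded and
byte-reproducible:

- *Lipidome tables*: log-normal intensities per feature (class-level
  location drawn in a two-decade window around 10^6; log10 scale 0.0857,
  i.e. ~20 % CV, matching four-replicate cell-culture lipidomics);
  planted fold changes applied multiplicatively to the second group.
- *MS/MS spectra*: true spectra carry 90 % of the predicted fragments
  with ±5 ppm uniform jitter and log-normal intensities over a low noise
  floor; decoys keep the true precursor (so precursor-level filters stay
  engaged) but randomize all peak positions; a "non-retaining" mode
  builds spectra solely from oxygen-losing fragments to exercise the
  evidence filter.
- *PRM runs*: Gaussian elution peaks (σ = 0.05 min, 0.01 min sampling)
  whose areas are amount × response factor; noise, when requested, is
  per-scan multiplicative Gaussian with sd 1/SNR (shot-noise-like; an
  additive-everywhere model would rectify at zero in the tails and bias
  areas upward).
- *Kinetic traces*: piecewise-linear lag/propagation with additive
  Gaussian noise; the coupled NADH channel decays to zero exactly at the
  lag breakpoint.

Passing tests on these generators demonstrates correctness of the
computational chain, not instrument realism: there is no chromatographic
drift or co-elution, no isotope envelopes beyond three isotopologues, no
chimeric spectra, no in-source fragmentation, and decoys are random
rather than chemically plausible near-isobars. Real-data performance
will be bounded by those effects, which is precisely why the rule-based
filters (oxygen-retention evidence, KMD–RT linearity) exist.

## Known limitations

- sn-position and double-bond-position isomers are out of scope; species
  are sum compositions.
- Truncated/core-aldehyde oxidation products are excluded by the default
  constraint set (epoxy cap 0 mirrors the reference constraints).
- Negative-mode TG chemistry is not modelled.
- The three identification scores are package-defined stand-ins for
  unpublished vendor formulas; thresholds retain the published values
  but absolute score scales are not comparable to other software.
- The baseline rule used by manual chromatographic curation is
  unknowable; the endpoint-linear baseline is a documented, deterministic
  divergence.
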