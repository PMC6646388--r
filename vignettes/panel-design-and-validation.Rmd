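---
title: "Targeted MRM panel design and rule-based detection validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted MRM panel design and rule-based detection validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmpanel)
```

## Scope and model

`mrmpanel` covers the desk side of developing a targeted LC-MRM-MS assay
for bacterial biomarker proteins — here, *Dehalococcoides mccartyi*
housekeeping proteins (GroEL, EF-Tu, S-layer) and dechlorination markers
(FdhA, the RDases TceA and BvcA) — and the rule-based interpretation of the
resulting chromatograms. It deliberately does not model the mass
spectrometer beyond what the assay rules require: no isotope envelopes, no
b-ions or neutral losses, no 3+ precursors, and no vendor raw-file
parsing. Inputs and outputs are FASTA and CSV.

### Candidate generation

Proteins are digested in silico with classic trypsin specificity: cleavage
after K or R, suppressed before proline (the proline rule is on by default
and configurable, since different search engines disagree). Missed
cleavages default to 0 — targeted assays monitor fully tryptic peptides —
and can be raised to 2 when reconciling discovery-search tables.
Candidates must be 7–18 residues long and methionine-free: shorter
peptides are rarely unique, longer ones fragment poorly on a triple
quadrupole, and Met oxidation splits signal between mass states.

### Ion arithmetic

Monoisotopic masses come from the standard residue table shipped as
package data (`inst/extdata/monoisotopic_residues.csv`), water
18.010565 Da, proton 1.007276 Da. Carbamidomethylation of cysteine
(+57.02146 Da) is a fixed modification by default, matching the alkylation
step of standard sample preparation; it can be disabled. Transitions are
the 2+ precursor paired with singly charged y3 … y(n−1). We interpret the
"terminal" y-fragment as y(n−1): the full-length y(n) ion has the
precursor's composition and is not a useful transition, a standard SRM
convention. Collision energy is linear in precursor m/z per charge state;
the shipped coefficients (charge 2: 0.034 eV/Th slope, 3.314 eV intercept)
are the widely used Thermo triple-quadrupole defaults and are explicit
placeholders — any real deployment should substitute the instrument's own
calibration through the `ce` config block. Product ions outside the
quadrupole transmission range (default 10–3000 Th, the mass range of
TSQ-class instruments; configurable) are dropped with a logged reason.
The y/b complementarity identity (y_i plus the complementary N-terminal
fragment mass equals M + 2 protons) is verified in the test suite to
1e-9 Da as an internal consistency check.

### Specificity tiers

A candidate is screened against a registry of proteomes labeled `target`,
`related_ohrb` (related organohalide-respiring bacteria, e.g.
*Dehalogenimonas*) or `other`. Precedence is fixed: any hit in an `other`
proteome makes the peptide non-specific (removed); otherwise a hit in a
related organohalide respirer makes it semi-specific (kept with caveat,
because such peptides still indicate dechlorination capability);
otherwise it is specific. Two match semantics are provided because public
peptide-lookup and protein-homology tools differ: the default tests
membership in the background's tryptic peptidome (would the background
organism actually produce this peptide on digestion?); the alternative
matches the peptide as a raw substring of undigested protein sequences.
Both are exposed and the screen can be run under either; they disagree
exactly when a peptide occurs without flanking tryptic boundaries.

Peptidome similarity is likewise reported under two definitions, Jaccard
(default) and overlap coefficient, both in percent, because published
"similarity (%)" figures for peptidome comparisons rarely state which set
metric was used. The choice is a config value and is recorded in output
headers. I/L equivalence (the two residues are isobaric and
indistinguishable by MS) is off by default and can be enabled; it then
applies consistently to peptidome construction and matching.

### Transition ranking and panel assembly

Within a peptide, each transition's contribution is its integrated area
divided by the peptide's total; the top five by contribution are
retained, with ties broken toward lower y-index (deterministic output;
the choice of tie-break is ours, as discovery data rarely produce exact
ties). Retention is allowed to be ragged — peptides can keep fewer than
five transitions when fewer were observed. When strains share a peptide
but retained different transition sets, the strain with the higher total
AUC wins (logged), with an "intersection" mode as the conservative
alternative. Manual signal-quality triage of discovery data is
operationalized as two objective flags: multi-load linearity (Pearson r
of total AUC against load amount ≥ 0.9 and strictly increasing AUC across
loads, e.g. 500 ng / 2 µg / 8 µg) and a minimum-total-AUC floor. These
replace, and cannot fully reproduce, an expert's eye; they are the
auditable approximation.

### Detection rules

A peptide is detected in a sample when all of the following hold across
technical replicates:

* **A — co-elution**: maximum apex spread among its transitions ≤ 0.2 min
  (default; the tolerance is an assay-tuning parameter, not a published
  constant, and is exposed in config) in every replicate.
* **B — pattern**: arithmetic mean across replicates of the dot product
  between observed areas and the reference pattern strictly exceeds 0.80.
  The dotp is computed on raw areas by default; a square-root transform
  option exists because spectral-library tools differ on this point.
* **C — reproducibility**: every replicate shows signal on every expected
  transition — smoothed apex above the trace baseline (median) by 3
  baseline MADs — and passes co-elution.

Spike-in confirmation against an unlabeled synthetic standard requires an
area increase of more than 50% of the endogenous total (default fold,
configurable), dotp > 0.80 against the standard's pattern, and apex
retention times within 3.0 min inclusive. The 0.80 threshold is strict
(`>`) and the 3-min window inclusive (`≤`); the boundary tests pin both.

### Numerical choices

Integration is trapezoidal over the full trace window, reported in
intensity·seconds; apexes are picked on a centered 3-point moving average
(width configurable) so single-sample noise spikes do not set the apex.
Traces shorter than 3 points are rejected. A zero observed vector has
dotp defined as 0 with a warning rather than NaN. All report orderings
(peptides alphabetically, transitions by ascending y-index) are fixed so
repeated runs are byte-identical; every output CSV header carries the
config hash and seed.

## What the simulator emulates — and what it does not

The generator produces (i) proteome registries built from
uniform-residue-frequency random proteins with candidate peptides planted
between tryptic boundaries, giving each specificity tier known-truth
members; and (ii) MRM peak groups as Gaussian elution peaks (amplitude
proportional to the reference ratio, shared apex plus per-transition
jitter of σ = 0.02 min, constant baseline of 20 counts, additive Gaussian
noise at 3% of peak amplitude, 2-s sampling over a ±0.5-min window).
Decoy modes corrupt one property at a time: `ratio_permute` reassigns
intensities by reversed rank (patterns are drawn skewed enough that the
permuted dotp is below 0.6 by construction, hence well under the 0.80
threshold); `rt_shift` moves the whole group; `dropout` silences
transitions; `absent` leaves baseline noise only.

Real data differ in ways the simulator does not attempt: peak tailing and
co-eluting interferences, ionization suppression by matrix, correlated
(non-white) noise, retention drift between runs, and residue frequencies
of real proteomes. Passing the simulation-based tests therefore
demonstrates that the *rules* are implemented correctly and discriminate
under controlled corruption — not that the default thresholds are optimal
for any particular instrument or groundwater matrix. Thresholds should be
tuned on real spike-in series.

Defaults were chosen once as typical of nano-LC triple-quadrupole
acquisitions (90-min gradients, 20-ms dwell): peak σ 0.05 min, base peak
amplitudes 5×10⁴–5×10⁵ counts, three technical replicates, five
transitions per reference pattern.

## Problem sizes

The shipped tests and the acceptance script use: 1000 random proteins
(50–500 residues) for the digestion-oracle comparison; 10,000 random
vector pairs for dotp scale invariance; 200 faithful plus 200
ratio-permuted peak groups (three replicates each) for the
detection/rejection rates; a 37-peptide panel with 13 present peptides
for the mixed-sample scenario; and seeded registries of 7 proteomes × 15–30
proteins for specificity-truth recovery. These sizes give stable rates
while keeping a full run to a few minutes on one core.

## Known limitations

* Exact string matching only; no e-value homology search, and no live
  queries of UniProt/NCBI — specificity is relative to the proteomes the
  user supplies. A peptide called "specific" against a small registry may
  not be specific against all sequenced bacteria.
* No absolute quantification: isotopically labeled internal standards and
  calibration curves are out of scope.
* No retention-time prediction or iRT alignment; co-elution is judged
  within a run only.
* The collision-energy coefficients are placeholders until replaced with
  instrument-specific values.
* The published peptidome-similarity comparisons against reference
  proteome databases require downloading those proteomes; the package
  computes the matrices from any user-supplied FASTA set but ships no
  reference data.
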