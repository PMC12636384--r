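---
title: "CSGSA methods: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CSGSA methods: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csgsa)
```

## The problem this package addresses

Serum N-glycopeptides respond early and broadly to gastrointestinal
malignancy. Comprehensive Serum Glycopeptide Spectrum Analysis (CSGSA)
profiles on the order of a thousand enriched glycopeptides (EGPs) by
LC-MS, combines them with a conventional nine-analyte tumor-marker panel
(CEA, CA19-9, CYFRA, NCC-ST-439, CA125, PSA, CA15-3, AFP, SCCA), and
feeds the combined feature set to a machine-learning classifier whose
output probability is reported on a log scale (the CSGSA score).
Screening utility is then judged not on the case-control cohort itself
but after projecting sensitivity and specificity onto a realistic
100,000-person population with registry prevalences for colorectal (CRC),
gastric (GC), and esophageal (EC) cancer.

The package implements the full desk-scale pipeline — simulation, peak
processing, glycopeptide identification, biomarker screening, classifier
evaluation, and screening projection — with every stage testable against
planted ground truth.

## The synthetic cohort: a stated world

No public raw data accompany this problem, so the simulator is the
package's substrate. Its defaults are fixed commitments, not tuning
knobs:

* **Cohort structure.** 590 healthy / 296 CRC / 180 GC / 42 EC subjects,
  with stage mixes matching the observed demographics (CRC 76/96/79/38
  over stages I-IV among the 289 staged cases; GC 73/47/39/21; EC
  5/18/15/4).
* **Tumor markers.** Log-normal in native units with a common log10 SD of
  0.35 — a typical spread for serum analytes whose populations span about
  a decade. Group shifts are calibrated through the closed form
  `AUC = pnorm(shift / (sd * sqrt(2)))` so that single-marker
  discrimination hits the published operating points: CEA 0.805 and CYFRA
  0.834 in CRC, CYFRA 0.836 in GC, SCCA 0.794 in EC, CA19-9 0.613 in
  CRC; AFP, CA125, PSA, CA15-3 and NCC-ST-439 carry no planted signal.
* **EGP layer.** 1688 species by default, placed uniformly in RT 1-14 min
  and m/z 700-2500 Da with base areas log10-normal (mean 4.5, SD 0.5).
  A configurable fraction (default 10%) carries group effects of
  magnitude 1 log2 unit; the gastric group draws reductions with
  probability 0.8 (a broad down-shift), the other groups 0.5. Two
  "signature" species — stand-ins for the fully sialylated biantennary
  glycoforms at alpha-1-antitrypsin Asn271 and alpha-2-macroglobulin
  Asn70 — carry a consistent elevation in every cancer group calibrated
  to a per-feature AUC of 0.79.
* **Stage scaling.** Effects multiply by (0.5, 1.0, 1.1, 1.2) over stages
  I-IV. No quantitative stage model is available; this ordered default
  merely makes stagewise evaluation meaningful.
* **Peak emission.** Biological noise is multiplicative (log2 SD 0.5).
  Coordinates are jittered with SDs 0.05 min / 0.01 Da — strictly below
  half the alignment tolerances, so planted peaks are recoverable; the
  configuration validator enforces this. Isotope (+1.00335/z, z drawn
  from 1-3), sodium/potassium adduct (+21.98194 / +37.95588), and
  fragment (random lower m/z) satellites attach to species with
  probabilities 0.25/0.10/0.10 and ride the parent's per-injection area
  at fixed ratios (0.4/0.25/0.35). Peaks below the detection limit
  (default area 50) are dropped; downstream stages impute zeros. Random
  noise peaks (150 per injection around area 100) model the instrument
  floor and are what the CV filter later removes by the thousands.
* **QC replicates.** Six intra-day and six inter-day injections drawn
  around the species base areas at 8% and 10% CV. The replicate-based CV
  filters require an operational definition the source material does not
  give; QC injections are the natural choice and make both the 50%
  alignment-stage filter and the 15% screening criterion measurable.

What the simulator does **not** emulate: chromatographic drift and RT
warping, profile-mode spectra, correlated glycoform families,
batch effects, age/sex structure, or assay-specific marker kinetics. A
green test therefore establishes that the pipeline's logic is correct on
data obeying its stated assumptions — not that the published cohort
performance is reproduced. The cohort-level headline AUCs are explicitly
out of reach without the original serum samples.

## Peak processing

**Alignment** (tolerances 0.06 Da, 0.3 min) uses greedy seeded
clustering: peaks are processed by descending area; each unclaimed peak
opens a feature that claims the nearest unclaimed in-tolerance peak per
sample, with distance scaled by the tolerances and ties broken by
smaller |dm/z| then |dRT|. The procedure is deterministic and invariant
to sample order (peaks are canonically ordered before seeding).
Consensus coordinates are area-weighted means.

**Three-step EGP selection.** (i) CV > 50% on QC replicates (undefined
CV fails too), (ii) S/N < 5, (iii) isotope/adduct/fragment ions. All
removal conditions are strict inequalities exactly as stated, so CV =
50.0% and S/N = 5.0 are retained. S/N is defined here (no published
definition exists) as the median of a feature's non-zero areas over the
median area of noise peaks within ±0.5 min, falling back to the global
noise median; when no noise model is supplied, the floor is estimated
from sparse features (< 5% sample presence). The fragment rule requires
both co-elution (dRT <= 0.1 min) and cross-sample Pearson correlation
>= 0.95 with a heavier, more intense feature; 0.95 is our choice, set
high enough that biological co-regulation rarely triggers it (in a
noise-free simulation it can, which the tests document as a premise).

**Normalization** divides each sample's areas by the feature's mean QC
area, yielding relative levels; features absent from QC are excluded
with a warning. On satellite-free, noise-free simulations the whole
stage is information-preserving to < 1e-9 relative error, which the
test suite asserts.

## Glycopeptide identification

Proteins are digested in silico (cleavage after K/R except before P,
<= 2 missed cleavages, carbamidomethyl-Cys fixed), keeping peptides with
an N-X-S/T sequon (X != P). Candidates enumerate a glycan composition
grid — by default Hex 3-9, HexNAc 2-6, NeuAc 0-4, Fuc 0-2, which spans
bi- to tetra-antennary sialylated structures including the fully
sialylated biantennary Hex5HexNAc4NeuAc2 — with neutral mass equal to
the peptide mass plus residue masses (Hex 162.05282, HexNAc 203.07937,
NeuAc 291.09542, Fuc 146.05791). Observed features measured in negative
mode as [M - zH]^z- (charges 1-4, proton 1.007276 Da) match candidates
within an **inclusive** 0.03 Da window — the natural reading of
"within" — and all in-window candidates are reported ranked by |delta|:
without spectral libraries or retention-time standards, identity
confirmation is advisory, so no unique assignment is forced.

## Biomarker screening

Per-feature statistics use the equal-variance (Student's) two-sided
t-test — deliberately not Welch — with zeros included, and the
mean-fold ratio MFR = mean(cancer)/mean(healthy). Volcano classes use
p < 1e-10 with MFR outside [2^-0.5, 2^0.5]. The candidate screen
requires p < 1e-10, fold change exceeding 1.5 **in either direction**
(both elevated and reduced EGPs are real biology; one-sided screening
would discard the reduced gastric signal), and intra- and inter-day CVs
<= 15%. No multiple-testing correction is applied: the 1e-10 threshold
is itself the stringency device, and the tests verify it yields at most
~1 false positive per 1000 null features at the simulator's noise
levels. Screening defaults to transferrin-normalized levels (a stable
serum anchor removes sample-preparation scale); QC-normalized input is
equally accepted.

## Classifier tiers and evaluation

* **Model 1**: the nine markers as log10(value + eps), eps the smallest
  positive observed value per marker (log-scale entry matches how these
  analytes distribute).
* **Model 2**: adds the two signature glycopeptide levels.
* **Model 3**: adds the EGP block reduced to 100 principal components.

PCA is fitted on the training split only and test rows are projected
with training means, scales and loadings. Fitting the reduction on all
samples would leak test information into Model 3; the honest variant is
the default and the only one the acceptance tests use.

Evaluation draws 10 independent stratified random 70/30 splits
(stratification protects the 42-sample EC class; independent splits are
the closest reading of "randomly split, iterated"), trains per split,
and pools held-out predictions for a single ROC. The AUC uses
trapezoidal integration with tied scores stepping simultaneously, and
equals the Mann-Whitney statistic exactly — an identity the tests check
to 1e-12.

Because no neural-network or boosting package is available in the
target environment, both learners are implemented here behind one
interface: `fit_mlp()` (ReLU hidden layers, softmax output, full-batch
Adam, early stopping on a stratified validation slice) and `fit_gbt()`
(Newton boosting of depth-limited regression trees on the logistic
loss, xgboost-style split gain). The default hidden sizes are (32, 16)
rather than a larger (64, 32): at desk-scale cohorts of a few hundred
samples and ~110 features the smaller net trains in milliseconds and is
less prone to overfitting; both are configurable via `learner_args`.

## Screening evaluation

The CSGSA score is `min(10, -log10(1 - p))`; p = 1 maps to the cap.
Being strictly monotone below the cap it leaves AUC unchanged. The
decision rule is score >= cutoff (default 5); the boundary side is not
externally specified, and inclusive-positive is documented here.
An optional selector picks the smallest cutoff achieving a target
training specificity ("minimize false positives").

Prevalence projection applies observed sensitivity/specificity to a
100,000-person population: expected diseased positives and healthy
positives are rounded **half away from zero** and complements obtained
by subtraction — the only rounding rule that reproduces all nine
adjusted counts of the bundled reference blocks exactly, and it
conserves the population total by construction. The bundled CRC block
carries prevalence 247/100,000, the value its own projection is
consistent with; the registry incidence figure of 124/100,000 is also a
valid input and both are accepted. Two-stage typing thresholds the
score, then assigns stage-1 positives the argmax type probability;
per-type accuracy defaults to the recall-style denominator (correct
identifications over true members entering stage 2), with a
precision-style option, since the verbal definition is ambiguous
between the two.

## Numerical and degenerate-input conventions

* Undefined CV (fewer than two replicates, or zero mean) fails filters;
  zero healthy means exclude a feature from MFR with a log entry; zero
  transferrin flags the sample out of screening.
* Zero-variance columns pass through standardization with unit scale.
* Splits that would leave one class absent from training are redrawn
  (logged); single-class ROC pools raise an error rather than returning
  a conventional value.
* All generators derive their streams deterministically from the
  config seed; identical configs give byte-identical outputs.

## Known limitations

Satellite detection assumes satellites are less intense than their
parents, as planted; real isotope envelopes of large glycopeptides can
violate this. The fragment-correlation rule cannot distinguish a true
in-source fragment from a perfectly co-regulated co-eluting species.
The NN is a small dense net without architecture search, and no
hyperparameter optimization is performed anywhere — the component-count
sweep for the PCA reduction is exposed as a utility choice
(`n_components`), not re-derived. None of the cohort-level published
AUCs are claims of this package; the acceptance suite checks ordering
and recovery properties on the stated synthetic world instead.
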