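---
title: "Models and methods in heliomod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in heliomod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heliomod)
```

heliomod supports studies of heliorhodopsins (HeRs) — inverted-topology
microbial rhodopsins whose genes often sit in operons next to genes they may
regulate. The package covers four layers of such a study: (i) gene
neighborhoods and co-transcription around HeR anchor genes in annotated
genomes, (ii) reference-anchored amino-acid frequency profiles across a
labeled HeR alignment, (iii) binding thermodynamics from isothermal titration
calorimetry (ITC), and (iv) the enzyme-kinetic, dose-response, photocycle and
assay-calibration calculations that accompany transporter activity
measurements. Seeded generators produce every input with planted truth, so
each stage can be validated offline.

## Gene neighborhoods and co-transcription

Anchors are HeR-like genes identified from a homology hit table (BLAST
tabular) or, for desk-scale inputs, from a built-in Smith–Waterman local
alignment (BLOSUM62, affine gap open 10 / extend 0.5) against a reference
protein, with a Karlin–Altschul e-value estimate. Defaults accept hits with
identity ≥ 20% and e-value ≤ 1e-5 — conventional permissive homology-search
thresholds; both are arguments.

Co-transcription is approximated by an intergenic-distance and strand
heuristic rather than promoter prediction: adjacent same-operon gene pairs in
prokaryotes concentrate at intergenic distances between −20 and 30 bp, so a
neighbor chain is called co-transcribed with the anchor when every
consecutive link outward shares the anchor's strand and falls inside that
window, breaking at the first failing link with no skipping. Gaps use the
GFF3-native 1-based inclusive convention, `start(downstream) −
end(upstream) − 1`, so 0 means abutting and negative means overlapping.
Users with external promoter calls can pass them per gene; they override the
heuristic. This is deliberately a documented stand-in: promoter-prediction
services are not reimplemented, and no claim is made that the heuristic
reproduces any particular promoter caller.

Classification into the ten neighbor-gene groups (glutamine synthetase,
NAD⁺ synthetase, photolyase, MerR-family regulator, TerC, ABC transporter,
SDR oxidoreductase, α/β hydrolase, DUF2177, DUF2238) scans co-transcribed
neighbors nearest-first against an editable keyword map; the map's list
order is the fixed priority for products matching several groups. Anchors
with no co-transcribed neighbor are `non_co_transcription`; unmatched
products are `other`. Cohort summaries use the total anchor count as the
denominator for the co-transcription fraction and for per-taxon fractions,
so per-taxon values sum to the overall fraction; taxon labels are always
taken from input, never inferred.

## Residue-frequency conservation

Alignment columns are mapped to the ungapped residue numbering of a
designated reference row (columns where the reference is gapped are dropped
everywhere). For a sequence group, the frequency of amino acid *a* at
reference position *i* is the count over the **full group size** — the
"per-HeR" convention — with gapped sequences accruing to a per-position NA
fraction, so frequencies plus NA mass sum to one. An option switches to
ungapped-only denominators.

The differential statistic is group frequency minus background frequency
(background: the non-co-transcription group), flagged when it strictly
exceeds θ = 0.19 in either direction — strictly, because the rule is
"more than 0.19"; equality is not flagged. The threshold is per amino acid
by default, with class-level aggregation available. Class membership
(hydroxylic {S,T,Y}, aliphatic {A,V,L,I,G}, aromatic {F,W,Y,H}, acidic
{D,E}, basic {K,R,H}) follows conventional chemistry groupings; Y and H
appear in two display classes, and `aggregate_classes()` enforces a disjoint
effective partition by list-order priority (or errors, by default, if asked
to aggregate an overlapping map).

Charge conservation counts K+R as positive (H excluded by default, opt-in)
and D+E as negative, and ranks positions within intracellular-loop (ICL)
regions. Only marker positions ship by default (ICL1: 102/104/105, ICL2:
166/167/170, ICL3: 225/229/233/235/236, in reference numbering); full loop
boundaries are user-supplied because only the markers are anchored in the
reference structure. "Highly conserved" uses a 0.5 frequency cutoff,
configurable.

## ITC binding models

Titrations are titrant-into-cell. Concentrations after the *i*-th injection
follow the displaced-volume convention of small-cell calorimeters (constant
cell volume $V_0$; cumulative injected volume $\Delta V$):
$M_t = M_{t,0}\frac{1-\Delta V/2V_0}{1+\Delta V/2V_0}$,
$X_t = X_{syr}\frac{\Delta V/V_0}{1+\Delta V/2V_0}$.

**One-site (Wiseman) model.** The bound fraction $\theta$ solves the
quadratic mass balance; cumulative heat is
$Q = n\,M_t\,\Delta H\,V_0\,\theta$, and the per-injection heat is
$\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i+Q_{i-1}}{2} +
q_\mathrm{off}$. A bisection-based solver of the same mass balance is kept
as an independent route and must agree with the closed form to 1e−9
relative — a standing regression test on the algebra.

**Sequential two-site model.** Stepwise constants $K_1, K_2$ give species
fractions $F_1 = K_1X/D$ and $F_2 = K_1K_2X^2/D$ with
$D = 1 + K_1X + K_1K_2X^2$, free titrant $X$ found by root-finding
$X_t = X + M_t(F_1 + 2F_2)$ on $[0, X_t]$, and
$Q = M_tV_0(F_1\Delta H_1 + F_2(\Delta H_1{+}\Delta H_2))$ with the same
differencing. As $K_2 \to 0$ the curve reduces to the one-site model with
$n = 1$ — another standing test. Fits report positive cooperativity when
$K_{d,2} < K_{d,1}$.

Fitting is Levenberg–Marquardt on the per-injection heats. Association
constants (and one-site stoichiometry) are fitted on the log scale to
enforce positivity; bound-hitting solutions are flagged. Following the usual
calorimetry-software convention the dilution offset is *fixed* (default 0)
unless `fit_offset = TRUE`; a free offset in the weak-binding, low-c regime
studied here trades off against $K_d$ and inflates its variance.
Initialization takes ΔH from the first-injection heat and $K_a$ from a
midpoint heuristic; the sequential model runs 5 seeded starts and keeps the
lowest residual norm. Because weak binding rarely saturates, fits report the
maximum molar ratio reached as a saturation-coverage diagnostic instead of
refusing.

Derived quantities use $\Delta G = RT\ln K_d$ (1 M standard state,
R = 1.9872×10⁻³ kcal mol⁻¹ K⁻¹, default T = 298.15 K) and
$-T\Delta S = \Delta G - \Delta H$; units are µM and kcal/mol throughout
reporting. The packaged reference table of published binding parameters is
checked by `thermo_closure_report()`: ΔH + (−TΔS) = ΔG exactly at printed
precision, and RT·ln K_d within ±0.1 kcal/mol *plus half of the last printed
digit* — the half-ulp term because the table stores independently rounded
replicate means, so the identity can only be expected up to printed
rounding.

## Kinetics and assay calculations

The Michaelis–Menten fit uses the Table-unit convention throughout: Vmax in
µM/min, Km in mM, kcat = (Vmax/[E])/60 in s⁻¹, kcat/Km in M⁻¹s⁻¹. When
per-replicate parameter sets exist, `specificity_report()` returns both the
mean-of-ratios and ratio-of-means specificity constants — kinetics tables
built from replicate fits usually print the former, and the two genuinely
differ, so both are labeled rather than silently picking one.

Dose–response is the four-parameter logistic
$y = A_1 + (A_2-A_1)/(1+10^{(\log x_0 - x)p})$ with IC₅₀ = $10^{\log x_0}$;
exponential decay is $y = y_0 + A_1e^{-x/t_1}$ with $t_{1/2} = t_1\ln 2$;
pH titrations fit the Henderson–Hasselbalch sigmoid (half-maximal signal at
pH = pKa). Phosphate release is calibrated by a linear A₃₅₅-vs-[Pi]
standard curve with an extrapolation warning outside the calibrated range.
MIC₈₀ is the lowest concentration with growth ≤ 20% of the no-drug control,
reported as "> max" when unreached. Fluorescence traces are normalized to
the time-0 recording, with delta values relative to that normalization.
All curve fits run Levenberg–Marquardt on an explicit model function
(rather than through a model-frame interface, which degenerates on
zero-residual data) with positivity bounds where physical.

## Synthetic-data generators

The generators define the conditions under which the pipeline is validated.

* **Genome cohorts** plant one anchor and one downstream neighbor per
  contig. Co-transcribed anchors (an exact planted count, default rate
  38.6% at the 448-anchor cohort scale) get a same-strand neighbor with a
  gap drawn uniformly *inside* −20..30 bp and a product drawn from the
  ten-group mixture (uniform by default); the rest get gaps strictly inside
  100..500 bp and a "hypothetical protein" product. Drawing gaps strictly
  inside/outside the window makes classification truth unambiguous, which
  is what lets round-trip tests demand 100% agreement. Proteins are random
  sequences — no biophysical realism is attempted, and none is needed for
  coordinate/strand logic.
* **Alignments** draw per-column background compositions from a symmetric
  Dirichlet (concentration 0.5, moderately peaked columns, a rough stand-in
  for real column conservation); planted enrichment raises the target
  group's probability of a chosen residue by exactly Δ, so the expected
  differential equals Δ and recovery can be tested against binomial error.
* **ITC titrations** default to a 200 µL cell with 20 × 2 µL injections,
  0.5 mM cell protein and 8 mM syringe titrant — reaching molar ratio ≈ 3.5
  at c ≈ 5 for the 91.6 µM regime, i.e. deliberately *not* saturating,
  matching the weak-binding character of the measured interaction. Noise is
  i.i.d. Gaussian; a `noise_sd` in (0,1) means that fraction of the largest
  model heat.
* **Kinetic datasets** use 8 substrate levels (1–160 mM ATP), 9 log-spaced
  dose points, 50 decay time points over ~5 time constants, and 10 pH
  points spanning ±2.25 units around the transition.

What passing tests do and do not show: the generators share their
functional form with the fitted models, so recovery tests validate the
estimation machinery and bookkeeping, not model adequacy for real
instrument data (no baseline drift, no heteroscedastic noise, no
phylogenetic correlation between sequences, no first-injection artifact).

## Numerical choices and test scale

Tolerances: closed-form vs bisection agreement 1e−9 relative; noiseless
recovery 1e−4 relative (ITC) / 1e−6 (kinetics); Monte-Carlo studies use 50
seeds at 5% noise with median-relative-error bounds (15% on Kd, 10% on
Vmax and t½). The cohort acceptance checks run at the study scale (448
anchors) and the alignment checks at 448 sequences per group over 240
reference positions; the whole suite runs in well under a minute on one
CPU. The Kd Monte-Carlo bound is the tightest of these: at the
non-saturating design the one-site Kd estimator has a heavy upper tail and
its median error sits near 14–16% depending on the seed block — a genuine
property of weak-binding ITC, worth remembering when interpreting single
fitted Kd values from such experiments.

Degenerate inputs fail loudly: flat heats ("uninformative titration"),
flat rates/signals, fewer than 8 informative injections or 4 substrate
levels, zero time-0 fluorescence, growth tables without a no-drug control,
non-positive calibration slopes. Zero-gap ties at the co-transcription
window edges are inclusive; the θ flagging is strict.

## Design notes

* The curve-fitting layer follows the classic R modelling idiom: fitting
  functions return classed objects (`her_fit` subclasses) with `print`,
  `summary`, `coef`, `predict`, `residuals`, `simulate` and `plot` methods;
  the genomics and conservation layers are plain pipeline functions since
  nothing about them is a fitted model.
* `run_pipeline()` orchestrates seeded synthetic runs end to end and writes
  only TSV/JSON artifacts stamped with a config hash, the seed and the
  package version; identical configs produce byte-identical outputs.
* The packaged reference tables (`read_thermo_table()`,
  `read_kinetics_table()`) carry published mean parameters used as fixture
  inputs for closure and fold-change checks; rows whose parameters were not
  calculable in the source carry NA and are skipped, not failed.
* Known limitations: the co-transcription heuristic is a stand-in for
  promoter evidence; ICL boundaries beyond the marker positions must be
  supplied by the user; the ITC layer fits integrated heats only (no raw
  power traces, no global multi-experiment fits); significance testing of
  group differences is out of scope — the frequency statistic is a fixed
  threshold, not a test.
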