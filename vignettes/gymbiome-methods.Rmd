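---
title: "Methods: longitudinal microbiome analysis of resistance-training cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal microbiome analysis of resistance-training cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gymbiome implements a complete analysis chain for longitudinal
resistance-training interventions with stool 16S profiling: strength metrics
from machine-recorded session logs, responder stratification, rarefaction
based diversity, within-subject Bray-Curtis trajectories, a paired
bias-corrected differential-abundance test over timepoint contrasts, a
permutation-subset robustness procedure, diet-stability ordination, and a
responder-prediction benchmark. Because the human data such studies produce
are typically under controlled access, the package ships a seeded synthetic
study generator that emulates the design (205 enrolled, 150 analysed, three
stool timepoints W0/W4/W8, seven training machines, two programs) so that
every stage is exercised end to end by code anyone can run.

## Strength metrics

The headline strength metric is the **average strength gain**: the mean over
the seven machines of the log2 fold change in maximum strength between two
fitness tests,

$$\bar{g} = \frac{1}{M}\sum_{m=1}^{M} \log_2 \frac{S_{m,t_2}}{S_{m,t_1}},$$

reported as a percent via $(2^{\bar g}-1)\times 100$. The percent is derived
from the mean log fold change, not from the mean of per-machine percents;
this makes gains exactly additive over composed intervals
(W0→W4 plus W4→W8 equals W0→W8 in log2 units) and symmetric in the machine
set. Leg press maximum (kg) and a strength-based biological age complete the
three responder metrics.

**BioAge surrogate.** Commercial training equipment reports a proprietary
age-equivalent of muscular fitness. gymbiome uses a deliberately minimal
monotone surrogate: a sex-specific reference curve of relative strength
(strength / body weight)

$$R(a) = R_{\text{peak}}\, e^{-\lambda (a - a_{\text{peak}})}, \qquad a \ge a_{\text{peak}},$$

with defaults $a_{\text{peak}} = 25$ y, $\lambda = 0.01$/y,
$R_{\text{peak}} = 1.2$ (male) / $0.85$ (female). An observed relative
strength is mapped to the age at which the curve takes that value (the
inversion is analytic and extrapolated below the peak age for
above-reference strength), per-machine ages are averaged, and the average is
clamped to a floor of 21 years — matching the behaviour of the commercial
metric it stands in for. Clamping after averaging (rather than per machine)
is a package decision; the alternative is defensible but changes values only
for athletes near the floor. Activity Points (an EPOC-based load metric) are
intentionally not modelled; the surrogate parameters are exposed in
`bioage_params()` and should not be mistaken for the proprietary model.

## Responder stratification

For each metric, high responders (HR) are participants strictly above the
empirical 80% quantile and low responders (LR) strictly below the 20%
quantile (type-7 quantiles; ties at a cut go to the medium class). For
BioAge the sign is inverted: the largest *decrease* marks a high responder.
Stratification is invariant under strictly monotone transforms of the
metric. The **non-HR pool** — participants not HR under *any* of the three
metrics — is the sampling pool for the permutation null below.

## Diversity

Counts are rarefied without replacement to a common depth before diversity
computation; the default depth is 90% of the minimum retained sample depth
(the underlying study states rarefaction but not a depth), and shallower
samples are dropped and logged. Shannon entropy is reported in natural-log
units (fixed for reproducibility and stated in output headers), together
with observed ASVs and Pielou evenness. Between-sample dissimilarity is
Bray-Curtis, $1 - 2\sum_i \min(x_i,y_i) / (\sum_i x_i + \sum_i y_i)$,
computed on rarefied counts (the QIIME2 convention). Within-subject
trajectories collect the three pairwise distances (W0-W4, W4-W8, W0-W8) per
participant. UniFrac is out of scope — no phylogenetic tree enters the
pipeline.

## Paired differential abundance with bias correction

The within-participant design ("ASV ~ timepoint with a participant random
effect") is realised as a paired-difference analysis, which for complete
pairs is the exact within-participant contrast:

1. **Paired log2 fold changes.** For each participant with a baseline and a
   follow-up sample, and each ASV passing a prevalence filter (nonzero in at
   least 25% of the analysed samples), compute
   $\log_2\frac{c_{t}+pc}{d_t} - \log_2\frac{c_{0}+pc}{d_0}$ with
   pseudocount $pc = 0.5$ (half-count convention) and $d$ the raw sample
   depth.
2. **Bias correction.** Subtract from each participant-contrast vector its
   median across ASVs. A shift shared by all ASVs of a sample pair is a
   compositional / sampling-fraction artifact, not biology; median centring
   removes it while leaving isolated true effects almost untouched (with
   ~10% of ASVs planted, the induced attenuation is below the test's
   resolution). This is a transparent stand-in for model-based
   sampling-fraction estimation; the full estimator (EM over structural
   zeros, sensitivity scores) is deliberately out of scope.
3. **Testing.** Per ASV and contrast (W4 vs W0, W8 vs W0), a one-sample
   t-test of the centred fold changes against zero; Holm adjustment across
   the two contrasts within each ASV (the many-to-one, Dunnett-type
   family); an ASV is *significant* when the Holm-adjusted p ≤ 0.05 **and**
   |mean log2FC| ≥ 1 (at least two-fold). Zero-variance ASVs get p = 1 with
   a warning rather than an error, so degenerate subsets do not abort
   permutation runs.

The joint p-and-fold-change rule is what controls false discoveries in
practice: under a global null with n = 30 participants the fraction of ASVs
passing both gates is far below 1% (the t-test alone would pass 5%).

## Permutation-subset robustness

Discovery counts in a selected subgroup (HR) are calibrated against random
subsets: the same DAA is run on 100 random draws (without replacement,
size-matched to HR) from the non-HR pool. The empirical p-value is the plain
fraction of subsets with at least as many significant results as observed —
deliberately *without* the add-one correction, so that 99 of 100 subsets
falling below the observed count reports exactly p = 0.01. A count of zero
is reported as "< 1/N" rather than 0. Per ASV, the *chance frequency* is the
fraction of subsets in which it was significant (either direction, any
contrast); Benjamini-Hochberg q-values are computed over the chance
frequencies of the ASVs significant in HR (the rows of the discovery
heatmap), with zero frequencies floored at 1/N before adjustment. Subset
size-matching and direction-agnostic chance counting are package decisions
where the emulated analysis is silent. Elsewhere in the package (the
rank-trajectory interaction test, the prediction benchmark) permutation
p-values use the add-one convention, which never reports exactly zero; the
k/N convention here is forced by the 99-of-100 ⇒ 0.01 behaviour.

## Nonparametric toolkit

Omnibus tests delegate to the standard base-R implementations
(`kruskal.test`, `wilcox.test` with continuity correction, `cor.test`,
`ks.test`, `chisq.test`, `p.adjust`). The Friedman statistic is computed
with the mid-rank tie correction,
$(k-1)\sum_j (R_j - n(k+1)/2)^2 / (A_1 - C_1)$, because survey-scale data
are heavily tied and the classical formula over-rejects otherwise; it
reduces to the textbook statistic on tie-free data. Conover's all-pairs rank
t-tests follow a significant Friedman test; Dunn's z tests follow
Kruskal-Wallis; both are BH-adjusted across pairs (the emulated analysis
does not state the post hoc adjustment; BH is the package's choice) and
summarised as a compact letter display at α = 0.05. The split-plot
group-by-time analysis is a permutation surrogate: observations are globally
mid-ranked, participant rank trajectories are centred by their own means,
the statistic is the sum over timepoints of squared group differences in
mean centred ranks, and group labels are permuted across participants. The
exact ANOVA-type statistic with its box approximation is out of scope; the
surrogate is calibrated (uniform p under the null) and powered against
divergent group trajectories.

## Diet stability

The 12 diet summary variables (8 food frequencies on a 0–7 occasions/week
scale — an encoding assumption, the source scale being unspecified — and 4
drink volumes in ml) are centred by their overall mean and scaled by the
root mean square of the centred values; Euclidean distances on this scale
are invariant to per-variable affine unit changes. Sammon's nonlinear
mapping embeds the records in two dimensions by minimising
$E = \frac{1}{\sum \delta_{ij}}\sum \frac{(\delta_{ij}-d_{ij})^2}{\delta_{ij}}$
(pseudo-Newton iteration with step halving, via `MASS::sammon`),
initialised from classical scaling so results are deterministic. Exact
duplicate records — common in ordinal survey data, and fatal to the
objective's division by $\delta$ — receive a deterministic 1e-9 jitter.
Convergence is declared when a short continuation run improves stress by
less than the tolerance (default 1e-7, maximum 500 iterations). A stress
below 0.2 is conventionally a fair representation. Within-participant diet
distances per timepoint pair are compared across LR/MR/HR with
Kruskal-Wallis; an all-equal degenerate case (zero generator noise) is
reported non-significant with a warning.

## Responder prediction benchmark

HR vs LR separability from baseline-only features is scored by a Random
Forest (500 trees by default) under stratified 5-fold cross-validation,
with the ROC-AUC computed from pooled out-of-fold class probabilities via
the rank statistic. Significance comes from label permutations: the full
cross-validation is repeated on permuted labels and
$p = (1 + \#\{\text{perm AUC} \ge \text{obs}\})/(1 + n_{\text{perm}})$,
1000 permutations in the full benchmark. Cross-validated (rather than
training-set) AUC is a package convention, stated as an assumption. Gini
importances are averaged over folds and normalised to sum to one. A guard
refuses features whose names indicate post-training information (W4/W8,
gain columns).

## The synthetic study generator

The generator defines the study conditions; it is not a tuning dial.

* **Cohort**: 205 enrolled; 43 dropouts, 6 quality exclusions, 6 validation
  exclusions, leaving 150 (the four groups partition enrollment exactly).
  Ages are truncated-normal 41.7 ± 11.6 on [24, 61]; BMI 24.5 ± 3.5
  (bounds 16.9–34.2); 42.6% male; 1:1 program assignment.
* **Training**: four 2-week phases per program with the published
  repetition and %-of-max parameters (regular: 20 reps at 45%, negative
  15 at 38/58%; muscle-building: negative, adaptive 10 at 68%, isokinetic
  2 × 8 at 73/105%, adaptive), 2–3 sessions/week, 2 sets × 7 machines per
  session. Per-participant true percent gains are drawn with mean 24 and sd
  16 (truncated at −50%); baseline leg press is 154 ± 54 kg, coupled to
  gain by a Gaussian copula with correlation −0.4 (weaker participants gain
  more — the diminishing-returns pattern). Within a participant all
  machines share the gain exactly; machine heterogeneity enters only
  baseline levels. Strength grows log-linearly through a week-4 waypoint at
  70% of the log gain, matching the larger first-half improvement.
  Compliance is a per-repetition completion probability of 0.97.
* **Microbiome**: 300 ASVs (a desk-scale table; the real feature space is
  ~30× larger), per-ASV baseline log abundances i.i.d. normal (sd 1.5),
  participant random intercepts giving a within-subject correlation of 0.7,
  per-sample noise sd 0.45 (natural log), softmax composition, multinomial
  reads at negative-binomial depths with mean 69,000 and size 100 (~10%
  CV, as for library-normalised pooling). Neither the within-subject
  correlation nor the noise sd is estimable from the published material;
  they are free parameters fixed so that the planted-coupling regime below
  behaves as designed, and are documented here rather than fit to data.
  Sixteen planted ASVs shift up and eleven down — at W4 by 1 log2 unit and
  at W8 by 2, scaled per participant by
  coupling_strength × gain percentile (coupling 1 by default) — so
  community change grows with strength response, high responders carry
  ≥2-fold average effects, and random non-HR subsets sit mostly below the
  fold-change gate. Planted ASVs take baseline abundances at fixed
  quantiles (30–95%) of the abundance distribution rather than random
  draws: the differential taxa being emulated include abundant SCFA
  producers, and a random draw occasionally makes the entire planted set
  rare, which would silently remove the community-level signal the design
  calls for. Dropouts contribute W0 samples only. A mock SILVA-style
  taxonomy (synthetic lineages drawn from a small pool of plausible gut
  genera) and a ground-truth sidecar (planted ids, per-participant gain
  percentiles) are always written; the sidecar never feeds analysis inputs.
* **Metabolites**: 34 named compounds (SCFAs, amino acids, bile-acid
  derivates, ...), log-normal with participant level and *no* time effect —
  a null panel by construction, mirroring a negative stool-metabolome
  result; paired W0/W8 tests on it reject at the nominal rate.
* **Diet**: stable per-participant profiles plus small noise (sd 0.5 in
  food-frequency units, proportional for drinks); zero noise gives exactly
  zero within-participant distances.

What the generator does **not** emulate: read-level artifacts (chimeras,
primer bias), taxonomic structure beyond labels, zero-inflation beyond what
the log-normal-multinomial induces, diet–microbiome interactions, seasonal
or menstrual-cycle variation, and any real effect sizes beyond the planted
ones. Passing the recovery suite therefore shows the pipeline detects the
class of effect it targets at realistic scale and noise — not that the
biological findings themselves are reproduced.

## Seeds and determinism

All randomness flows from one global seed; each stage derives its own seed
from the global seed and the stage name (a small polynomial hash kept
inside 32-bit range), so a stage rerun in isolation reproduces its output.
Identical config and seed reproduce every emitted file byte for byte; the
test suite checks the full-bundle digest. Library code saves and restores
the caller's RNG state.

## Problem sizes in the test suite

The suite favours many small, deep checks: enumeration oracles on 4-block
designs and 5-per-group toys; type-I calibration at 2,000 replicates per
rank test; 200 global-null DAA simulations at n = 30 with 200 ASVs;
planted-effect recovery and subset permutation at the full 150-participant,
300-ASV, 100-subset scale over 10 seeds; and byte-identity of two complete
pipeline runs at a 66-participant scale. These sizes are the package's
choices for a thorough desk-scale validation; all are parameters, and every
simulation-based check fixes its seeds.

## Known limitations

* The bias correction removes only shifts common to all ASVs of a sample
  pair; unequal sampling fractions that correlate with composition are not
  modelled.
* The BioAge surrogate is not the commercial model; only its monotone
  shape, averaging and floor semantics are preserved.
* The t-test on centred log fold changes assumes approximate normality of
  within-participant differences; with heavy zero-inflation at low depth
  the pseudocount dominates and power degrades before validity does.
* Compact letter displays are greedy and not guaranteed minimal in the
  number of letters (they are correct as a covering).
* The diet food-frequency encoding (0–7 per week) is an assumption about
  an unspecified survey scale.
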