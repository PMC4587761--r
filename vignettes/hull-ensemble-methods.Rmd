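---
title: "Convex-hull selective-voting ensembles for small proteomic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Convex-hull selective-voting ensembles for small proteomic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hullvote)
```

## The problem

Whole-pelvis radiation therapy for gynecological cancers frequently causes
gastrointestinal mucositis (GM), an inflammatory injury of the gut mucosa
graded 0-4 on the CTCAE scale. If patients at risk could be identified
*before* treatment, radiation plans could be individualized. The setting
this package addresses is a pilot-scale one: a cohort of 17 patients, each
with a pre-radiation serum proteomic profile (spectral counts for 132
proteins after filtering, two technical LC-MS/MS replicates per sample),
and a binary outcome — class 1 for patients who stayed at GM grade 0,
class 2 for those who developed grade 1-2 GM (9 and 8 subjects
respectively).

Classifying with 132 predictors and 17 samples is hopeless for most
learners. The classifier implemented here sidesteps the dimensionality
problem by only ever working in two dimensions at a time.

## The classifier

**Pair ranking.** Every unordered pair of predictors — $\binom{132}{2} =
8646$ pairs for the full protein set — is scored by the coefficient of
determination $R^2$ of the ordinary least-squares regression of the
numeric class label on the two predictors plus an intercept (main effects
only). $R^2$ is invariant to affine recoding of the label, so 1/2 and 0/1
codings are equivalent. The top $m$ pairs (default $m = 100$) become the
ensemble members. Ties are broken lexicographically on the pair index, and
pairs with a singular normal-equation system fall back to the better
single-predictor fit (zero if both predictors are constant), so ranking is
fully deterministic. Internally the $R^2$ of all pairs is obtained from
the closed-form solution of the $2 \times 2$ normal equations, vectorized
over pairs; the test suite checks exact agreement with per-pair `lm()`
fits.

**Trimmed class hulls.** For each retained pair, the training samples form
a 2-D scatter; one convex hull is built per class. The hulls are then
*trimmed to complete separation* by deterministic peeling:

1. build each class's hull from its surviving points;
2. from each class, remove the *single* surviving point lying deepest
   inside the opposite class's hull (interior distance to the nearest
   boundary; ties broken by lowest point index); repeat;
3. if no point of either class lies in the opposite hull but the hull
   boundaries still cross (possible without any vertex containment),
   remove from each class the hull vertex nearest in Euclidean distance
   to the opposite class's vertex centroid, ties broken by lowest point
   index; repeat.

Every iteration removes at least one point, so the procedure terminates —
either with two disjoint hulls or with an empty hull (for example, when
the two classes' point sets coincide, the sweeps remove everything).

Peeling one point per class per sweep, rather than every overlapping
point at once, is a deliberate choice with real consequences for count
data. Class-conditional spectral counts are typically *nested*: the
GM-positive class has both higher means and higher spread, so its cloud
engulfs the GM-negative support in many pair plots. A mass removal then
deletes the narrow class entirely in one sweep and leaves the wide
class's hull covering the narrow class's home territory — every held-out
narrow-class sample votes for the wrong class, and accuracy drops
*below* chance. Gradual peeling lets both hulls recede from the overlap
region and preserves each class's core; in simulation it turned
systematic anti-learning at the published effect sizes into the expected
positive accuracy.
Hulls may degenerate to segments or points on tiny training folds; these
remain usable, with containment defined by exact point/segment tests at an
absolute tolerance of $10^{-9}$ in predictor units. All hull vertices are
original training points; nothing is interpolated. Disjointness is defined
as: no vertex of either hull inside or on the other, and no pair of
boundary edges crossing. The test suite verifies it against an independent
ray-casting/segment-intersection oracle on a thousand random overlapping
instances.

**Selective voting.** A member votes class $j$ for a sample that falls
within its trimmed class-$j$ hull (boundary inclusive by default — "falls
within" naturally includes the hull itself; configurable) and abstains for
samples outside both. Because the hulls are disjoint, membership in both
is impossible. A simple majority among the members that do vote classifies
the subject; equal non-zero tallies, or universal abstention, leave the
subject *unclassified* — in practice such patients would be evaluated by
other criteria, and the evaluation machinery records rather than imputes
them.

## Performance estimation

Accuracy is estimated by repeated 10-fold cross-validation. With $n = 17$,
fold sizes are deterministic: seven folds of two subjects and three of
one. Twenty repetitions are run by default, each with a fresh random
permutation (run $r$ seeds its fold draw with `base_seed + r`). Within a
fold, pair ranking and hull construction see only the training subjects —
the held-out subjects influence nothing (asserted structurally and by a
no-leakage test).

Five indices are computed per repetition from the pooled confusion counts,
with class 2 (GM-positive) as the positive class: ACC, SEN, SPC, PPV and
NPV. Unclassified subjects are excluded from every denominator; a zero
denominator leaves an index undefined (`NA`) rather than zero. This
denominator convention is a documented choice: with one abstention among
17 subjects, an accuracy of 13/16 = 0.812 is reported, consistent with how
the motivating analysis printed its abstention run. Across repetitions,
each index is summarized as AVG, SD (sample, $n-1$), and the 95% margin of
error $\mathrm{MOE} = t_{0.975,\,\mathrm{reps}-1} \cdot \mathrm{SD} /
\sqrt{\mathrm{reps}}$, with the CI $\mathrm{AVG} \pm \mathrm{MOE}$.

**Permutation control.** `permutation_control()` re-assigns the class
labels by a uniform random permutation (class counts preserved), reports
how many permuted labels coincide with the truth, and re-runs the full
repeated CV. Near-chance (or below-chance) accuracy under permutation
supports the claim that the true-label result reflects real signal. Note
that this classifier, like other selective-voting schemes on tiny
samples, can score *below* 0.5 on uninformative labels (anti-learning):
members selected for apparent training separation can systematically
mis-place held-out points.

One practical caveat baked into the API examples: the permutation seed
must come from a stream unrelated to the one that generated the data. If
the same integer seeds both the generator and `sample()`, the "random"
relabeling can correlate with the generated counts and score absurdly
well.

## Clinical association tests

`association_report()` dichotomizes enrollment order (first `split_rank`
subjects vs the rest; default 8) and BMI (> `bmi_cut` vs $\le$; default
30, with the boundary value assigned to the low group) and applies
Fisher's exact test to each resulting 2x2 table against GM class. The
two-sided p-value follows the probability-mass rule — the sum of
hypergeometric probabilities of all tables with the observed margins no
more probable than the observed one (relative tolerance $1+10^{-7}$) —
which is exactly the rule `stats::fisher.test()` implements; an
independent full-enumeration oracle in the test suite confirms agreement
for all tables with total at most 40. The cohort configuration of
interest (one GM-positive among the first eight enrolled versus seven
among the last nine; eight of twelve high-BMI subjects GM-positive versus
zero of five low-BMI) yields p = 0.0152 and p = 0.0294.

At $n = 17$ these exact tests are markedly discrete and conservative: the
null distribution of the p-value lies well below uniform (Kolmogorov
distance $\approx 0.4$ in simulation), but never above it. The test suite
therefore asserts super-uniformity (validity), not uniformity.

## Prominence analysis

For each training fold of each repetition, the ten highest-$R^2$ pairs are
recorded (20 runs x 10 folds x 10 = 2000 pairs). `tabulate_prominence()`
counts occurrences of each protein and each pair, retaining entries whose
frequency strictly exceeds a threshold (default 50, i.e. 2.5% of 2000).
Each pair contributes two protein incidences, so protein counts always sum
to exactly twice the pair counts. The ranking is reused from ensemble
training rather than recomputed, which guarantees consistency with the
classifier.

On synthetic cohorts the retained list is strongly *enriched* for the
informative signature (the signature's share of retained proteins runs
two to three times its chance rate, and the largest counts typically
belong to signature members such as ITIH2 and LPA) without being a
majority: a strongly predictive protein drags its recurring — and
individually uninformative — pair partners over the frequency threshold
too. Prominence tables should therefore be read as ranked evidence, with
the counts, not as a clean biomarker panel.

## The synthetic cohort generator

The original cohort's raw data are not publicly deposited, so every stage
is exercised on synthetic cohorts with the structure the analysis assumes:

* **Signature.** Twelve proteins with class-conditional means and SDs
  taken from the published spectral-count summaries of the most prominent
  mucositis predictors (`default_signature()`): e.g. apolipoprotein(a)
  (LPA) at 0.9 (SD 1.2) in class 1 versus 5.8 (7.7) in class 2. Two
  entries printed with comma decimals in the source table are read as
  decimal points (F10 class 2: 2.9 (3.5); ITIH2 class 2: 32.4 (21.7)).
* **Count law.** Counts are negative binomial, moment-matched to each
  (mean, SD), when SD² exceeds the mean; otherwise Poisson with the given
  mean, since no standard two-parameter count law is under-dispersed (the
  affected rows — MASP1, CFP, CLEC3B — are reported by message).
* **Noise proteins.** 120 by default, with means drawn uniformly from
  (3, 40), variance twice the mean, identical in both classes.
* **Zero inflation.** Each subject-protein latent level is independently
  zeroed with probability 0.02. Spectral-count zeros arise mostly from the
  count law itself (LPA's class-1 law already gives mostly zeros); the
  structural dropout is kept mild so the published moments survive at the
  cohort level and the 12-of-17 prevalence filter retains about 90-100% of
  proteins. Because several signature proteins have near-zero class-1
  means, a handful of them can legitimately fall below the filter in a
  17-subject draw — the post-filter matrix is approximately, not exactly,
  17 x 132.
* **Replicates.** Two technical replicates per subject are produced by
  multiplying the latent level by a Gaussian factor with CV
  `replicate_cv = 0.1` and rounding to a non-negative integer, so
  replicate averages are always multiples of 0.5.
* **Co-regulation (optional).** Proteins are independent by default: only
  marginal class-conditional moments are known for the signature, and
  simulation showed that with the gradual trimming rule above no joint
  structure is needed to reproduce the method's qualitative behavior.
  Because serum panels are in reality co-regulated (acute-phase and
  lipoprotein programs move together) and a pair-based classifier can
  exploit joint structure, `signature_cor > 0` activates a shared
  per-subject severity factor (log-normal, CV 0.5) inducing
  approximately that pairwise correlation among signature proteins
  within each class. The factor model preserves every class-conditional
  mean and SD exactly (the shared component is carved out of the printed
  variance, capped per protein at what that variance allows); it only
  reallocates variance from independent to shared. Noise proteins stay
  independent — a factor shared by *all* proteins would largely cancel
  under total-count normalization.
* **Effect scale.** `effect_scale` interpolates the class-2 means *and*
  SDs toward the class-1 values (0 = exchangeable classes, used by
  `generate_null_cohort()`, which also disables the covariate
  associations; 4 = strongly separated, used as a positive control).
* **Covariates.** Age, BMI, enrollment rank, cancer type, smoking and
  treatment flags are drawn with class-conditional distributions matched
  to the cohort's clinical summary; with the association switches on and
  default class sizes, the dichotomized enrollment and BMI tables
  reproduce the 1/8-vs-7/9 and 8/12-vs-0/5 configurations exactly, hence
  the p-values 0.0152 and 0.0294.

What passing tests on these cohorts do **not** show: fidelity to real
serum proteomes beyond the printed class-conditional moments. True
inter-protein correlation, marginal distribution families, batch
structure, and depletion-column artifacts are all unknown; the generator
claims none of them.

## Numerical choices

* Geometric tolerance $10^{-9}$ (absolute, predictor units) for boundary
  containment and degenerate hulls; orientation tests use $10^{-12}$.
* Equal-$R^2$ ties broken lexicographically on the pair index;
  trimming tie (equidistant vertices) broken by lowest point index.
* Normalization: total-spectral-count scaling of each subject's protein
  row to the grand-mean row total. The upstream normalization of the
  source data is cited but not specified there; total-count scaling is
  the standard spectral-count choice and is isolated in
  `normalize_profiles()`, so it can be swapped. Covariate columns bypass
  normalization and filtering ("proteins" are filtered, not predictors).
* "Non-zero" in the prevalence filter means strictly positive after
  replicate averaging, and the boundary (exactly 12 of 17) is retained.
* Display rounding is 3 decimals half-up; all stored values are full
  precision.

## Problem sizes used by the test and acceptance suites

The package's own checks run at sizes chosen to exercise every code path
while staying comfortably reproducible on one CPU: the signal-vs-null
separation property uses 10 generator seeds with 5-repetition 10-fold CV
per cohort (the acceptance script runs the full 20-repetition protocol on
one default cohort); geometry invariants use 1000 random instances;
moment recovery uses $10^5$ draws per signature protein and class.

## Known limitations

* The trimming rule is this package's own deterministic definition of
  "trimmed to complete separation"; other selective-voting
  implementations may resolve edge cases differently.
* With one abstention, the printed per-run SPC of the motivating analysis
  cannot be reconciled with its PPV/NPV under any single denominator
  convention; the classified-only convention used here matches all
  indices except that single SPC cell.
* At the published effect sizes with independent proteins, roughly one
  default cohort draw in five realizes too little separation for the
  classifier (true-label accuracy near or even below chance), so the
  true-versus-permuted accuracy contrast, strong in aggregate, does not
  dominate on every single draw.
* Accuracy estimates at $n = 17$ carry large CV-to-CV variability
  (SD $\approx 0.06$-0.08 per index); the MOE quantifies only
  repetition noise, not cohort-level sampling error.
* The generator's covariate associations are constructions that reproduce
  the observed 2x2 tables; they encode no causal claim about BMI or
  enrollment order.
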