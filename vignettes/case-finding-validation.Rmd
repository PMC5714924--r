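---
title: "Claims-based NSCLC case finding: method, validation statistics, and the synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Claims-based NSCLC case finding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casefindr)
```

## Why infer the subtype from treatments

Administrative claims record what was billed, not the histology report.
ICD codes for lung cancer do not separate non-small cell (NSCLC) from
small cell (SCLC) disease, so claims-only studies of either subtype must
infer it. Because the two subtypes are treated differently — SCLC almost
always with platinum/etoposide-type chemotherapy, NSCLC with surgery, PET
staging, platinum doublets with taxanes/pemetrexed/gemcitabine, and
targeted EGFR/ALK agents — the billed first-line treatments and tests
carry a strong subtype signal. `casefindr` operationalises that signal as
a rule set and, just as importantly, provides the statistics a validation
study needs to quantify how well any such rule performs against a
pathology gold standard.

## The classification model

Each **criterion** is a named set of treatment/test *concepts*. A
single-component criterion (topotecan, PET imaging, lung resection)
matches when any of the concept's codes appears in the patient's claims
inside the evaluation window, `index_date ± eval_window` days (default
±90: the three months around diagnosis in which first-line therapy is
captured). A **combination regimen** (2–3 drugs) matches when some anchor
date starts a `combo_window_days` run containing at least one claim of
every component. We default `combo_window_days` to 21 days — one standard
chemotherapy cycle — because claims bill combination partners on nearby
but rarely identical service dates; same-day co-occurrence would be far
too strict, and the window is configurable per criterion for sensitivity
analyses. Matching is pure set membership over `(code_system, code)`
pairs: drug (GPI/HCPCS) and procedure (CPT/ICD-procedure) concepts are
treated identically, and match *multiplicity* never matters, only the
boolean.

The **case-finding algorithm** carries nine SCLC-indicative regimens as
exclusion criteria and the NSCLC-indicative tests/treatments as inclusion
criteria, under an `exclusion_first` policy:

1. any matched SCLC-exclusion criterion → **SCLC**;
2. else any matched NSCLC-inclusion criterion → **NSCLC**;
3. else the default label.

Exclusion-first precedence is a design choice we make explicit (and log
per patient in `decisive_rule`): the exclusion list exists precisely to
remove SCLC-treated patients, so it must dominate when a patient matches
rules on both sides — e.g. a PET scan plus carboplatin+etoposide. The
default label is **SCLC**, making the output binary: a lung-cancer
patient with no matching first-line evidence is conservatively *not*
claimed as NSCLC. Researchers who prefer a three-way output can set
`default_label: UNCLASSIFIED` in the algorithm YAML.

The **control algorithm** uses the complete guideline treatment list
(SCLC regimens included) purely as inclusion criteria with no exclusions
(`inclusion_only`). It is expected to fail — nearly every treated patient
matches something, so it calls NSCLC almost indiscriminately among
treated patients and SCLC for the untreated remainder — and exists as the
baseline against which the case-finding rule's discrimination is judged.

Single agents that also appear inside combinations (an etoposide claim
within a cisplatin+etoposide cycle) still match their own single-agent
rows where those exist: the published criterion table states no
suppression rule, and any precedence belongs in the classification
policy, not in matching.

## Cohort eligibility

Eligibility mirrors standard pharmacoepidemiology practice: index date
inside the intake window, age ≥ 18 at index, and continuous enrollment
for at least `pre_months`/`post_months` around the index. "Month" is
implemented as a 30-day block (configurable) to avoid calendar-month
ambiguity; windows are inclusive at both ends. `gap_tolerance_days`
defaults to 0 — strictly continuous coverage — but is exposed because
real studies often tolerate short administrative gaps; the check is
provably monotone in the tolerance. Exclusions are applied in a fixed,
logged order (missing gold-standard label → intake window → age →
enrollment), each patient tallied under the first rule that removes them,
so the attrition table always sums to the input count.

## Validation statistics

All 2×2 measures are exact functions of (tp, fp, fn, tn). Confidence
intervals: Wilson score for proportions (well-behaved at the 0/1
boundaries reached by near-perfect classifiers), Woolf log method for the
DOR, and a binomial normal approximation for the single-operating-point
AUC. A zero cell makes the DOR undefined; the Haldane–Anscombe +0.5
correction is available but must be requested explicitly
(`correction_applied` is reported either way).

**AUC of a dichotomous rule.** A binary classifier has one operating
point, so its ROC "curve" is the two segments through (1−Sp, Se) and its
area reduces to (Se+Sp)/2. We adopt that definition for the headline AUC
because it is exactly recoverable from a published 2×2 table; the
package's `auc_delong()` computes the same value from 0/1 scores (a
cross-module identity covered by tests), and handles continuous scores —
e.g. the optional criterion-count score — with the general Mann–Whitney
kernel.

**Correlated ROC comparison.** Two algorithms evaluated on the *same*
patients yield correlated AUC estimates, so their difference is tested
with the DeLong placement-value estimator: the test statistic is
(AUC₁−AUC₂)²/Var(AUC₁−AUC₂), referred to χ²(1). We use 1 degree of
freedom, the standard for a two-curve contrast, and surface `df`
explicitly in the result. Degenerate cases are reported, not hidden:
identical score vectors give difference 0 and p = 1; unequal AUCs with a
zero variance estimate set a `degenerate` flag with `p = NA`.

**Covariate robustness.** The hierarchical logistic regression enters
covariates (age, gender, stage, BMI, comorbidity index, insurance) first,
the algorithm's prediction second, and reports McFadden pseudo-R²
(1 − logLik(model)/logLik(null)) at each step; the increment is the
variance in the gold standard uniquely attributable to the algorithm.
McFadden is the variant reported by the major statistical packages'
logistic routines and has the clean likelihood interpretation; p-values
are likelihood-ratio tests, interactions are screened one at a time
against the step-2 model, complete cases only (dropped rows counted), and
fits with numerically 0/1 fitted probabilities raise a separation flag.

## The synthetic test bed

Real validation requires linking claims to a clinical gold standard —
data that cannot be redistributed. The generator instead emulates the
*structure* of such a cohort so every pipeline stage is testable:

- subtype ~ Bernoulli(prevalence), default 0.80 NSCLC at n = 1,353;
- with probability `p_concordant_<subtype>` the patient receives a
  regimen drawn uniformly from their own subtype's criterion list,
  emitted as dated claims with an anchor 0–45 days post-index and all
  combination components within 10 days of the anchor (inside one
  21-day cycle);
- with probability `p_crossover_<subtype>` they *additionally* receive a
  regimen from the other subtype's list — the real-world mechanism
  (shared drugs, off-guideline care) that degrades treatment-based
  classification;
- NSCLC patients receive PET imaging and resection surgery claims with
  probabilities `p_pet_scan` and `p_surgery`;
- demographics are sampled per subtype (age ≈ 60 ± 7–9, ~50% male,
  BMI ≈ 26, Deyo–Charlson ≈ 7.5, ~3% Medicare supplemental, mostly stage
  IIIA–IV) and, by default, carry **no** subtype signal beyond these
  first moments — deliberately, so the covariate-robustness regression
  has a known null to recover;
- enrollment spans cover the index generously except for a configurable
  violating fraction whose span ends 45 days post-index, which the
  eligibility check must remove.

Because the NSCLC regimen pool shares no drug with the SCLC exclusion
list, concordant NSCLC claims can never accidentally fire an exclusion,
and the expected operating point has a closed form:

- Se = (1 − p_crossover_nsclc) × [1 − (1 − p_concordant_nsclc)(1 − p_pet)(1 − p_surgery)]
- Sp = 1 − (1 − p_concordant_sclc) × p_crossover_sclc

The defaults (0.90 concordance and 0.043 crossover for NSCLC with PET
0.90 and surgery 0.30; 0.62 concordance and 0.50 crossover for SCLC) were
chosen once so this closed form sits at Se 0.950 / Sp 0.810 — the
operating point of a strong published treatments-based rule — making the
round trip generate → classify → cross-tabulate → measure a sharp test:
at n = 20,000 the recovered Se and Sp must land within 3 Monte-Carlo
standard errors of the closed form, and they do. Crossover is
parameterised per subtype because a single shared rate cannot reach an
asymmetric operating point like (0.95, 0.81) under this sampling scheme.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: real code dictionaries (the bundled registry is
synthetic placeholders), billing noise such as reversals and adjustments,
regimen frequency differences (sampling is uniform over each list),
line-of-therapy sequencing beyond the evaluation window, and any
dependence of treatment choice on demographics. Results on real claims
depend on the user's code lists and on local practice patterns.

## Numerical and degenerate-input choices

- Dates are ISO-8601 throughout; all window arithmetic is integer days,
  inclusive endpoints; no timezone or calendar-month logic anywhere.
- Combination detection needs only anchors at observed component dates
  (shifting an anchor right to the earliest date in a qualifying set
  never loses it); this is verified against a brute-force enumeration
  oracle on random claim sets.
- An empty enrollment-span set fails the continuous-enrollment check
  (unless the tolerance exceeds the whole window, the same rule applied
  to any fully uncovered window).
- Duplicate claim lines are dropped at load; classification is invariant
  to claim order and duplication.
- The generator draws from a single RNG stream seeded from the config,
  so cohorts are bit-reproducible; the seed is echoed in run metadata.

## Problem sizes

The bundled checks run the pieces at the scale that makes each
informative: oracle comparisons at n ≤ 40 where enumeration is exact;
distributional checks at n = 4,000–10,000; the end-to-end operating-point
recovery at n = 20,000, where 3 Monte-Carlo SEs correspond to ±0.5
percentage points on sensitivity and ±1.9 on specificity — tight enough
to catch a real defect in matching, policy or generator, while the whole
suite stays comfortably fast on a laptop.

## Known limitations

- The published criterion table is transcribed at concept level; the
  shipped code registry is synthetic, so out-of-the-box classifications
  of real claims are meaningless until real dictionaries are supplied.
- A treatments-based rule must not be used to study treatment patterns
  themselves — the predictor and the outcome would coincide.
- The binary-test AUC is an operating-point summary, not a full-curve
  AUC; comparisons with score-based classifiers should use
  `delong_compare()` on scores.
- Only first-line-window evidence is considered; later-line treatments
  are out of scope by design.
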