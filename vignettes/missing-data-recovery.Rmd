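---
title: "Recovering missing allostatic load components from auxiliary ICD-10 diagnoses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering missing allostatic load components from auxiliary ICD-10 diagnoses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(alirecover)
```

## The problem

The allostatic load index (ALI) summarizes physiological "wear and tear" as
the proportion of ten biomarkers falling in a clinically unhealthy range.
The ten components span three body systems — cardiovascular (systolic and
diastolic blood pressure), metabolic (body mass index, triglycerides, total
cholesterol), and inflammation (C-reactive protein, hemoglobin A1c, serum
albumin, creatinine clearance, homocysteine). As a computable phenotype on
electronic health record (EHR) data the ALI runs into a structural problem:
several of its biomarkers are ordered only when a clinician suspects a
problem, so they are missing for most patients, and the missingness is
informative (missing not at random). Laboratory panels such as homocysteine
or C-reactive protein can be absent for nearly the entire cohort while
blood pressures are essentially always present.

Enriched chart-review protocols address this with a *roadmap*: for each
biomarker, a list of auxiliary diagnoses whose presence in a patient's
chart justifies treating the unmeasured biomarker as unhealthy (e.g. a
hypertension diagnosis stands in for a missing blood pressure). Chart
reviews are accurate but expensive; this package implements the
algorithmic analogue, which applies the same roadmap to coded ICD-10
diagnoses and therefore scales to the whole cohort at negligible cost.

## The recovery algorithm

The algorithm has three stages.

1. **Matching.** A search term matches an ICD-10 code when *every word* of
   the term appears in the code's description: "vitamin deficiency"
   matches "Vitamin D deficiency" because both words are present. Text on
   both sides is normalized identically — lowercased, punctuation replaced
   by spaces — so "Auto-immune" becomes the tokens `auto`, `immune`.
   Within a component, a code is matched if *any* term matches it (AND
   over a term's words, OR over terms).
2. **Expansion.** `expand_roadmap()` applies the matching rule to a whole
   catalog, yielding per-component matched-code sets (the *match
   universe*). Matching is component-scoped: a code matched for
   C-reactive protein has no effect on any other component.
3. **Recovery.** `recover()` flips a MISSING patient-by-component data
   point to UNHEALTHY exactly when the patient carries at least one
   diagnosis in the component's matched-code set. Non-missing points are
   never touched, and a missing point can never become HEALTHY: the
   absence of an auxiliary diagnosis is not evidence of health. Every
   justifying (code, term) pair is kept as audit evidence.

```{r}
rm0 <- original_roadmap()
rm0
catalog <- icd10_catalog(tibble::tibble(
  code = c("I10", "A41.9", "E55.9"),
  description = c("Essential (primary) hypertension",
                  "Sepsis, unspecified organism",
                  "Vitamin D deficiency, unspecified")))
universe <- expand_roadmap(rm0, catalog)
universe$codes
```

### Token versus substring matching

The matching rule's phrase "appear somewhere in the description" admits two
readings. The default, **token** mode, requires each term word to occur as
a whole word of the description; **substring** mode only requires it to
occur as a substring, so "art" would match "He**art** failure". Token mode
is the default because substring hits of that kind are clinically absurd,
but both are implemented and exposed (`mode =`) so their consequences can
be compared; the choice is recorded in every match report and run
manifest.

### Thresholds

Discretization thresholds ship as editable YAML (`ali_thresholds()`), with
the comparison direction printed explicitly: SBP > 140 mmHg, DBP > 90,
BMI > 30 kg/m², TRIG ≥ 150 mg/dL, CHOL ≥ 200 mg/dL, CRP ≥ 10 mg/L,
HbA1c ≥ 6.5%, serum albumin ≥ 3.5 g/dL, creatinine clearance < 110 (males)
/ < 100 (females) mL/min, homocysteine > 50 µmol/L. Boundary semantics
follow the printed strictness exactly (`discretize("SBP", 140)` is
HEALTHY; `discretize("TRIG", 150)` is UNHEALTHY). The serum-albumin rule
is deliberately kept as printed even though *low* albumin is the
conventional risk direction; silently "fixing" a published threshold would
make results incomparable, so the anomaly is flagged here and the YAML is
the place to change it.

### The ALI denominator

With missing components the ALI needs a denominator convention.
`compute_ali()` defaults to `"nonmissing"` (unhealthy count / non-missing
count), because observed ALI distributions in sparse EHR data center near
1/3 while patients average only six non-missing components — implausible
under a fixed /10 denominator. A `"all10"` mode is provided for
sensitivity analysis. Under the nonmissing mode, recovering a missing
point to unhealthy can never decrease a patient's ALI, and strictly
increases it whenever the pre-recovery ALI is below 1 — a property the
test suite checks on randomized pipelines.

## Roadmap expansion and adjudication

Term proposers (in practice, large language models; in the tested surface,
any function) are wrapped in a self-consistency loop: `run_expansion()`
invokes the proposer once per iteration in a fresh session — prior context
could skew later proposals — and aggregates the **superset** of all
proposals, every term that appeared at least once. The default of 20
iterations reflects a practical per-day query budget for free API tiers; a
saturation curve (cumulative distinct matched codes) diagnoses when
iterations stop adding information. "Plateau" is not standardized, so the
package's operational definition is declared in `saturation_plateau()`:
the earliest iteration after which every per-iteration gain is at most
`tolerance` new matched codes (default 0). Live API adapters are out of
the tested surface by design: the proposer contract is the boundary, and
the package ships a seeded mock and a fixture replayer so the entire path
runs offline.

Clinician adjudication keeps every item endorsed by *at least one*
reviewer. The ledger can target terms or matched codes; code-level
rejections become per-roadmap exclusion lists applied after matching
(mirroring review workflows that adjudicate the matched codes rather than
the terms). One subtlety is resolved explicitly: an empty ledger endorses
nothing and therefore empties the roadmap's term set, but a ledger
containing *only* code-level entries leaves terms intact — otherwise
adjudicating codes would silently delete the clinical knowledge base.
Adjudication is contractive (the adjudicated match universe and recovery
set are always subsets of the parent's) and idempotent; both properties
are tested on random instances.

## Evaluation statistics

`evaluate_recovery()` assembles: status-flow tables (with the one-sided
rule *asserted* — an algorithm output containing any transition other than
MISSING → UNHEALTHY is an integrity error, not a correction); per-patient
and per-component missingness summaries (quantiles use R's default
linear-interpolation convention, type 7, fixed so IQR assertions are
deterministic); the two-way disagreement taxonomy against chart reviews
(chart-only recoveries, e.g. reviewers using information beyond coded
diagnoses; algorithm-only recoveries, e.g. codes reviewers deemed not
relevant); ALI distribution summaries before and after recovery; and a
logistic regression of care engagement (≥ 1 emergency department visit or
hospitalization) on the ALI with Wald 95% intervals. Chart-review
*protocol errors* — points missing in the EHR where the reviewer recorded
an out-of-window value instead of applying the roadmap — are reclassified
to missing before any comparison, with an audit flag preserving the
original label.

## The synthetic study generator

Real EHR data of this kind cannot be shared, so the package is validated
end to end on a generator with known ground truth. `generate_cohort()`
draws, per patient and component: a latent true status from the component
prevalence; an observed value (uniform within a clinically sized band on
the correct side of the threshold, rounded to 2 decimals with a margin so
rounding never crosses the cutoff) with the component's measurement
probability; roadmap-matching code carriage with one sensitivity for truly
unhealthy and a false-carriage rate for healthy patients; Poisson
background noise codes; a chart-review oracle that recovers missing
truly-unhealthy points with a set probability (independently of code
carriage, so chart-only disagreements arise) and stamps protocol errors;
and engagement from a logistic model on the true ALI, with the review
subset sampled 50/50 on engagement.

Defaults were chosen once to emulate a 1000-patient primary-care sample:
blood pressures never missing and BMI missing for ~2/1000; C-reactive
protein and homocysteine measured for only 4.5% and 1.7% of patients; the
remaining labs measured for 55–60% so the per-patient median is ~6
non-missing components; ~30 noise codes per patient; component prevalence
0.35 (observed ALI median ≈ 1/3); chart recovery probability 0.3 (≈ 11% of
missing points recovered, as prevalence × probability); protocol errors on
1% of missing points; engagement intercept −1.55 and slope 2 on the true
ALI (≈ 32% engaged). Where published marginals exist they drove these
choices; the rest are stated assumptions, not claims about any specific
cohort.

`generate_catalog()` builds catalogs in three strata — guaranteed
token-mode matches, decoys whose descriptions contain term words only
inside longer words (telling token and substring modes apart), and pure
noise sharing no term word even as a substring — so matching-mode behavior
is testable by construction.

### What the generator does and does not emulate

It reproduces the *structure* of the problem: MNAR-capable missingness
(via `mnar_multiplier`), carriage correlated with true status, one-sided
chart recovery, protocol errors, engagement driven by health burden. It
does not emulate realistic ICD-10 code frequency distributions, visit-level
temporal structure (diagnosis dates are uniform in the study window),
correlated components within patients, or adaptive residual-based
selection of later chart-review waves (the review subset is a simple
balanced case-control sample). Passing tests therefore demonstrate
algorithmic and statistical correctness under these conditions, not
clinical performance on any real EHR.

One known edge: the two blood-pressure components share the search term
"hypertension", so their matched-code sets overlap. With the default
conditions this is harmless (blood pressures are never missing), but for
custom configurations where such components can be missing, a
truly-healthy missing point can be recovered through the shared code of
the sibling component — exactly the over-recovery behavior shared terms
cause in practice.

## Numerical and design choices

- **Determinism.** All generator randomness flows from one integer seed
  (`withr::with_seed`, restoring the caller's RNG state); the mock
  proposer seeds each iteration as `base_seed + iteration` so runs are
  bit-reproducible yet iterations independent. Matching output is sorted,
  so results are invariant to catalog row order.
- **Degenerate inputs.** An empty roadmap yields an empty universe and
  zero recoveries (warning, not error); a patient with all ten components
  missing has an undefined nonmissing-mode ALI and is excluded (and
  counted) by the engagement model; a constant ALI or separated fit is
  flagged (`degenerate` / `separation`, intervals reported unbounded)
  rather than returned as a finite estimate.
- **Ties and duplicates.** Terms are de-duplicated after normalization
  within a component; exact duplicate catalog rows collapse with a
  warning, conflicting descriptions for one code are an error.
- **Problem sizes in tests.** Property tests run on 60–120-patient
  cohorts; calibration checks use n = 5000 with 3-binomial-SE bands;
  oracle equivalence uses 200 random catalog/roadmap instances (20–120
  codes, 4–20 terms) in both matching modes; confidence-interval coverage
  uses 200 replicates at n = 500. These sizes make Monte-Carlo error
  negligible relative to the assertions while keeping the default test
  run fast.

## Limitations

- Matching is exact after normalization: no stemming, fuzzy matching, or
  negation detection ("family history of diabetes" matches "diabetes").
  Adjudication exists precisely to remove such clinically invalid hits.
- Diagnosis timing is ignored: any code in the study period marks the
  component unhealthy for the whole period. A lookback window is a
  natural refinement and deliberately not implemented here.
- The algorithm produces statuses, not numeric imputations; downstream
  models needing biomarker values require a different tool.
- The engagement regression is the naive/augmented comparison only; it
  does not reproduce design-based estimators that combine chart-review
  and EHR data with sampling weights.
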