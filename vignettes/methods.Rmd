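---
title: "Methods: case-based survival estimation for CRC screening registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-based survival estimation for CRC screening registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcscreen)
```

`crcscreen` models the decision-support core of a population-based
colorectal-cancer screening registry: code each patient against a minimum
data set, stratify hereditary risk by published pedigree and molecular
criteria, recommend a surveillance schedule, and attach a person-centred
survival percent derived by case-based reasoning against the registry's
deceased members. This vignette explains the model, its assumptions, the
tunable parameters, the numerical contracts, and what the synthetic-data
tests do and do not establish.

## 1. The minimum data set and its codec

The unit of analysis is one registry record: socio-demographics, lifestyle
flags, tumor classification (topology, morphology, grades, pT/pN/pM),
past medical history, symptoms, and vital quality. `crc_codebook()` freezes
one integer code per categorical label and, critically, the *slot order* of
the encoded vector: cosine similarity compares vectors position by position,
so order is part of the contract and travels with a serialized codebook.

Three slots are derived rather than looked up:

* **BMI category** — `weight / (height/100)^2`, binned by the strict
  less-than chain `< 18.5 → 1`, `< 24.9 → 2`, `< 29.9 → 3`, else `4`. The
  chain is deliberately kept as the operational coding script defines it
  (so BMI 24.95 codes as 3, not 2). The script's other quirk — an undefined
  BMI falls through every comparison into category 4 — is available as
  `mode = "faithful"` in `compute_bmi()` for reproducing legacy codings;
  the default `"strict"` mode codes undefined BMI as missing.
* **Age category** — birthdates are Persian-calendar strings
  (`"YYYY-MM-DD"`); age is `reference_year − Gregorian birth year`, a plain
  year difference with no birthday adjustment, again faithful to the
  operational definition (a corrected completed-years mode exists via
  `adjust = TRUE`). `reference_year` is an explicit parameter, never the
  wall clock, so encodings are reproducible. Categories: `< 45 → 1`,
  `45–64 → 2`, `≥ 65 → 3`.
* **Tumor size class** — the size cut depends on pathologic grade: 20 mm for
  grade I, 35 mm for grade II (and, by choice, for any other or missing
  grade); below the cut codes 1, at or above codes 2. Both cuts are
  arguments.

Two code collisions in the source coding sheet are resolved and documented:
ethnicity "Other" (printed as 1, colliding with "Fars") moves to 5, and the
tumor-topology sites are renumbered sequentially 1–10 after collapsing a
case-duplicated "Sigmoid colon" entry — label matching in the package is
case-insensitive, so case-only duplicates cannot be distinct labels. The
missing marker in encoded vectors is `NA`, never 0: 0 is a live code
("No", T0, N0, M0, "Dead" vital status).

The codec is bijective on defined codes: `decode_patients()` returns
canonical labels (derived slots decode to bin labels such as `"18.5-24.9"`,
not to raw weight), and encode ∘ decode ∘ encode equals encode, which the
test suite asserts over generated registries.

### Calendar arithmetic

Jalali↔Gregorian conversion uses the arithmetic 33-year-cycle leap rule via
Julian day numbers — deterministic, dependency-free, and bijective over the
package's supported range (exercised on 1300–1450 AP, i.e. Gregorian
1921–2072). The arithmetic rule can in principle deviate from astronomical
reckoning in rare years far outside this window. The test oracle is a frozen
table of well-documented historical equivalences (e.g. 22 Bahman 1357 =
1979-02-11, 28 Mordad 1332 = 1953-08-19, Nowruz 1395 = 2016-03-20) plus
round-trip bijection in both directions.

## 2. The similarity kernel and its rounding contract

Cosine similarity is computed with a fixed two-stage rounding: each norm is
rounded to 3 decimals (round-half-even) *before* the denominator product,
and the quotient is rounded to 3 decimals again. This is a behavioural
contract, not an implementation accident — the kernel's reference value
(0.972 for the vectors `[3,45,7,2]` and `[2,54,13,15]`) is only reproducible
with this order of operations. Consequences worth knowing:

* the result can differ from the exact cosine by up to ~0.002 (the test
  suite bounds it at 0.002 over random nonnegative integer vectors), and can
  exceed 1.0 before the final rounding for near-parallel vectors; the
  survival estimator clamps its output to [0, 100] accordingly;
* `mode = "unrounded"` gives the plain high-precision cosine where the
  contract is not wanted.

**Missing data.** `prepare_pair()` aligns two encoded vectors before a
query. The default `"pairwise-complete"` policy keeps a slot only when both
records carry an *informative* code there: `NA` slots are dropped, and so
are slots holding an `Unknown` code (code 3 on yes/no/unknown fields) —
treating "unknown" as the literal value 3 would make two ignorances
maximally similar. The `"unknown-as-coded"` policy keeps the 3s for
registries where "Unknown" is considered informative. A pair with no shared
informative slot is an error, surfaced as an `NA` entry (with a warning) in
`similarity_matrix()`.

**Feature scaling.** `similarity_matrix()` compares raw codes over all
slots. The survival estimator, however, scales each slot by its field's
maximum code before the similarity query (`scale_features = TRUE` in
`registry_config()`): feature values must be comparable in scale for a
distance calculation to be meaningful, otherwise a single wide-coded field
(tumor topology runs 1–10) dominates the angle. The estimator also excludes
the two outcome slots (`vital_status`, `survival_quality`) from its default
`feature_set` — an alive query compared to deceased references on the
outcome slots would carry a constant dissimilarity and leak the very label
being estimated. Both choices are configuration, not hard-coded.

## 3. The risk rule engine

All thresholds and clause sets live in `risk_config()`; the shipped defaults
are the widely published criteria.

**Amsterdam II** (all clauses must hold): ≥ 3 relatives with a
Lynch-spectrum cancer (CRC, endometrial, small bowel, ureter/renal pelvis);
≥ 1 of them first-degree; ≥ 2 successive generations affected; ≥ 1 diagnosis
before 50; FAP excluded; ≥ 1 tumour pathology-verified. The relatives table
records degree *relative to the proband* and a generation index, not
pairwise kinship, so "one is a first-degree relative of the other two" is
operationalised as "at least one affected first-degree relative", and
"successive generations" as two adjacent generation indices among the
affected. This is the information actually collectable on a registry
questionnaire; a full pedigree graph is out of scope.

**Revised Bethesda** (any active clause suffices): CRC before 50;
synchronous/metachronous Lynch-spectrum tumours — operationalised as a
personal CRC history on a CRC proband, the registry's available signal;
MSI-high before 60; a first-degree relative with a Lynch-spectrum tumour
before 50; ≥ 2 first/second-degree relatives with Lynch-spectrum tumours.
The active clause set is editable (`bethesda_clauses`), absorbing guideline
version ambiguity.

**The cascade.** Exactly one subgroup per patient, by fixed priority:
confirmed FAP → AFAP → MYH → HNPCC, then Suspected HNPCC (Amsterdam II
*and* Bethesda, no molecular confirmation), Suspected FAP (≥ 10 adenomas
without confirmation), IBD, then the moderate tier (family CRC history
without hereditary criteria; the tier can be disabled, in which case such
patients stay average risk), else average. Every rule that fired is recorded
in `fired_rules`; the first entry decides, making ties deterministic and
auditable. Adenoma thresholds (10 attenuated, 100 classical) and the
MUTYH-biallelic trigger are config values; the source subgroup list contains
an evident duplicate ("Suspected FAP" twice), and the package ships the 7
distinct subgroups.

**Molecular transitions.** `apply_molecular_update()` promotes Suspected
HNPCC to HNPCC on an identified germline mutation, or on abnormal IHC
together with MSI-high. "Untested" is distinct from negative and never
triggers. The operation is idempotent, and the transition is appended to the
rule trace.

**Recommendations.** A `(group, subgroup)` lookup in an overridable table
(annual colonoscopy from age 12 for FAP, 1–2-yearly colonoscopy from age 20
for the Lynch-spectrum groups, 5-yearly from 40 for the moderate tier,
annual FIT from 50 for average risk). The shipped rows are sensible
published defaults, not clinical advice; an uncovered stratum is a
configuration error, never a silent pass-through.

## 4. The survival estimator

The registry estimates survival for *alive* patients from its *deceased*
members. The default `deceased-distance` estimator is the most literal
reading of "estimate the living by similarity to the dead":

\[
\text{percent} = 100 \times \bigl(1 - \tfrac{1}{k}\textstyle\sum_{j=1}^{k}
\text{sim}(x, d_j)\bigr)
\]

over the `k` deceased patients most similar to the query (default `k = 5`),
clamped to [0, 100]. A patient resembling the registry's deceased closely
gets a low percent; one far from every deceased profile gets a high one. The
reference set is the query's own risk stratum when it holds at least `k`
deceased members, the whole registry otherwise — per-subgroup survival
reporting implies within-group comparison where the data support it, and the
`scope` column records which was used. Neighbor ties break by patient id,
ascending.

The alternative `outcome-weighted` mode takes the `k` most similar patients
of *known* vital status and returns `100 × Σ(sim·alive)/Σ(sim)` — a
similarity-weighted alive fraction that uses survivors as well. Deceased
patients' survival time in months is recorded by the codec but unused by
either default estimator.

Interpretation caveat: the percent is a *relative, registry-internal* score,
not a calibrated survival probability. Its absolute level depends on the
similarity geometry of the registry at hand; its value is in ranking,
within-group means, and real-time change on registry updates.

**Group statistics and real-time consistency.** `group_mean_survival()`
reports the arithmetic mean estimate per risk stratum (high-risk subgroup,
or risk tier for unassigned patients) with member counts and a revision
stamp. `upsert_patient()` / `update_on_change()` recompute, after any
insert or edit: the changed patient's encoding, assignment and
recommendation; every estimate whose reference set could contain the changed
patient (in `deceased-distance` mode, alive patients of the old and new
stratum plus all registry-wide-scope estimates, when a deceased record was
touched; everyone in `outcome-weighted` mode, where any patient is a
potential reference); and all stratum statistics. The contract — the
post-state equals a full recomputation from raw records — is asserted
exactly, over random edit sequences, in the test suite. Estimates exist only
once the registry holds a deceased reference; an all-alive registry reports
none rather than guessing.

## 5. The synthetic registry generator

`simulate_registry()` exists so that every pipeline stage is testable
without patient data. It emulates:

* complete, valid minimum-data-set records (every generated registry passes
  validation with zero errors and encodes without error);
* a controllable stratum mix (`subgroup_mix`, default 40% high-risk overall:
  5% FAP, 3% AFAP, 4% suspected FAP, 8% HNPCC, 10% suspected HNPCC, 3% MYH,
  7% IBD — a screening-registry enrichment, not population prevalence), with
  the determining fields set by construction: pedigrees for suspected HNPCC
  are generated to provably satisfy every Amsterdam II clause
  (`generate_pedigree()` verifies against the rule engine at generation
  time, and can instead break one named clause);
* a latent per-patient disease severity that drives the tumor-burden fields
  jointly (pT/pN/pM, grades, tumor size, stage-linked symptoms) with
  preserved marginals — stage components of real tumours are strongly
  correlated, and independent sampling would misrepresent the geometry the
  estimator works in;
* planted prognosis structure: true survival probability
  `p = plogis(c + w·x)` over the *complete* encoded features, with default
  weights on the tumor-burden slots and the intercept `c` calibrated by root
  finding so the expected deceased share equals `deceased_fraction`
  (default 0.3); vital status is then Bernoulli(1 − p). The generator knows
  nothing of cosine similarity or neighbor counts, so recovery of the
  planted ranking by the estimator is an honest calibration check;
* an observation process: missingness (default 2% per maskable field) is
  applied *after* the truth is fixed, and never to stratum determinants or
  outcomes.

What it does **not** emulate: real label frequencies of any population,
informative missingness, measurement error in labels, pedigree
misreporting, competing mortality, or calendar-time effects. Passing tests
therefore establish internal correctness and directional recovery of a
known signal — not clinical validity on real registries, whose per-subgroup
survival levels are not reproducible from published summaries.

## 6. Numerical choices and degenerate inputs

* Rounding is round-half-even (R's `round()`), matching the documented
  kernel contract; the worked example is insensitive to the tie rule.
* Zero-norm pairs and empty overlaps are errors (`similarity_matrix()`
  records them as `NA` with a warning rather than aborting a whole matrix).
* In `outcome-weighted` mode a neighborhood with all-zero similarities falls
  back to the unweighted alive fraction.
* Estimator output is clamped to [0, 100] because the rounding contract can
  push a near-identical pair's similarity marginally above 1.
* The intercept calibration solves on [−30, 30] with `uniroot` at 1e−10
  tolerance; `subgroup_mix` must sum to 1 and `deceased_fraction` lie in
  (0, 1); the seed is mandatory.
* Ingest rejects rows individually (validation error, unknown label,
  duplicate id) with named reasons, and builds the registry from the rest.

## 7. Problem sizes in the shipped tests

The suite exercises: codec round-trips on 500 generated records; 1000
random vectors for the rounding bound; 100 random dates (plus 11 historical
anchors) for the calendar; a ~9&nbsp;200-case combinatorial grid for the rule
cascade; 100 incremental edits on a 200-patient registry checked against
full recomputation after every 4-edit sequence; and calibration on
500-patient registries (deceased fraction 0.3, `k = 5`) over three seeds,
requiring Spearman ≥ 0.3 between estimates and planted survival probability
in the majority. These sizes keep the default suite in the low minutes while
leaving each property's failure modes visible.

## 8. Known limitations

* The Amsterdam II kinship clause is approximated from proband-relative
  degrees (see §3); registries recording full pedigrees should pre-compute
  the clause and override.
* The estimator is similarity-based by design — no Kaplan–Meier or Cox
  modelling, no censoring semantics; recorded survival months are unused by
  default.
* "Referral type" is stored as an uncoded passthrough (searchable, not
  encoded): it has no codebook row.
* The tumor-morphology label list is extensible (`crc_codebook()`'s
  `extra_morphology`) because the source list is visibly truncated.
* Single-process, in-memory registry; the directory store is plain
  CSV/JSON. No concurrency, no authentication, no web layer.
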