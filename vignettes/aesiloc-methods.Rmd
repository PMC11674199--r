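---
title: "Classifying adverse events of special interest with three-valued case-definition logic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying adverse events of special interest with three-valued case-definition logic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aesiloc)
```

## The problem

Hospital-based active surveillance for adverse events of special interest
(AESI) collects one line-list row per suspected case and asks, for each
case, how certain the diagnosis is. Brighton-style case definitions answer
this with graded *levels of certainty* (LOC): level 1 is the most specific
("definite"), level 2 intermediate, level 3 the most sensitive
("possible"), level 4 means the chart did not contain enough information
to confirm or exclude the case, and level 5 means the case is definitively
not one. The grading is criterion-based — clinical signs, temporal
patterns, laboratory, electrophysiology and imaging findings, and
exclusion of alternative diagnoses — so it can be applied mechanically
once each criterion is recorded as present, absent, or unknown.

In routine practice, especially in low-resource referral hospitals, the
third state does the heavy lifting: tests are often not ordered (cost,
availability, clinical priorities), so criteria are *unknown* rather than
negative. aesiloc therefore treats unknown as a first-class value
everywhere, and derives "insufficient information" (level 4) only from
unknowns, never from silently assumed negatives.

## The rule engine

A case definition is a `rule_set`: a list of criteria plus three
predicates (`level1`, `level2`, `level3`) built from `atom`, `all_of`,
`any_of`, `at_least(k, ...)` and `not_of`. Predicates are evaluated under
**strong Kleene three-valued logic**: a conjunction is false as soon as
one child is false, true when all children are true, and unknown
otherwise; disjunction dually; `at_least(k, ...)` is true when `k`
children are already present, false when even resolving every unknown in
favour could not reach `k`, and unknown in between.

Kleene evaluation is *sound*: whenever a predicate evaluates true (or
false) on a partially-known case, every two-valued completion of the
unknowns agrees. The test suite checks this against a brute-force oracle
that enumerates all completions of random expressions. Kleene logic is
not *complete* — `any_of("a", not_of("a"))` evaluates unknown when `a` is
unknown even though every completion is true — which we accept and
document: clinical rule sets do not rely on tautological structure.

Classification evaluates the three predicates in order of specificity and
assigns the first true level. If none is true:

* the case is **level 5** exactly when the level-3 predicate — the most
  sensitive definition — is definitively false; the reported
  `failed_criteria` are the known criterion values that force it false;
* otherwise the level-3 predicate is unknown and the case is **level 4**;
  the reported `blocking_unknowns` are the unknown criteria that
  contribute to that indeterminacy. Resolving all of them forces a
  definite level, which is the operational meaning of "insufficient
  information": these are the missing tests. We attribute blocking
  unknowns to the level-3 predicate (not the level-1 predicate) because in
  any level-4 case it is the level-3 evaluation that is undetermined, and
  because that matches how surveillance reports narrate such cases
  ("lacked a chest radiograph or ECG to reach at least level 3").

A structural invariant makes the levels meaningful: under fully-known
assignments, level 1 implies level 2 implies level 3.
`validate_rule_set()` checks this by exhaustive enumeration (2^n
assignments, refused above 20 atoms). Several of the shipped simplified
definitions are written as `level2 = ANY(raw1, raw2)` and
`level3 = ANY(raw1, raw2, raw3)` — each looser level is the disjunction
of the stricter raw predicates — which preserves the clinical content of
each raw predicate while guaranteeing nesting by construction.

## Shipped definitions

The Guillain-Barré syndrome (GBS) set is the most faithful: level 3 is
the clinical core (bilateral flaccid weakness, decreased/absent deep
tendon reflexes in weak limbs, onset-to-nadir 12 h–28 d, no alternative
diagnosis); level 2 adds *either* CSF white cells < 50/µL *or*
electrophysiology consistent with GBS (AIDP/AMAN/AMSAN); level 1 requires
both cytoalbuminologic dissociation (CSF WBC < 50/µL *with* protein
elevation) and the electrophysiology criterion. A convenience field
`onset_to_nadir_hours` on `case_record()` derives the temporal criterion.

Myocarditis level 1 follows the published logic (histopathology, or
elevated biomarkers with abnormal cardiac MR or echocardiography); its
levels 2–3, and the pericarditis, generalized-convulsion,
encephalitis/myelitis, thrombocytopenia and thrombosis/thromboembolism
sets, are simplified approximations chosen to be internally nested,
tri-state aware, and to reproduce the documented level-4/5 case
narratives (e.g. pericarditis with one suggestive sign but unknown ECG,
chest radiograph and effusion imaging is level 4, blocked by exactly
those tests). Injection-site abscess, TTS, anaphylaxis, ADEM and Bell's
palsy ship as schema examples without validated clinical logic. Because
rule sets are data (JSON files under `inst/definitions/`), an implementer
with access to the full companion-guide algorithms can replace any of
them without touching code.

## The synthetic roster generator

`generate_roster()` emulates a sentinel-hospital AESI roster. Per
condition it draws, independently per case: sex, residence and detection
site as Bernoulli variables; each criterion present with a stated
prevalence (else absent), then masked to unknown with a stated
missingness — mirroring the two distinct processes in real charts
(disease biology vs. test ordering); and a `prop_not_a_case` fraction of
records forced into definitive exclusion via per-condition overrides.
One RNG stream per condition is derived from the single seed, so adding
or reordering conditions does not perturb the other conditions' draws.

Ages are drawn by a **split-uniform** rule: with probability ½ uniform on
[min, median], else uniform on [median, max], rounded to integer years.
This matches all three published controls (minimum, median, maximum)
exactly. A triangular distribution was considered and rejected: for
strongly skewed groups (e.g. generalized convulsion, range 14–82 with
median 31) no triangular mode inside the range attains the stated median,
so the generator's own parameter-recovery requirement (empirical median
within 2 years) would be unsatisfiable.

The default parameters (`default_sim_params()`) encode the stated world
of a one-year surveillance at a large referral hospital: 203 cases
dominated by thrombosis/thromboembolism (100) and generalized convulsion
(38); GBS criterion prevalences and missingness taken from the published
criterion-availability table (electrophysiology tested in ~73 % of cases,
CSF in ~9 %); demographics per the published per-condition marginals.
Where the sources state no value (e.g. criterion prevalences for
myocarditis), defaults were chosen once at plausible clinical magnitudes
and are not tuned.

What the generator does **not** emulate: correlation between criteria
within a case (real charts test in panels), site- or season-structured
detection, duplicate detection across departments, and data-entry error.
A green simulation test therefore establishes that the engine and
summaries behave correctly on rosters with the stated marginal structure
— not that the generator reproduces the joint distribution of real
surveillance data.

## The 203-case reference roster

The study data behind the published tables are not shareable, so
`fixture_roster()` re-creates a deterministic stand-in: per-condition
counts, detection-site, sex, residence and age marginals match the
published demographics table, and criterion patterns are authored by a
minimal-pattern rule — each case receives the weakest assignment that
realizes its narrative outcome, with untested criteria left unknown. The
GBS sub-roster reproduces the published criterion marginals exactly
(11/11, 10/11, 11/11, 7/8, 1/1, 10/11); its single CSF-tested case
carries dissociation but no electrophysiology, so it lands at level 2 —
the only authoring consistent with both the criterion table and the fact
that no GBS case reached level 1. Ages within a condition are
deterministic interpolations hitting the stated min/median/max; the
pooled all-condition median is whatever those interpolations imply (40,
against a published 38) — only the per-condition values were authored
targets.

Crucially, the fixture stores only criteria; every level of certainty in
the acceptance tests is *derived* by the rule engine at run time, so
these are regression targets for the engine, not bookkeeping identities.

## Reporting conventions

* Percentages round half up to integer percent (7/8 → 88).
* An undefined percentage (denominator 0) renders as "—", never 0.
* Medians of even-sized groups are the mean of the central pair, rounded
  half up to integer years.
* Criterion prevalence is n/N where N counts cases with a *known* value.
* One consequence: 196/203 definitively classified is reported as 97 %,
  where truncation would print 96 %.

## Known limitations

* Non-GBS rule sets are simplified approximations; their level-1/2/3
  boundaries should not be used for clinical inference.
* Kleene incompleteness (above) can in principle under-confirm cases
  whose rule sets contain redundant structure; the shipped sets do not.
* The fixture's within-condition joint criterion patterns are authored,
  not observed; only the published marginals and outcome counts are
  faithful.
* Blocking-unknown sets can include criteria (e.g. histopathology) that a
  clinician would not order first; the engine reports logical blockers,
  not a test-ordering recommendation.
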