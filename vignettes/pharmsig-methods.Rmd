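---
title: "Methods: two-source ADE signal detection and knowledge-base evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-source ADE signal detection and knowledge-base evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmsig)
```

## Overview

`pharmsig` screens for adverse drug events (ADEs) of a drug D prescribed
for an indication IND using two complementary designs, then evaluates
and combines the resulting signal sets:

1. **Disproportionality on spontaneous reports.** Each candidate
   reaction gets the report-level 2×2 table (a: drug ∧ event, b: drug ∧
   ¬event, c: ¬drug ∧ event, d: ¬drug ∧ ¬event) and the reporting odds
   ratio ROR = a·d/(b·c). Candidates are the reactions appearing in the
   (D, IND) report subset; a signal is a reaction whose lower 95 %
   confidence bound exceeds 1.
2. **Case-crossover on patient timelines.** Each patient in the cohort
   (diagnosed with IND strictly before first exposure to D) acts as
   their own control: the pre-exposure interval [t_dx, t_first) is the
   control window and the on-treatment interval [t_first, t_last] the
   case window. Occurrence is binary per window — a patient counts once
   in `a` with any case-window mention and independently once in `c`
   with any control-window mention — so both table rows describe the
   same cohort and a+b = c+d always. The analysis is unconditional
   (pooled 2×2 odds ratio), not a matched-pair McNemar analysis; a
   signal needs both the lower 95 % bound above 1 and a two-sided
   independence p-value below 0.05.
3. **Evaluation and hypothesis generation.** Signals are joined to
   knowledge bases by UMLS concept identifier (CUI), exactly or
   flexibly; precision, recall and F1 are computed; the union of both
   sources is scored the same way; and flagged outcomes missing from
   the expanded knowledge bases are ranked as novel-ADE hypotheses.

Within-patient comparison removes time-invariant confounders (sex,
genetics, stable comorbidity). It assumes the outcome-mention process
is otherwise stationary across the two windows; time-varying
confounding (disease progression, co-medication, carry-over) is not
controlled, which is why outcomes lying below the indication term in
the hierarchy are annotated `possible_indication_confounder` rather
than silently trusted — or excluded, since indication-related findings
can still be informative and dropping them would hide real flags.

## Estimator and numerical choices

* **Confidence interval.** Woolf's log-normal interval
  exp(ln OR ± z·√(1/a+1/b+1/c+1/d)) with z = 1.96 by default. The
  interval method is the standard pharmacovigilance default for both
  ROR and case-crossover OR; `z` is exposed for other coverage levels.
* **Zero cells.** The Haldane–Anscombe correction adds 0.5 to *all
  four* cells, and only when at least one cell is zero. The
  `signal_score` records whether it fired. An all-zero table is an
  error, not a score.
* **p-values.** Pearson χ² without continuity correction by default;
  `"auto"` (the default in the detector) switches to Fisher's exact
  test when any expected cell is below 5, recording the choice in the
  result's `method` attribute. Degenerate column margins (outcome never
  or always present) return p = 1 with a warning: such tables carry no
  information about association.
* **Multiplicity.** Bonferroni is min(1, p·m) with m defaulting to the
  number of candidate outcomes actually tested for the drug;
  `bonferroni_m` overrides it (e.g. m = 40 when correcting a ranked
  top-10 table pooled over four drugs). The *signal rule* uses the raw
  p-value; the corrected value is reported for ranking and triage.
* **Ties.** Signal tables sort by descending OR, then ascending
  p-value, then lexicographic CUI, so output order is total and
  reproducible.
* **Window conventions.** Control [t_dx, t_first) is half-open, case
  [t_first, t_last] closed: a mention on the first-exposure day is an
  on-treatment event. A single-exposure patient has a one-day case
  window; `exposure_tail_days` (default 0) can extend t_last to model
  drug persistence.

## Mapping strategies and metrics

Exact mapping intersects discovered and confirmed CUI sets. Flexible
mapping first expands every knowledge-base term *downward* through the
five-level hierarchy (SOC→HLGT→HLT→PT→LLT, multiple parents allowed,
expansion computed on the DAG) to all sub-level terms — a coarse label
term then covers the finer-grained concepts detectors emit. Expansion
is never upward: a specific recorded ADE should not validate a vaguer
detected term.

Metric conventions, where expansion could create ambiguity:

* precision = |matched| / |discovered|, with the discovered set never
  expanded;
* recall = |matched| / |confirmed|, where the denominator is the
  **un-expanded** knowledge-base set. Expansion affects which signals
  match, not how many ADEs there are to find; using the expanded set
  would deflate recall by thousands of descendants and make exact and
  flexible recalls incomparable. (A `match_result` keeps both sets, so
  the other convention is one division away.)
* F1 = 2m / (2m + |discovered∖matched| + |confirmed∖matched|), which
  equals the harmonic mean 2PR/(P+R) whenever P+R > 0 — both identities
  are property-tested.
* A discovered CUI counts at most once even when two knowledge-base
  parents share the descendant that matched it.

The knowledge-base loaders follow the SIDER 4.1 column layout
(label id, STITCH flat/stereo ids, CUI, MedDRA term type, code, name)
and a 4-column ADReCS-style flat dialect. SIDER extraction is
restricted to labels whose indications contain the requested indication
name — exact, case-insensitive matching, chosen for reproducibility
over recall. LLT/PT duplicates of one concept collapse during CUI
de-duplication, which also sidesteps the question of which term type to
prefer. A drug's extraction indication is never admitted as its own
confirmed ADE.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study
conditions under which every statistical guarantee of the package is
demonstrated.

* **Hierarchy**: a perfect multi-way tree with configurable branching
  (default 3,3,3,3 → 121 terms, 81 LLTs) and deterministic codes.
* **Reports** (default n = 5,000): each report lists the focal drug
  with probability 0.3 plus one comparator drug, the study indication
  with probability 0.9, and each of the 30 pool outcomes as a reaction
  with background probability 0.02. For a planted pair the exposed
  reaction probability is raised to p₁ = R·q/(1−q+R·q), which makes the
  analytic cell probabilities attain the target ROR R exactly;
  infeasible configurations are rejected analytically at construction.
* **Timelines** (default n = 2,000 patients over a 20-year span): one
  indication diagnosis, first exposure 30–365 days later (so every
  patient has a non-empty control window), 90–1,500 days on drug.
  Outcome occurrence is Bernoulli per (patient, outcome, window):
  planted outcomes use p_case = 0.30 / p_control = 0.05 (analytic
  OR ≈ 8.14), background outcomes one shared probability (default
  0.05) in *both* windows. The Bernoulli-per-window default maps
  one-to-one onto the binary occurrence counting of the case-crossover
  table and gives closed-form truth odds ratios; `background_mention_rate`
  is therefore read as that per-window probability. A
  `mention_mode = "poisson"` flag instead draws background mention
  counts from a Poisson process at the configured rate per patient-year
  scaled by window length — more realistic mention streams, at the cost
  of a length-dependent background (planted outcomes stay Bernoulli so
  the planted truth remains exact).
* **Knowledge bases**: one indication-annotated label carries three of
  the five planted ADEs (one stored as its PT parent so only flexible
  mapping can recover it) plus two confirmed-but-never-planted terms
  that cap attainable recall at 0.6; a decoy label with a different
  indication must never leak through the restricted extraction. The
  two uncovered planted ADEs are the ground truth for the
  novel-hypothesis table.
* **Determinism**: one master seed derives fixed per-table sub-streams,
  so outputs are byte-reproducible and regenerating one table does not
  perturb the others.

Effect sizes (ROR 8, OR ≈ 8) are in the range of the strong,
well-supported associations such screens are designed to surface, and
large enough that recovery failures indicate bugs rather than sampling
noise. What the generator does *not* emulate: reporting biases and
duplicate reports, NLP extraction noise (negation, sectioning),
coding-granularity mismatch beyond the planted parent-level terms,
drug–drug interactions, and time-varying mention rates. Passing tests
therefore demonstrate correctness of the estimators and plumbing under
the stated sampling model, not robustness to those real-data
pathologies.

## What the test suite establishes

Beyond unit examples, the suite checks (problem sizes chosen to give
stable Monte-Carlo behavior at interactive runtimes):

* closed-form oracle equivalence of ROR/OR scores on hundreds of random
  tables, plus label-swap antisymmetry and CI narrowing under cell
  scaling;
* cohort conservation a+b = c+d for every outcome on all fixtures, and
  translation invariance of the whole analysis under date shifts;
* parameter recovery: over 200 replicates of 2,000-patient cohorts,
  the mean log-OR estimate lies within 3 Monte-Carlo standard errors of
  ln(27/7) and 95 % CI coverage falls in [92 %, 98 %];
* null calibration: with no planted effects (50 null outcomes, 40
  seeds), the flag rate of the lower-bound rule — and of the stricter
  EMR joint rule — stays within binomial tolerance of the nominal
  2.5 %;
* flexible-⊇-exact dominance and union-recall monotonicity
  (recall(combined) ≥ max of the sources) on 100 random hierarchies and
  signal sets — the mechanism by which combining sources raises recall;
* Venn inclusion–exclusion conservation on random triples;
* end-to-end recovery: across 100 default scenarios, the three
  knowledge-base-covered planted ADEs appear in the flexible matched
  set and both novel planted ADEs in the hypothesis table in ≥ 90 % of
  seeds.

## Demographic summaries

Report-table summaries follow the spontaneous-report convention:
percentages against the full total including unknown-gender reports (so
female + male < 100 %), while cohort summaries use the two-gender sum
and include race counts. Ratios and percentages round half-up to one
decimal; a cohort with no male records reports an undefined (NA) ratio
rather than dividing by zero.

## Known limitations

* The comparator population for report tables defaults to the whole
  loaded dataset (`comparator = "all"`, standard disproportionality
  practice); `"indication_restricted"` confines the table to
  indication-matched reports. The choice can shift borderline signals.
* Case-crossover here is unconditional; with strong within-patient
  correlation a conditional analysis would differ.
* Exposure is reduced to [first, last] use; gaps, dose and switching
  are ignored, and control-period carry-over from earlier drugs is not
  modeled.
* Flexible mapping only bridges granularity downward from the
  knowledge base; a detected term coarser than the recorded ADE stays
  unmatched.
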