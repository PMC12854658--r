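---
title: "Detecting antithrombotic-related bleeding: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting antithrombotic-related bleeding: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bleedr)
```

`bleedr` classifies inpatient stays of older patients on antithrombotic
therapy as major bleeding (MB), clinically relevant nonmajor bleeding
(CRNMB), or no bleeding, from two complementary views of the medical
record: structured data (hemoglobin series, transfusions, prescriptions,
billing diagnoses) and discharge-summary text. This vignette explains the
underlying model, the parameters that matter, the numerical conventions,
and what the synthetic test bed does and does not demonstrate.

## The rule engine over structured data

The severity definitions adapt the International Society on Thrombosis and
Haemostasis (ISTH) criteria for use with routinely collected data. Two
laboratory summaries drive most decisions:

* **ΔHb** — the largest decline between two hemoglobin measurements at most
  `window_hours` apart (default 48 h, the conventional window for "acute"
  falls). Both measurements must belong to the stay; a single measurement
  can never produce a drop.
* **minHb** — the stay's nadir (earliest timestamp on ties).

A stay is MB if ΔHb ≥ 4 g/dL; if ΔHb ∈ [2, 4) g/dL and the patient died
within `death_horizon_hours` (default 24 h) of the drop; if minHb < 7 g/dL;
if minHb ∈ [7, 9] g/dL with death within the horizon of the nadir; if more
than 5 units of whole blood or red cells were transfused during the stay
(plasma does not count toward this criterion); if a reversal agent
(idarucizumab, andexanet alfa, or a prothrombin complex concentrate) was
prescribed; or if an MB diagnosis code is present. The CRNMB tier consists
of the same ΔHb and minHb bands without the linked death, plus the CRNMB
code list. MB always outranks CRNMB; a stay with firing criteria in both
tiers is MB.

Several boundary conventions are deliberate and fixed:

* **Band edges.** "4 g/dL or more" pins the MB edge of the drop bands, so
  the CRNMB drop band is the half-open interval [2, 4). The nadir bands are
  `< 7` strictly for MB and the closed interval [7, 9] for the intermediate
  band. Together the bands are exhaustive and non-overlapping, so every
  stay gets exactly one label.
* **Death anchor.** The clinical definitions link death "within 24 hours"
  to the bleed but do not name a measurement anchor. We anchor at the
  drop's *later* measurement (the event's detection time) for ΔHb rules
  and at the nadir's timestamp for minHb rules, with an inclusive bound
  (death at exactly 24 h counts). This is one defensible reading; the
  anchor is a function argument, not a constant, so sensitivity analyses
  are straightforward.
* **Tie-breaks.** Among equal maximal drops, the earliest end timestamp
  wins, then the earliest start. Nadir ties resolve to the earliest
  measurement. These rules make the engine a pure function of its input.
* **Missing data.** Absent labs, transfusions, or codes mean "criterion
  not met", never an error: real extracts are incomplete and the engine
  must be total over valid bundles.
* **Eligibility boundary.** A stay of exactly 24 h 0 min is eligible ("at
  least 24 hours" read inclusively); age is age at admission.

Diagnosis matching is dot-aware: codes are normalized (uppercase, dot
inserted after the chapter+category block, `I610` → `I61.0`) and a
trailing-underscore pattern such as `I61_` matches the bare stem and every
dotted subdivision, but never a sibling like `I63.0`. The packaged lists
(12 MB, 41 CRNMB patterns) ship as a CSV data file rather than code so they
can be audited and overridden; the lists intentionally reproduce their
source table verbatim, including its uneven coverage of the chronic-ulcer
subcodes (`K25.4` absent while `K26.4` is present) — correcting the table
would break comparability. The present-on-admission flag is carried through
for reporting but does not alter matching, since the structured record
cannot reliably time bleeding onset.

Units are a classic failure mode for hemoglobin rules: values in g/L are
exactly 10× the g/dL thresholds. `read_cohort()` therefore requires an
explicit per-row unit declaration (`g/dl` or `g/l`) and never guesses from
magnitude. Laboratory values outside (0, 25] g/dL after canonicalization
are load errors, and labs more than 24 h (configurable) outside the stay
bounds are dropped with a warning, because pre-admission values would
corrupt ΔHb.

## The discharge-summary classifier

Text complements the structured record: past bleeding is usually only in
prose, and many minor bleeds never reach a code or a transfusion. The
classifier works at sentence level in three stages — (1) bleeding-relevant
vs irrelevant, (2) irrelevant / antecedent (history) / active, (3) MB vs
CRNMB within active sentences — and a document inherits its highest-priority
sentence label (MB > CRNMB > history > none). The priority order is
conservative by design: when a summary mentions both a minor and a major
bleed, the stay is a major-bleeding stay.

Design choices where the architecture was open:

* Stage 2 re-includes an *irrelevant* class and can veto stage 1; a
  sentence must survive both gates. This keeps stage 1 cheap and
  high-recall while stage 2 arbitrates with three-way context.
* Features are lemma 1–2-grams with a document-frequency floor (default
  `min_df = 2`) and smoothed TF-IDF weighting, L2-normalized per sentence.
  Bigrams matter for negation ("no active bleeding") and history phrasing.
* Two linear families are trained per stage — ridge-penalized logistic
  regression (`glmnet`, λ grid 0.1/0.01/0.001) and a linear SVM (`e1071`,
  cost grid 0.1/1/10) — and the winner is picked by 5-fold cross-validated
  macro-F1 on stratified folds. Ties prefer the logistic model, then the
  stronger regularization: interpretable weights and simpler models win
  unless the data argue otherwise.
* Class imbalance (irrelevant sentences dominate real summaries) is
  handled with inverse-frequency class weights in both families.
* Everything language-specific is pluggable: the lemmatizer is a plain
  function (`NULL` = identity, a valid configuration), the abbreviation
  list for sentence segmentation is an argument, and the synthetic
  templates exist in a language-neutral and a French-like set. The test
  suite runs with the neutral set so no language model download is ever
  needed. No contextual-embedding stage is implemented; the vectorizer is
  a self-contained component that an embedding backend could replace.

Training is deterministic under its seed: fold assignment is the only
random element, and `glmnet`/`libsvm` fits are themselves deterministic.
The corpus splitter allocates `round(n × fraction)` documents to training,
stratified by document label via largest-remainder apportionment, so a
400-document corpus at 0.7 always splits 280/120 and class proportions are
preserved within one document.

## Combining detectors and validating

`combine_calls()` implements union (either detector positive; severity =
max) and intersection (both positive; severity = max). Union trades
precision for sensitivity, intersection the reverse — set-theoretic facts
that the test suite asserts on random call sets. When the two detectors
disagree on severity the default keeps the *more severe* label; the
alternative reading, in which the text detector's severity overrides on
co-detection, is available as `nlp_overrides = TRUE`. A `history` call is
negative for active-bleeding combination but preserved in the output,
because bleeding history is itself useful (it is invisible to structured
data).

Validation offers three binarizations: any bleeding vs none; MB vs all
else; and CRNMB vs none with gold-MB stays excluded from the denominator.
In the last scenario a call counts positive only if it is exactly CRNMB;
the scenario asks "is CRNMB detected among non-MB stays", not "is anything
detected". History calls are negative in all scenarios. Six metrics are
computed from the confusion counts; sensitivity, specificity, PPV, NPV and
accuracy carry Wilson 95% score intervals (well-behaved near 0 and 1, with
exact 0/1 bounds at the degenerate corners), F1 is a point estimate only.
Metrics with empty denominators are reported as `NA` with a reason, never
silently as 0. Reported percentages round half away from zero (2 decimals
for prevalence, 1 for attribution shares); exact values are always
retained alongside.

Interrater agreement uses Fleiss κ for a fixed rater count, with the
Landis–Koch interpretation bands and a large-sample z test of κ = 0. The
implementation is checked in the tests against a hand-computed 4-item,
3-rater example (κ = 1/3) and against near-zero behaviour under label
permutation.

## What the synthetic cohort emulates — and what it does not

The generator produces eligible stays by construction (age 65+, an
antithrombotic ATC code, ≥ 24 h) with, per positive stay, exactly one
injected qualifying event drawn from a configurable criterion mix:
engineered hemoglobin pairs (drop 4 + U(0,3) g/dL for MB, 2–3.9 g/dL for
the intermediate band), slow "ladder" descents (0.9 g/dL per 24 h, so no
48-h pair ever reaches 2 g/dL) to nadirs in (5, 7) or [7, 9], 6–8
transfused units, one reversal-agent prescription, or one listed diagnosis
code. Deaths for the death-linked criteria fall at anchor + U(0, 23.5) h,
with a configurable fraction at exactly +24 h to pin the inclusive
boundary. Default prevalences are 8% MB and 15% CRNMB, the magnitudes
reported for this population in hospital data; baseline hemoglobin is
N(13, 1) g/dL truncated to [10, 17] with 3–10 measurements at irregular
4–24 h spacing. A quarter of negatives (configurable) are near-misses built
at the rule boundaries: 1.9 g/dL drops, 9.1 g/dL nadirs, exactly 5 units,
and codes absent from the lists. Documents are assembled from label-keyed
template sentences plus irrelevant filler and hard-negative negated
mentions, and the emitted document label always equals the priority
aggregation of the emitted sentence labels.

This construction makes two strong guarantees testable — the rule engine
must recover generator truth perfectly, and near-misses must never fire —
and the suite asserts both on a 1000-stay cohort. But the guarantees are
about *the rules*, not about clinical reality: the generator has no
nonhemorrhagic anemias, no hemodilution, no transcription errors, no
comorbidity structure, and its summaries are templated, not dictated
prose. Perfect synthetic performance therefore demonstrates correctness of
the implementation, not expected accuracy on hospital data, where the same
rules are known to trade precision for sensitivity.

## Problem sizes and runtime choices

The shipped tests and the acceptance script run at desk scale: 1000-stay
cohorts for the closure checks, 1000 random series (n ≤ 200) against the
all-pairs oracle for the windowed-drop search, 400-document corpora for
classifier training, 500 random call-set pairs for the combination laws,
and 1000 label permutations for the κ null check. These sizes were chosen
so the whole suite completes in a couple of minutes while still exercising
every rule boundary; all of them scale up by changing one argument.

## Known limitations

* Transfusions enter as explicit unit counts; mapping from procedure
  billing codes of limited granularity to units is site-specific and out
  of scope.
* The engine does not attribute bleeds to specific antithrombotic agents
  (causality assessment needs chart review), and cannot distinguish
  present-on-admission bleeding from in-hospital onset using structured
  timestamps alone.
* The text pipeline reproduces an architecture, not trained weights; on
  real summaries it must be retrained on annotated local data, and its
  performance there is an empirical question this package cannot answer.
* Fixed thresholds mean fixed operating points; no ROC analysis is
  provided.
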