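---
title: "Depression phenotyping from coded diagnoses and clinical-note mining: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depression phenotyping from coded diagnoses and clinical-note mining: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(textpheno)
```

## The problem

Depression is a frequent, under-coded comorbidity in cancer patients.
In longitudinal electronic health records (EHRs) the evidence for a
depressive disorder is scattered across two kinds of data: structured
ICD-9-CM diagnosis codes attached to visits, and free-text clinical notes
— in the setting this package models, written in Spanish or Catalan —
that mention antidepressant drugs or depressive-disorder terms, often
with misspellings and often inside negations ("niega tristeza",
"sense clínica depressiva").

`textpheno` implements the full analysis pipeline for this setting:

1. **Lexicons** — normalized bilingual dictionaries of antidepressant
   substances and brands, depressive-disorder terms, and an ICD-9-CM
   depression code set.
2. **Text mining** — language identification, tokenization with exact
   character offsets, and misspelling-tolerant dictionary matching.
3. **Negation** — a Conditional Random Field (CRF) tagger for negation
   markers and scopes, plus a NegEx-style rule baseline; mentions inside
   a scope are excluded from evidence.
4. **Phenotyping** — study selection filters, per-channel temporal
   classification of evidence relative to the cancer-diagnosis index
   date, paired before/after tables.
5. **Statistics** — continuity-corrected McNemar tests on the discordant
   counts, chi-square associations, and the published table layouts.
6. **Synthetic cohort generator** — fully ground-truthed patients,
   visits, and notes, so every stage is testable without access to
   protected clinical data.

## Evidence channels and temporal classes

Each patient contributes three independent *evidence channels*: ICD
(a visit bearing a depression code), DRUG (a non-negated antidepressant
mention), and DISORDER (a non-negated disorder-term mention). Relative
to the cancer-diagnosis *index date*, each channel receives a *temporal
class*: `none`, `before_only`, `after_only`, or `both`. The COMBINED
channel is the union of before-evidence and after-evidence across the
three channels.

An event dated exactly on the index date counts as **after** by default
(`index_day_counts_as = "after"`): diagnosis-day notes typically concern
the cancer episode itself. The alternative convention is available as a
flag because the choice is genuinely open.

For one channel, excluding the `both` patients leaves discordant counts
`b` (before-only) and `c` (after-only). The paired test statistic is the
Edwards continuity-corrected McNemar

$$\chi^2_1 = \frac{(|b-c|-1)^2}{b+c},$$

with the p-value from the upper tail of $\chi^2_1$. This is the variant
`mcnemar_cc()` uses by default (an uncorrected option exists): it is the
one whose results match the worked examples this package reproduces, and
it agrees with `stats::mcnemar.test(correct = TRUE)`, which the test
suite uses as an independent cross-check. For $b + c \gtrsim 30$ the
corrected statistic also tracks the exact binomial sign test closely;
the suite quantifies that deviation. The chemotherapy–depression
association uses the Pearson chi-square without continuity correction
(`chisq_independence()`, delegating to `stats::chisq.test`).

```{r mcnemar}
mcnemar_cc(89, 575)
```

## Selection filters

`apply_selection_criteria()` includes a patient iff, checked in order:
exactly one qualifying cancer (breast — women only — or colorectal);
at least 2 visits strictly before and 2 on-or-after the index date;
stage in situ, I, II or III (stage IV patients are excluded — they are
typically in palliative care, where depression prevalence follows a
different regime); and a non-missing chemotherapy flag, which is how
"complete treatment information" is operationalized here. Each excluded
patient is tagged with the first rule it fails.

## Matching with misspelling tolerance

Matching runs on *normalized* text: lower-cased, Spanish/Catalan
diacritics folded to ASCII, whitespace collapsed (`normalize_surface()`,
idempotent). Raw surfaces are preserved for reporting. For a lexicon
surface of *k* tokens, every window of *k* consecutive note tokens whose
space-joined normalized form lies within restricted Damerau–Levenshtein
distance (substitution, insertion, deletion, adjacent transposition) of
the surface yields a candidate mention.

Tunable parameters, with defaults and rationale:

* `max_edits = 1` — one edit captures the dominant clinical-note typo
  classes (dropped accents are already handled by normalization;
  single-letter slips and transpositions by the distance).
* `min_fuzzy_nchar = 5` — surfaces shorter than 5 normalized characters
  must match exactly: at distance 1, short tokens are too ambiguous.
* Overlapping candidates are resolved by longest span, then smallest
  distance, then leftmost position, then lexicon order. The last
  tie-break matters only for pathological ties (a one-edit perturbation
  can sit at distance 1 from two related surfaces, e.g. `citalopram` /
  `escitalopram`); it makes output deterministic, and channel-level
  classification is unaffected because such ties stay within a category.

The matcher is implemented in compiled code for speed; the test suite
holds it equal to a brute-force all-windows × all-surfaces matcher built
on an independent pure-R distance implementation.

## Negation detection

Notes are segmented into sentences at `.`, `;`, and newline. Two
detectors are provided:

* **Rule baseline** (`rule_based_negation()`): each trigger token
  (es: *no, sin, niega, descarta, ausencia*; ca: *no, sense, nega,
  descarta, absència*) opens a scope over the next `window = 5` tokens,
  truncated at the sentence end or before a terminator
  (*pero/aunque/sino*, comma).
* **CRF tagger** (`train_tagger()` / `tag_negation()`): a linear-chain
  CRF over BIO labels `{O, B-MARK, I-MARK, B-SCOPE, I-SCOPE}`, trained
  by L2-regularized maximum likelihood (forward–backward gradients,
  L-BFGS; `lambda = 0.05`, chosen as a mild default for a few thousand
  sparse binary features). Decoding is Viterbi; a malformed `I-X`
  without a compatible predecessor is repaired to `B-X`. Features are
  purely orthographic plus trigger-list membership over a −2…+2 window
  (surface, word shape, 3-character prefix/suffix, punctuation/digit
  flags, sentence-boundary flags). No part-of-speech tagging is used:
  a full tagger would add a heavyweight dependency, and on clinical
  shorthand orthographic features carry most of the signal.

A mention is negated iff its span overlaps a detected scope by at least
one character; negated mentions are excluded from evidence. Training is
deterministic given the corpus and hyperparameters; save → load → predict
is bit-identical to predict before save.

## The synthetic cohort generator

Real hospital EHRs of this kind are not redistributable, so the
generator is a first-class module. Its defaults *are* the study
conditions the package is designed around; they are fixed once and not
tuned per experiment:

* `cancer_mix = 0.48` breast (the remainder colorectal, 57.9% men);
  ages drawn near 62 (breast) and 70 (colorectal) years.
* `stage_probs = (0.18, 0.27, 0.33, 0.19, 0.03)` over in situ…IV —
  stages I–III dominate, with a small stage-IV mass so the selection
  filter is exercised.
* `p_depression_before = 0.08`, `p_depression_after = 0.28` —
  patient-level probabilities of depression evidence in each period,
  sampled independently; they reproduce the before/after asymmetry that
  drives the paired analysis (combined-channel ever-rates of roughly 8%
  and 28%).
* `channel_probs = (icd 0.65, drug 0.55, disorder 0.35)` — per
  depressed period, each channel emits evidence independently; if none
  fires, one is forced (proportionally), so every depressed period is
  observable and the combined truth class is exactly the sampled
  (before, after) pair. This mirrors the relative channel frequencies
  of the target analysis, where ICD codes are the most common single
  source and disorder-term mentions the least.
* `negation_rate = 0.10` — per note, probability of a planted *negated
  decoy* mention. Decoys are planted independently of depression status
  and are never evidence; evidence mentions are never negated. This
  separation keeps the planted temporal classes well defined while
  still exercising the negation filter on realistic text.
* `misspelling_rate = 0.10` — probability that a planted surface is
  perturbed by exactly one edit (`inject_misspelling()`, letters only,
  words of ≥ 4 characters, surfaces of ≥ 5 characters — aligned with
  the matcher's tolerance so recall properties are provable).
* `visits_per_patient = c(4, 12)`, with at least 2 visits strictly
  before and 2 on-or-after the diagnosis date; visit dates are uniform
  in ±3-year windows around it. Temporal classes are sampled directly
  rather than through a longitudinal disease model: the downstream
  analysis consumes only the class.
* `language_mix = 0.6` Spanish per note, matching the bilingual corpus
  proportions (572 es / 277 ca).
* Chemotherapy is sampled from a per-stage baseline plus
  `chemo_depression_boost = 0.15` for patients with after-index
  depression, which creates the chemotherapy–depression association the
  chi-square operation tests.

Note text is template-based: clinical-style sentence skeletons per
language, so ground-truth spans and scopes are exact by construction.
Filler sentences contain no lexicon surface and no negation trigger.
Negated templates place the term inside the trigger's scope; scope
length varies (some scopes exceed the rule window of 5 tokens, some stop
at a conjunction), which is what lets the CRF overtake the rule
baseline. What the generator deliberately does **not** model: free
clinical prose, abbreviations, cross-sentence scope, hedging, visit-level
correlation of content. Passing on synthetic data therefore demonstrates
the pipeline's mechanics — recall under planted noise, correct negation
exclusion, correct paired arithmetic — not performance on real notes.

The annotated negation corpus (`emit_negation_corpus()`) draws sentences
from the cohort's notes, 572 Spanish and 277 Catalan by default, with
negation-bearing sentences over-sampled up to half of each language
quota and a 25% stratified held-out split. (The per-language counts are
the authoritative defaults; their total is 849.)

## Numerical and degenerate-input choices

* Percentages print via half-up rounding to one decimal
  (`proportion_cell()`); integer-valued percents print bare, matching
  the published table style ("(91)", not "(91.0)").
* `mcnemar_cc(0, 0)` is an error (the test is undefined without
  discordant pairs); `build_paired_table()` accepts the degenerate
  all-`both` cohort (zero considered patients); `render_tables()` on an
  empty cohort returns empty tables without error.
* Visits without time-of-day are ordered by (date, visit id).
* Cohort generation and corpus sampling run in a private RNG stream:
  they are pure functions of their seeds and do not disturb the
  caller's RNG.
* Unknown-language notes are matched against the full lexicon and
  default to Spanish trigger lists.

## Problem sizes used in the shipped checks

The reproducibility script runs the full pipeline on a 1,000-patient
cohort (misspelling rate 0.2) and trains the CRF on the default
bilingual corpus drawn from a 450-patient cohort; the test suite uses
cohorts of 60–2,000 patients. These sizes give stable (deterministic,
seeded) results while keeping a full run in the minutes range on one
CPU.

## Known limitations

* The bundled lexicons are synthetic stand-ins (35 substances with 82
  Spain-style brand names, a ~20-surface disorder-term list, a 7-entry
  ICD-9-CM depression code set). Real analyses should load their own
  dictionaries via `load_lexicon()` / `load_code_set()`; the pipeline is
  lexicon-agnostic.
* Language identification is a function-word profile comparison,
  adequate for separating Spanish from Catalan clinical notes but not a
  general language identifier.
* Negation handling is sentence-local; family-history and hypothetical
  contexts are out of scope.
* The CRF's feature set is orthographic; on real notes with richer
  syntax, performance would need re-evaluation on a manually annotated
  corpus (ingestable through the CoNLL interface).
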