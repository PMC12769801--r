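---
title: "Rule-based asthma phenotyping with Predetermined Asthma Criteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based asthma phenotyping with Predetermined Asthma Criteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asthmapac)
```

## The phenotype

The Predetermined Asthma Criteria (PAC) are a fixed chart-review rule set
for classifying a patient's asthma status retrospectively from medical
records and for dating incident asthma. A patient is **definite** asthma if
a physician has diagnosed asthma, or if three conditions hold together:
repeated respiratory symptoms (cough with wheezing and/or dyspnea, or cough
and/or dyspnea plus wheezing at examination), substantial symptom
variability or symptom-free periods of weeks, and at least two of eight
minor criteria. A patient with only the first two conditions is
**probable** asthma; both definite and probable count as asthma for
downstream analysis, because most probable cases progress to definite over
time. Eight exclusion conditions (fixed airflow obstruction, foreign body,
immunodeficiency, and other mimics) remove a patient from the case pool.
The **index date** is the first calendar day on which cumulative documented
evidence meets the criteria.

`asthmapac` implements this phenotype over two inputs: free-text clinical
notes (JSONL, one note per line) and a structured observation table (CSV:
labs, spirometry, smoking status). The core assumption inherited from the
criteria themselves is day-granular evidence dating: an event is dated by
the note or observation date that documents it, since records carry no
finer in-text event time that we attempt to resolve.

## Text processing

Section segmentation is line-anchored header matching against an editable
dictionary (`HISTORY OF PRESENT ILLNESS:`, `FAMILY HISTORY:`,
`DIAGNOSIS:`, ...); text before the first recognized header — or a
headerless note — is labeled `unknown`. Section spans are 0-based,
half-open, and tile the note, so every character belongs to exactly one
section.

Sentence splitting is deterministic and rule-based: terminators (`.`, `!`,
`?`) and newlines end a sentence, except when a period closes a token on
the abbreviation guard list (`Dr.`, `vs.`, ...) or sits between two digits
(`IgG 1.8 mg/mL`). Spans tile their section; whitespace-only fragments are
absorbed into the preceding sentence.

Concept extraction is dictionary lookup: each PAC-relevant concept has a
list of case-insensitive literal surface forms in a YAML lexicon
(`inst/extdata/pac_lexicon.yaml`). Matching is longest-match-per-position
with consumption: at any position the longest matching surface form wins
and the text it covers is not re-matched, so *"sleep disturbance by
nocturnal cough and wheeze"* produces one nocturnal-symptoms mention rather
than also a cough and a wheeze mention. This is the standard behavior of
dictionary-lookup annotators and is what makes long composed phrases safe
to include. The published system's pattern inventory is not public; the
shipped lexicon covers every criterion concept with three to eight surface
variants and is deliberately user-replaceable, so equivalence claims attach
to this rule set, not to the original system.

Assertion follows a NegEx-style scope-window rule: a negation trigger
(`denies`, `denied`, `no`, `not`, `without`, `negative for`) within five
tokens before the concept — with no intervening scope terminator (`but`,
`however`, `except`) — marks the mention negated; hypothetical triggers
(`if`, `should`, `return if`) in the same window mark it hypothetical.
Experiencer is resolved sentence-wide: a family trigger (`mother`,
`father`, `family history`, ...) anywhere in the sentence, or a
family-history section label, attributes the mention to someone other than
the patient. Only affirmed, patient-experienced mentions become evidence;
hypothetical mentions are discarded (a conservative choice — the
alternative of treating them as affirmed would credit instructions like
*"return if wheezing recurs"*). The five-token window is the classical
default for trigger-scope negation; widening it trades precision on long
coordinated lists for recall on distant triggers, and it is exposed as
`pac_config(negation_window =)`.

A physician-diagnosis concept is credited only from diagnosis-type sections
(`diagnosis`, `impression_assessment`, `plan` by default): the word
*asthma* in a narrative history ("history of asthma in childhood, per
mother") is weaker evidence than a diagnosis line, and the section
constraint is the rule-based expression of that. Symptom concepts are
credited from any section except family history.

## The rule engine

Evidence is cumulative and *sticky*: each condition, minor criterion, and
exclusion is assigned the first date at which the evidence so far satisfies
it, and once satisfied it stays satisfied (adding later records can only
move first-satisfaction dates earlier, never later — a monotonicity
property the tests check). Two consequences are worth noting:

* The nonsmoker criterion is satisfied on the first day the latest
  documented smoking status is `never` while the patient is at least 14
  years old; a later `current` entry does not revoke it. The alternative
  (instantaneous status) would make classification non-monotone in the
  record stream.
* Condition 1 combines primary concepts *across* notes: cough in January
  and wheezing in March complete the combination in March.

Numeric thresholds sit in `pac_config()` with the criteria's published
values: eosinophilia strictly `> 300` cells/µL (a count of exactly 300 does
not qualify); spirometry low `< 70 %` predicted, improvement `>= 20 %`
(inclusive — "at least"), improved FEV₁ `> 70 %`; methacholine decline
`>= 20 %` (inclusive); exclusion FEV₁ `< 50 %` predicted, required on at
least two measurements with none above it ("consistently"); IgG
`< 2.0` mg/mL. Where the criteria name no number, defaults were chosen once
and are configurable:

* *Elevated serum IgE* has no published cutoff; by default only an explicit
  `elevated` flag counts, and a numeric kU/L threshold can be supplied
  (`ige_threshold`).
* *Favorable bronchodilator response* accepts a textual mention or, when
  only numbers exist, a post-bronchodilator FEV₁ improvement of at least
  12 % (`bd_improvement_threshold`) — the conventional spirometric
  reversibility cutoff.
* *Foreign body at or about the incidence date* is unquantified; the
  default window is ±365 days around the candidate index date
  (`foreign_body_window_days`). The candidate index is computed first,
  ignoring exclusions, and the foreign-body exclusion then applies if any
  such mention falls in the window.
* Whether repeated symptoms must span multiple visits is unstated;
  `min_episodes` (default 1) can require the condition-1 symptoms to occupy
  at least *k* distinct dates.
* "Nonsmoker" means a latest documented status of `never`;
  `admit_former_smoker = TRUE` relaxes this.

Classification reads the definite rule's "and/or" as a true disjunction: a
physician diagnosis alone suffices. The index date is the minimum over
qualifying routes of the date each route completes: the first diagnosis
date; the later of conditions 1 and 2 (probable route); or the latest of
conditions 1, 2, and the second-earliest minor criterion
(definite-by-criteria route, which can never precede the probable route and
is included for auditability). Classification is evaluated as of the corpus
end date by default; `as_of` replays any historical cutoff, and
`replay_index()` walks every evidence date to produce the incident-case
view. Degenerate inputs are defined, not errors: a patient with no
mentions and no observations classifies as `none` with no index date.

The engine's closed-form date arithmetic is cross-checked in the test suite
against an independent brute-force oracle that replays the rule set from
scratch at every candidate date (boolean cumulative state, no date
algebra), on 1,000 randomly generated small evidence sets spanning
thresholds, smoking-status flips, under-14 timelines, and exclusions.

## Validation statistics

Criterion validity: exact 2×2 cross-tabulation against the reference
standard, unweighted Cohen's κ from the margin formula, agreement
(= accuracy), sensitivity, specificity, PPV, NPV. A zero denominator makes
a metric undefined (`NA`), never zero. For the degenerate one-category
table with perfect agreement κ is defined as 1. Construct validity:
cross-product odds ratios with Wald 95 % intervals
(`exp(ln OR ± 1.96·SE)`, `SE = sqrt(Σ 1/cell)`), identical to
single-covariate logistic estimates — the tests verify this equivalence
against `glm()` — with a Haldane–Anscombe +0.5 correction available behind
a flag for zero cells. No multiplicity adjustment is applied and the
confidence level is fixed at 95 %.

Display rounding is half-away-from-zero: integer percentages, one decimal
for odds ratios, two for κ. Raw full-precision values are always carried
alongside. A table whose specificity is 99.50 % therefore *displays* as
100 %; printed tables elsewhere may truncate such cells instead, which is
why comparisons should use the raw values.

## The synthetic corpus generator

`generate_corpus()` emulates the *evidence structure* the pipeline
assumes — multi-note patient timelines in which canonical sentences
instantiate criterion concepts, threshold-bearing values arrive as
observations straddling their boundaries (eosinophil counts both at and
above 300), excluded patients carry full case evidence plus one exclusion,
and distractors (negated symptoms, family-history mentions in running text
or a dedicated section, filler sentences) appear at configurable rates. The
ground-truth label and index date are derived analytically from the
planted events at generation time, and the generator asserts that the
derived label matches the sampled target, so a corpus is self-consistent by
construction. Non-cases may also carry *partial* evidence that can never
complete the criteria — a lone symptom, a lone variability sentence,
boundary laboratory values, an isolated atopic history — which exercises
the engine's conjunction logic and gives the construct-validity odds ratio
a realistic denominator.

Defaults encode the validation-cohort conditions this design mirrors: 5 %
prevalence, 2–4 notes per patient over 2001–2010, 60 % of cases definite,
a 2 % exclusion rate; the canonical test cohorts
(`canonical_corpus_config()`) fix 500 patients and seed 42, noise-free or
with all distractor rates at 0.3. Five hundred patients keeps the full
extract–classify–validate cycle in the tens of seconds while leaving the
binomial noise on recovery rates negligible.

What the generator does **not** emulate — and therefore what passing tests
do and do not show — matters: sentences are canonical templates with
limited paraphrase variety, so perfect recovery demonstrates correctness of
the assertion logic, the combination rules, and the date arithmetic, *not*
lexical coverage of real clinical prose; there is no misspelling, no
copy-forward duplication, no documentation bias between provider types, no
conflicting evidence, and no temporal expressions beyond the note date.
Real-world performance is bounded by lexicon coverage and must be
established against chart review in each deployment, exactly as the
underlying validation design does.

`perturb_negate_all()` rewrites every canonical affirmed evidence sentence
with its negated counterpart (idempotently) and relabels affected patients
to `none`; the pipeline must then predict zero asthma. This is the
end-to-end demonstration that assertion status, not phrase spotting, drives
classification.

## Known limitations

* Dictionary extraction cannot find concepts phrased outside the lexicon;
  the lexicon is a configuration file precisely so sites can extend it.
* Negation scope is a token window: long coordinated negated lists
  ("denies cough, fever, chills, night sweats, and wheezing") can exceed
  the window and leave late conjuncts affirmed.
* Evidence is day-granular and monotone; asthma remission and relapse
  dating are out of scope.
* The structured-observation path assumes observations arrive already
  normalized to the supported kinds and units; unit conversion is the
  caller's responsibility.
* Construct-validity odds ratios are univariable by design; adjusted or
  continuous-covariate models are out of scope.
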