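---
title: "Scoring, screening and prioritizing NMP toxicity studies with tsat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, screening and prioritizing NMP toxicity studies with tsat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsat)
```

## The problem

Risk assessors evaluating the human-health implications of nano- and
microplastic particles (NMPs) face a fast-growing literature of
non-standard in vivo and in vitro effect studies. Before any
toxicological interpretation, each study has to be appraised for its
quality assurance / quality control (QA/QC) reporting: how well the test
particles were characterized, how the experiment was designed, and
whether the data are usable in a quantitative risk assessment at all.
`tsat` implements that Tier-1 appraisal as a reusable toolkit: a
configurable criteria registry, multi-rater 0/1/2 scoring with
consensus, total-assessment-score (TAS) aggregation, three screening
schemes, and corpus-level analytics. Tier-2 — expert elicitation on the
prioritized studies — is out of scope; this package only decides which
studies get there.

## The rubric

A registry holds an ordered list of criteria in three assessment areas:

* **particle characterization** (8 criteria in both shipped rubrics):
  size, shape, polymer type, source, surface chemistry, chemical
  purity, microbial contamination, production/cleaning;
* **study design** (13 in vivo / 11 in vitro): test system and its
  husbandry or culture, dosing, vehicle, dose metric, homogeneity and
  stability of the suspension, exposure schedule, controls and — in
  vivo — verification of the delivered dose;
* **applicability for risk assessment** (5 / 4): endpoints,
  dose-response design, effect-threshold reporting (in vivo only),
  statistics, environmental relevance.

Every criterion is scored 0 (inadequate), 1 (adequate with
restrictions) or 2 (adequate), all criteria carry equal weight, and the
TAS is the plain sum: maximum 52 for the 26 in vivo criteria and 46 for
the 23 in vitro criteria. The supplementary scoring-guidance tables of
the original tool are not distributed with it in machine-readable form,
so the shipped per-level guidance text is this package's own
reconstruction from the published method description; the criterion
roster, the category split and the 26/23 totals are fixed. Registries
are plain YAML or JSON, so a user can edit wording, add criteria, or
re-flag the red set without touching code.

A subset of criteria is flagged **red** (critical). The shipped red set
is the four particle-characterization criteria that any extrapolation
hinges on (size, shape, polymer, source) plus the risk-assessment
criteria for endpoints, dose-response and (in vivo) effect threshold.
Red flags mark criteria critical *for a given screening purpose* — they
are configuration, not a statement about intrinsic study quality.

## Scoring and consensus

Each study is evaluated by at least two raters. `consensus()` merges
their score maps under one of three rules:

* `min` (default) — per-criterion minimum. Conservative: a criterion is
  only credited at the level every rater would grant. Chosen as the
  default because the screening gate is itself a minimum-based rule.
* `mode` — per-criterion majority, ties broken to the lower level
  (again conservative).
* `strict` — any disagreement is an error; for audited workflows where
  raters must reconcile before scoring is accepted.

Whatever the rule, every discordant criterion is reported with the
per-rater levels, so reconciliation discussions have a worklist.
Inter-rater statistics (kappa and friends) are deliberately not
computed — with two or three raters per study they would be noise
dressed as signal.

`summarize_evaluation()` reports category subtotals, TAS, the integer
percent of maximum, the fraction of criteria at the maximum score, and
the number of zero-scored criteria. Percentages are rounded half away
from zero; that convention reproduces all published score/percent pairs
for the shipped rubrics (44/52 → 85, 37/52 → 71, 34/46 → 74, 12/52 →
23, 16/46 → 35). Mean TAS over a stratum is kept unrounded, and the
stratum's mean percent is computed from the unrounded mean — rounding
the mean first and converting afterwards can shift the percent by a
point.

## The three screening schemes

1. **Red-criteria Tier-1 gate** (`red_criteria_check()`,
   `tier1_screen()`): pass iff every red criterion scores at least
   `red_min_level` (default 1), regardless of TAS. This is the
   prioritization rule: a modest-TAS study that documents the critical
   items can still be worth expert review.
2. **Fernández-Cruz reliability classes**
   (`fernandez_cruz_class()`): *reliable* when the share of criteria at
   the maximum score exceeds 0.85 and the red criteria are met;
   *reliable with restrictions* in 0.61–0.85 with red criteria met;
   *not reliable* otherwise. The published wording is "> 85%",
   "61–85%" and "< 61%", so the upper cut-off is strict and the lower
   bound inclusive; a share of exactly 0.85 or 0.61 lands in the
   restricted class.
3. **de Ruijter adequacy** (`de_ruijter_adequate()`): adequate iff no
   criterion scores 0.

The classification basis is genuinely ambiguous in the field's usage:
the reliability cut-offs are phrased as "questions receiving the
maximum score", but the same discussions also reason in percent of the
TAS maximum (an all-ones study "scores 50% of the maximum"). Both
readings are implemented (`classification_config(basis =)`), with
`max_score_fraction` as the default since it follows the cut-offs'
literal wording. The two disagree exactly for studies with many 1s: all
ones is 50% of TAS but 0% of criteria at maximum — not reliable either
way, yet adequate under the all-nonzero rule. That tension between the
schemes is a feature of the method, not a bug in the package, and is
why all three results are reported side by side.

With `red_min_level = 1` the schemes nest: de Ruijter adequacy implies
the red gate (all-nonzero includes the red subset), and any reliability
class other than *not reliable* requires the red gate by definition.
The test suite asserts this implication chain on randomized inputs.

## Synthetic corpora

`generate_fixture()` builds corpora with known properties from a
`fixture_spec()`: per-study target TAS, a red-pass constraint, the
number of raters and a rater-noise level, all under one integer seed.
Scores are drawn by seeded composition: start every criterion at its
floor (red criteria at the required minimum when the study must pass
the gate, 0 otherwise) and add unit increments at uniformly chosen
criteria with headroom until the target is reached. Since each
increment is +1 and capacity is 2 per criterion, every target in the
feasible band is hit exactly; infeasible targets are rejected with the
feasible range in the message.

Rater sheets are derived from the composed scores: rater 1 carries them
verbatim, and each further rater independently bumps a criterion one
level up with probability `rater_noise` (default 0.1, a deviation on
roughly every tenth criterion — about the density of disagreements a
two-rater review of a well-specified rubric produces). Deviations are
upward-only by design: the minimum-rule consensus is then guaranteed to
recover the composed scores, so the consensus TAS equals the target
exactly and the red constraint survives merging. Symmetric noise would
break that exactness; if both directions matter for a simulation, apply
the generator twice with swapped roles instead.

The generator reproduces the *structure* of a screening exercise — TAS
targets, red-pass composition, rater discordance — not real studies:
scores are exchangeable across non-red criteria, whereas real corpora
concentrate zeros in specific criteria (surface chemistry, purity,
endotoxin testing are notoriously under-reported). Passing tests on
fixtures therefore validates the arithmetic and the schemes, not any
empirical claim about the literature. `demo_corpus_spec()` ships a
15-study in vivo demonstration corpus of red-passing oral and
inhalation studies with consensus TAS values spanning 23–44 — the
score profile of a Tier-1 prioritization — with two raters per study.

## Numerical and degenerate-input choices

* Percent rounding: half away from zero (`floor(100 * tas/max + 0.5)`
  for the non-negative domain), validated against the five published
  pairs above.
* Report ordering: prioritized studies first, TAS descending, study id
  ascending as the tie-break — a total order, so screening output is a
  permutation-invariant function of the corpus.
* Empty corpus: `criterion_distributions()` and `tier1_screen()` return
  zero-row tables; `corpus_summary()` errors, since league statistics
  of nothing are not meaningful.
* "Not applicable" levels are not part of the shipped rubrics — the
  fixed maxima 52/46 presuppose that every criterion always applies.
  Custom registries that need conditional applicability should drop the
  criterion rather than score it.
* Studies with both in vivo and in vitro arms are two independent
  evaluations keyed by `(study_id, study_system)`, each against its own
  registry; sheets may mix systems but screening runs per system.

## Problem sizes

The test suite exercises 500 random corpora of up to 5 studies for the
oracle-equivalence checks, 200 randomized evaluations for the
implication and monotonicity properties, and 400 random fixture specs
(half in the module tests, half in the acceptance checks) for TAS
recovery; the whole suite and the acceptance script each run in well
under two minutes on a single core. These sizes give every branch of
the schemes (gate pass/fail, all three classes, both bases) hundreds of
hits per run.

## Limitations

* The shipped guidance text is a reconstruction; users comparing
  results against an evaluation done with the original spreadsheet
  tool should load their own registry file rather than assume verbatim
  agreement of wording.
* The package validates and aggregates human-assigned scores; it does
  not read papers, and the advisory helpers
  (`suggest_dose_response_score()`, `particle_size_context()`) never
  overwrite a rater's judgement.
* No weighting schemes: all criteria are equal by construction, and the
  three schemes are implemented as published, without partial-credit
  variants.
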