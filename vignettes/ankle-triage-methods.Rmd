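---
title: "Methods: the ankle-triage rule engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ankle-triage rule engine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ankletriage)
```

## The procedure

`ankletriage` implements triage as a knowledge-based expert system: a
declarative rule base evaluated by forward chaining. The knowledge base is
a document (JSON canonically, YAML accepted) holding seven question
groups, 32 questions, five production rules with ten condition cases, and
recovery plans; the engine is generic over any document that passes
`validate_kb()`. Keeping the clinical content in data rather than code is
the central design commitment: the rules can be diffed, audited and
replaced without touching the engine.

Classification proceeds in three layers:

1. **Question findings.** Each answered question is mapped through its
   polarity to a clinical finding. Most questions are positive on "yes";
   the weight-bearing/balance question is positive on "no", because the
   Ottawa finding it probes is the *inability* to bear weight. The two
   body-metric questions derive their finding from BMI
   (weight / height², positive at or above the knowledge base's
   threshold). An unanswered question's finding is *unknown*.
2. **Group aggregates.** A group is `positive-present` as soon as one
   applicable question shows its finding (the "yes in any" aggregate
   short-circuits), `absent` only when every applicable question is
   answered and none is positive, and `undetermined` otherwise. The
   pregnancy questions are applicable only to female patients and
   auto-resolve to "no finding" otherwise.
3. **Rules.** Case conditions are trees of AND/OR over
   `any_positive`/`none_positive` leaves, evaluated in strong Kleene
   three-valued logic. R's native `&`, `|`, `!` over
   `TRUE`/`FALSE`/`NA` *are* the strong Kleene connectives, so the
   evaluator delegates the truth tables to the language. Kleene evaluation
   is sound with respect to completions: a definite value never changes
   when more questions are answered.

## The determinacy contract

Rules are evaluated in a severity priority (fracture before sprain before
no-injury, stored as data in `settings$rule_priority`), cases in their
published order, and the first case evaluating definitely true fires. The
engine reports `determined` only when, additionally, every
higher-priority case is definitely *false*. If a higher-priority case is
still unknown, the status is `needs-more-answers` even if some later case
is already true: otherwise a later answer could upgrade a reported sprain
to a fracture, which is precisely the retraction the contract forbids.
Under this rule, `determined` is equivalent to "the (rule, case) outcome
is invariant under every completion of the unanswered questions", which
the test suite checks by randomized completion. The severity ordering
itself is a design choice the audit makes necessary: 19 of the 64
group-finding assignments satisfy more than one rule case, and a triage
tool should resolve such ties toward the worse diagnosis rather than
under-triage a possible fracture.

Question sequencing (`next_question()`) follows the questionnaire's group
order, but skips any group that no still-resolvable rule case references
with an unknown leaf. This is observable behavior: once the
contraindication screen G1 is positive, no surviving case mentions G2, so
the Ottawa palpation questions are never asked.

## Strict versus compatibility mode

The two shipped case studies expose an internal inconsistency in the
published rule table: the sprain patient answers "yes" to the G1
neurological red-flag question, which under the literal table semantics
makes G1 positive and fires fracture Case 2, yet the published
classification is sprain Case 1. The only reading we found that reproduces
the published row is to exclude that one question from the G1 aggregate
and surface it separately. Both behaviors are first-class:

* **strict** (default): the table as printed; the sprain case study
  classifies as fracture Case 2.
* **compatibility**: the flag `exclude_G1_Q6_from_aggregate` is enabled,
  G1.Q6 becomes a red-flag annotation, and the published sprain Case 1 is
  reproduced.

Every classification and report is stamped with the mode that produced
it, and both behaviors are pinned as regression tests. Strict is the
default because silently reproducing an inconsistent row would hide the
discrepancy from exactly the users who need to know about it.

## Tunable parameters

| parameter | default | units | notes |
|---|---|---|---|
| `bmi_elevated_threshold` | 25.0 | kg/m² | WHO overweight cut-off; the source material says only "elevated". Comparison is inclusive (≥), fixed for determinism; the boundary direction is otherwise arbitrary. |
| `rule_priority` | 1, 2, 3 | — | severity-first conflict resolution (see above) |
| `compatibility_flags` | all off | — | currently only `exclude_G1_Q6_from_aggregate` |
| `outcome_paths` | fracture→visit-clinician, sprain→home-care, none→no-action | — | the outcome→path mapping is data; the clinician branch is the one described with x-ray/cast procedures, the home branch with rest and exercises |

## Recovery plans

The Weber A plan is specified: 6 weeks healing in a cast, residual pain
and swelling for up to 6 months, with phased rehabilitation. Weber B is
described only as following the Weber A course, so it is stored with the
same timeline and `provisional = TRUE`; callers must surface that flag.
The sprain plan's published details live in supplementary material not
reproduced here, so it ships minimal — 2 weeks of protected rest with a
1-month residual horizon, also provisional — which is a typical
lateral-sprain home-care schedule rather than a sourced one.

## The synthetic cohort generator

`generate_cohort()` samples complete questionnaires at the *finding*
level: each boolean question shows its positive finding with probability
`positive_prob` (default 0.15, a mid-range symptom prevalence chosen once
for test realism), overridable per question; findings are translated to
yes/no answers through each question's polarity. Sex is female with
probability 0.5; pregnancy questions are sampled only for female records.
One body is sampled per patient — height ~ N(170, 10) cm and a BMI placed
below or at-and-above the threshold with probability
`bmi_elevated_prob` — and drives both body-metric questions, so the two
BMI findings are always consistent. Sampling runs in an isolated RNG
stream: the caller's `.Random.seed` is saved and restored, and identical
(seed, config) pairs reproduce identical cohorts byte for byte.

What the generator emulates is the *logical* surface of real intake data:
complete, polarity-consistent questionnaires with controllable marginal
finding rates. It makes no epidemiological claims — findings are sampled
independently, with no symptom correlations, no age structure, and no
relation between BMI and the boolean findings. Tests passing on these
cohorts therefore demonstrate engine correctness (aggregation, polarity,
priority, determinism), not clinical performance on real patients.

## The audit as oracle

`audit_rules()` enumerates all 64 positive/absent assignments over the six
diagnostic groups and evaluates every case condition by plain two-valued
recursion — a code path deliberately independent of the Kleene engine. The
audit works at group level because every rule condition factors through
the group aggregates; the raw answer space (2³²) would add nothing.
Derived once and pinned: the packaged base has **0 gaps** and **19
overlaps**. The engine is then required to agree with the
priority-resolved oracle on all 64 assignments, via `canonical_answers()`,
which deterministically realizes any assignment as a complete
questionnaire (positive groups by their first question, absent groups by
all non-finding answers — including "yes" on the balance question — and
body metrics fixed below the BMI threshold).

## Numerical and degenerate-input choices

* BMI requires both metrics; with either absent the body-metric finding is
  unknown, which can leave a group undetermined but never blocks a
  short-circuiting positive.
* Pain-score logging accepts integers 0–10, rejects everything else, and
  requires strictly increasing timestamps; the trend summary is
  descriptive only (latest, mean, OLS slope via `stats::lm`), since no
  predictive pain model is specified in the source material; the slope is
  `NA` below two reports.
* A complete answer set that fires no diagnostic rule raises an error
  rather than returning a value — it is impossible under the audited
  packaged base and indicates a gapped custom base.
* `cohort_config()` rejects probabilities outside [0, 1] and n < 1.

## Problem sizes

The test suite and the acceptance script run exhaustively where the space
is small (64 assignments, 128 contraindication vectors) and by seeded
randomization elsewhere (200 partial questionnaires for the determinacy
property, cohorts of 100). These sizes make the enumerable checks total
and keep the whole suite interactive — a few tens of seconds on one CPU.

## Known limitations

* The engine reproduces the published rule semantics as-is, including
  clinically odd corners: a single lifestyle finding (e.g. smoking) alone
  satisfies "yes in any of G3-A or G3-B", and a fully examined patient
  with isolated fracture signs but clean G1/G2/G4 screens resolves to
  "no injury" under Rule 3 Case 1. The audit makes such corners visible;
  it does not repair them.
* Outcomes are categorical labels; there is no probabilistic scoring,
  no imaging input, and no persistence or messaging layer.
* TENS intensity is an opaque ordinal: no published quantification of
  levels or adjustment policy exists to encode.
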