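# ankletriage

A rule-based clinical decision-support engine for first-line triage of
ankle injuries. Ankle sprains and fractures are among the most common
musculoskeletal presentations, and the first decision — send the patient
for radiography and casting, or manage at home — is routinely made from a
structured symptom interview. `ankletriage` packages that interview as a
declarative knowledge base and a small, auditable inference engine, aimed
at people building or studying telemedicine triage tools: the rules are
data, the engine is generic, and the whole rule space can be enumerated and
verified.

## The model

The knowledge base is a set of IF–THEN production rules over **question
groups** drawn from an Ottawa-Ankle-Rules-style questionnaire:

| group | content |
|---|---|
| G1 | contraindications to the Ottawa assessment (age < 18, intoxication, multiple injuries, pregnancy, head injury, neurological red flags) |
| G2 | the Ottawa findings themselves (malleolar tenderness, midfoot tenderness, inability to bear weight) |
| G3-A / G3-B | fracture signs (pain, swelling, deformity; skin changes, absent pulse, osteoporosis, smoking, elevated BMI, ecchymosis) |
| G4-A / G4-B | sprain signs (twisting injury, painful swelling, bruising; walking difficulty, stiffness, elevated BMI) |
| G5 | TENS/cast contraindications (heart disease, pregnancy, seizures, epilepsy, lymphedema, blood clots) |

Each rule case is a conjunction of group aggregates — `any_positive(g)`
("yes in any of g") or `none_positive(g)` ("no in all g") — for example the
first fracture case is

```
(no in all G1) AND (yes in any of G2) AND (yes in any of G3-A or G3-B)
```

Question **polarity** is explicit: for most questions a "yes" is the
positive clinical finding, but for the weight-bearing question ("Are you
able to balance when you walk four steps?") the positive Ottawa finding is
the *inability* to bear weight, i.e. the answer "no". Two questions are
body-metric: BMI = weight / height², positive when at or above a
configurable threshold (default 25 kg/m²).

Partial questionnaires are evaluated in **strong Kleene three-valued
logic** (true / false / unknown). A group with one positive answer is
positive regardless of what is still unanswered; a group is negative only
when fully answered. Classification forward-chains through the diagnostic
rules in severity order (fracture > sprain > no injury) and reports
`determined` only when the fired case is true *and* every higher-priority
case is definitely false — so a determined triage result can never be
retracted by answering more questions.

The audit module enumerates all 2⁶ = 64 assignments of positive/absent to
the six diagnostic groups, evaluates every rule case by brute force
independently of the engine, and reports **gaps** (assignments no rule
covers — the packaged base has none) and **overlaps** (assignments several
rules claim — there are 19, which is why the severity priority exists).

## Worked example

The package ships two patient answer files transcribed from published case
studies. Classifying the fracture case:

```r
library(ankletriage)
kb <- ankle_kb()
patient <- read_answers(system.file("extdata", "case_fracture.json",
                                    package = "ankletriage"))[[1]]
(cls <- classify(kb, patient))
#> <classification> mode=strict kb=v1.0
#>   Rule 1: Case 1 -> High possibility of ankle fracture
elig <- tens_eligibility(kb, patient)   # "undetermined": G5 not yet asked
recommend_path(kb, cls, elig)
#> <triage_recommendation> path=visit-clinician tens_allowed=undetermined
#>   High possibility of ankle fracture. Visit a clinician for assessment
#>   (x-ray, cast application and supervised TENS therapy as indicated).
#>   Cast/TENS eligibility is not yet determined.
get_recovery_plan(kb, "weber-a")
#> <recovery_plan weber-a>
#>   healing: 6 weeks; residual symptoms up to 6 months
#>   ...
audit_rules(kb)
#> <audit_report> 64 assignments enumerated
#>   gaps: 0
#>   overlaps: 19
```

Rule 1 Case 1 fires because the contraindication screen (G1) is clean, the
Ottawa findings (G2) are positive, and fracture signs (G3-A) are present —
even though the sprain groups were never asked: the result is already
invariant under any answers to them.

The sprain case study is the interesting one: its answers mark the G1
neurological red-flag question positive, which under the table's literal
semantics fires fracture Case 2, while its published classification is
sprain Case 1. Strict mode (the default) follows the literal semantics;
`mode = "compatibility"` excludes that question from the G1 aggregate
(reporting it as a red flag instead) and reproduces the published row.
Every report is stamped with the mode that produced it.

A command-line front end wraps the same functions:

```sh
Rscript exec/ankletriage classify --answers inst/extdata/case_sprain.json --mode compatibility
Rscript exec/ankletriage audit            # exits nonzero if the rule base has gaps
Rscript exec/ankletriage simulate --seed 7 --n 100 --out cohort.csv
```

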