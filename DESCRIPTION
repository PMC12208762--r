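Package: ankletriage
Title: Rule-Based Expert System for Ankle Injury Triage
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A declarative clinical knowledge base and tri-state
    forward-chaining inference engine for first-line triage of ankle
    injuries. Encodes an Ottawa-Ankle-Rules-derived question set, IF-THEN
    production rules distinguishing likely fracture, likely sprain and no
    injury, and contraindication screening for transcutaneous electrical
    nerve stimulation (TENS) and cast use. Partial questionnaires are
    evaluated with strong Kleene three-valued logic so a classification is
    only reported when no completion of the unanswered questions could
    change it. Includes a brute-force audit of rule-base completeness and
    overlap, a seeded synthetic-cohort generator, recovery-plan and triage
    path recommendation, pain-report logging, and a scriptable command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
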