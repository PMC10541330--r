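Package: hrfph
Title: Severity Scoring for Hypoxemic Respiratory Failure and Pulmonary
    Hypertension of the Newborn
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calculator and cohort-analysis toolkit for a combined hypoxemic
    respiratory failure / pulmonary hypertension (HRF/PH) severity score in
    neonates with persistent pulmonary hypertension of the newborn (PPHN).
    Computes the oxygenation index (OI) and oxygen saturation index (OSI),
    a 0-5 oxygenation sub-score from respiratory support at the time of the
    first echocardiogram, a 0-10 echocardiographic sub-score from septal
    position, TAPSE, Bernoulli-estimated right ventricular systolic pressure
    and right ventricular dysfunction, and the composite 0-15 score with
    mild/moderate/severe categories, plus the vasoactive-inotropic score.
    Includes exact contingency-table tests (hypergeometric 2x2 and
    Freeman-Halton r x c enumeration), linear regression with
    heteroskedasticity-consistent standard errors, a deterministic fixture
    cohort reconstructed from published category-level outcome counts, a
    stochastic patient-cohort simulator, CSV patient-record I/O with a
    versioned threshold configuration, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
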