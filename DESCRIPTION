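Package: reducerHTA
Title: Budget Impact and Cost-Utility Modelling of the Coronary Sinus
    Reducer in Refractory Angina
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decision-analytic models for evaluating the coronary sinus
    reducer against standard of care in refractory angina from a national
    payer perspective. Provides a five-year budget impact model built on a
    patient eligibility funnel and two market-mix scenarios, a
    success/failure decision-tree cost-utility model with annual cycles,
    discounting and ICER/dominance classification, one-way (tornado) and
    probabilistic (Monte Carlo) sensitivity analyses on the
    cost-effectiveness plane with acceptability curves, and a synthetic
    patient-level cohort generator with parameter-recovery estimators for
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    survival,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
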