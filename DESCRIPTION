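Package: shieldtext
Title: Automated COVID-19 Shielding Risk Stratification from Rheumatology Outpatient Letters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based text mining of semistructured rheumatology outpatient
    letters to apply the British Society for Rheumatology (BSR) COVID-19
    shielding criteria. Parses headed letter sections, maps free-text
    diagnoses to a small hierarchical terminology and rolls them up to
    comorbidity categories, extracts medications with class, dose, duration,
    temporal anchor and active/past/planned status, consolidates the two most
    recent letters per patient at an index date, scores patients with a
    configurable rule table (numerical scoring grid or non-numerical
    risk-stratification guide), and evaluates predictions against a gold
    standard with standard diagnostic-accuracy metrics. Includes a synthetic
    letter-corpus generator with an independent scoring oracle so the whole
    pipeline is testable without access to real patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
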