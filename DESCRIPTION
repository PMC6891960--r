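Package: insulinCEA
Title: Short-Term Cost-Utility Analysis of Basal Insulins via Hypoglycaemia
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and probabilistic cost-utility modelling of
    insulin degludec versus biosimilar insulin glargine U100 over a one-year
    horizon, for three diabetes patient groups (type 1 basal-bolus, type 2
    basal-oral, type 2 basal-bolus). Annual costs cover insulin acquisition
    and treated hypoglycaemic events (daytime non-severe, nocturnal
    non-severe, severe); effectiveness is measured in quality-adjusted life
    years accumulated as a baseline utility minus per-event disutilities,
    plus a flexible-dosing utility gain for degludec. Includes linear
    back-calibration of unpublished unit parameters (insulin unit prices,
    per-event costs, disutilities, baseline utilities) from the published
    aggregate cost and QALY tables, a one-way scenario engine with
    tornado-style sweeps, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves and net monetary benefit, and a
    synthetic parameter-set generator with closed-form incremental
    cost-effectiveness ratios for end-to-end verification.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
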