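Package: melmark
Title: Dynamic Markov Modelling of Melanoma Incidence, Detection and Mortality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A time-inhomogeneous eight-state Markov cohort model of melanoma
    epidemiology in a closed population, calibrated to annual diagnostic
    incidence and mortality rates (per 100,000) of the kind published by
    national cancer registries. The package generates emulated registry
    series from printed anchor values, calibrates a 1982 steady state,
    grid-fits the time course of the intrinsic incidence, and quantifies
    counterfactual secondary-prevention (early detection), tertiary-prevention
    (late-stage survival) and over-diagnosis scenarios both retrospectively
    (1982-2013) and prospectively (2014-2028), together with one-at-a-time
    Monte-Carlo parameter sensitivity and screening-economics arithmetic
    (number needed to screen, cost per life saved).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
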