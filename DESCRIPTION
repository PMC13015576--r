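Package: s1switch
Title: Cost-Effectiveness of Switching to S-1-Based Chemotherapy After
    Fluoropyrimidine Toxicity in Metastatic Colorectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A five-state weekly Markov cohort model for the
    cost-effectiveness of switching to S-1-based chemotherapy after
    hand-foot syndrome or cardiovascular toxicity on capecitabine or
    intravenous 5-FU in metastatic colorectal cancer. Provides
    Weibull-parameterised survival extrapolation, per-regimen cost
    arithmetic, probabilistic sensitivity analysis, ICER and dominance
    frontier construction, net-monetary-benefit acceptability curves,
    and a synthetic-trial module that simulates individual-patient
    survival data and refits parametric survival models by censored
    maximum likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    MASS,
    survival,
    flexsurv
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
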