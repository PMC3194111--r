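Package: radonrisk
Title: Cumulative Lifetime Lung-Cancer Risk from Residential Radon with
    Smoking Effect Modification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links three regression models -- a four-level log-linear model of
    indoor radon concentration, a multinomial logistic model of house type, and
    a multilevel logistic model of ever-smoking -- into an explicit lifetime
    fatal lung-cancer risk algorithm for demographic bins (county by age by sex
    by race by poverty cells), with population-weighted aggregation to county,
    state and national averages. Ships the published coefficient tables as
    data, refits each model on synthetic data for parameter recovery, and
    provides seed-deterministic generators for every input so the whole chain
    is testable without restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    lme4,
    nnet,
    pbkrtest,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
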