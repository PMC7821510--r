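Package: pfif
Title: Acoustic 3D Tracking of Bats at Lit Forest Edges and
    Distance-Response Models of Flight Paths
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study how streetlight proximity and light spectrum
    change bat flight paths at forest edges. Simulates bat flight
    trajectories and echolocation-call arrival times at a four-microphone
    array, localizes calls in 3D by time-difference-of-arrival
    multilateration with propagation of per-axis position imprecision,
    links positions into individual trajectories, labels each position by
    its distance to the light and by habitat (inside forest versus open),
    and fits precision-weighted binomial mixed models of the Probability
    of Flying Inside the Forest (PFIF) with trajectory- and night-level
    random intercepts. From a fitted model it derives the Flight-Path
    Switch Distance (the distance to the light at which the predicted
    PFIF equals one half), a perturbation-onset distance, and per-spectrum
    prediction curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmmTMB,
    jsonlite,
    readr,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    mclust,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
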