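Package: lgoTMZ
Title: Tumor Growth Modelling and In-Silico Trials for Temozolomide
    Treatment of Low-Grade Oligodendroglioma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-compartment ordinary differential equation model of
    WHO grade II oligodendroglioma response to temozolomide (TMZ) with
    impulsive dosing: proliferative tumor volume grows logistically and
    is moved by the drug into a lethally damaged compartment that dies
    through mitotic catastrophe. The package integrates the model with
    event handling for dose impulses, fits patient-specific parameters
    to longitudinal volumetric data, builds the standard, long-cycle,
    distributed-dose and induction-plus-maintenance ("5+12") TMZ
    schedules, simulates time to a lethal volume threshold, runs paired
    virtual clinical trials with Kaplan-Meier, log-rank and Cox
    proportional-hazards analysis, and performs trial-size power sweeps.
    A synthetic-cohort generator emulates clinical volumetric follow-up
    with multiplicative measurement noise for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    survival,
    lhs,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
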