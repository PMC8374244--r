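Package: villagesim
Title: Daily-Timestep Agent-Based Simulation of a Himalayan Smallholder Village
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An empirically parameterised, daily-timestep agent-based
    simulator of a small Nepalese Mid-Hills smallholder village.  Generates a
    synthetic household-structured population, simulates life-course
    demography (education, careers, marriage, birth, death), crop and
    livestock economics, household finances with informal credit, and
    stressor scenarios (the 2015 earthquake, alternative fertility rates,
    heightened crop-yield variability).  Includes replicate-count coefficient
    of variation analysis, grouped one-at-a-time sensitivity analysis with
    Mann-Whitney testing, per-run CSV logging, and summary statistics
    including the village Gini index.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
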