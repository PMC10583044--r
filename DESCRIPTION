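Package: pmslt
Title: Proportional Multistate Life Table Modelling of Trans Fat Policy
    Cost-Effectiveness
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multiple-cohort proportional multistate life table (PMSLT)
    model for estimating the health gains, healthcare costs and
    cost-effectiveness of eliminating industrial trans fatty acids (iTFA)
    from a national food supply.  Exposure-shift potential impact
    fractions (continuous distribution-shift method) drive an ischaemic
    heart disease illness-death submodel inside sex- and age-specific
    cohort life tables, producing averted events and deaths,
    health-adjusted life years, healthcare and policy implementation cost
    streams, net costs, incremental cost-effectiveness ratios and Monte
    Carlo uncertainty intervals.  Includes a synthetic input generator
    emulating the statistical structure of Global Burden of Disease style
    inputs so every stage runs without external data.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
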