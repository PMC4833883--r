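Package: rcindex
Title: Relative Competition Intensity from Biogeographic Competition Experiments
Version: 0.1.0
Authors@R: person("rcindex", "maintainers", email = "maintainers@rcindex.invalid",
    role = c("aut", "cre"))
Description: Tools for analysing glasshouse competition experiments that
    compare native and introduced plant provenances grown in live soil
    inocula. Builds the factorial pot design (species x provenance x soil
    site, single- and paired-plant treatments), simulates plant-level growth
    data from a log-normal mixed model with soil-site random effects, a
    nodulation covariate and competition effects parameterised by true
    relative competition intensity (RCI) values, fits no-intercept cell-means
    mixed models to log growth rates, propagates fixed-effect uncertainty by
    Monte-Carlo simulation into RCI indices and between-provenance RCI
    contrasts with 50% and 95% intervals, and relates growth-rate differences
    to competitive-ability differences by Pearson correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    lme4,
    MASS,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
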