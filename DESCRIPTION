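Package: XLinkRisk
Title: X Chromosome-Mediated Familial Risk from Sex-by-Lineage Proband Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates the share of familial disease risk mediated by the X
    chromosome from counts of affected probands cross-classified by proband
    sex and unilateral parental lineage. A female proband can inherit
    lineage-borne genetic risk through the 22 autosomes or the X chromosome
    from either parental side, whereas a male proband can receive X-borne
    risk only from the maternal side; the odds ratio of the resulting 2x2
    table therefore isolates the X-borne component, and (OR-1)/OR x 100%
    estimates the proportion of lineage-transmitted genetic risk residing on
    the X chromosome. The package provides the transmission-channel logic,
    the Wald log-odds-ratio interval and test, cohort-standardized
    observed/expected familial relative risks with exact Poisson (Garwood)
    confidence intervals, a synthetic-population generator with
    multiplicative autosomal/X/Y risk components for bias and coverage
    experiments, and report-generating pipeline drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, jsonlite, yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Epidemiology, StatisticalMethod, GeneticVariability
RoxygenNote: 7.3.3
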