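Package: nonchron
Title: Growth Curve Set Estimation from Nonchronological Size-Age Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maximum-likelihood estimation of anamorphic and polymorphic
    growth curve sets from nonchronological (one observation per
    individual) size-age data. The observable size distribution at each
    age is derived from the distribution of asymptotes and the geometry
    of the growth curve set by a change of variables, so both anamorphic
    sets (one standard curve scaled by the asymptote) and polymorphic
    sets (curve shape covarying with the asymptote through a rate term
    k*A^l) can be fitted by profile maximum likelihood. Includes
    lognormal and generalized gamma asymptote distributions, particle
    swarm optimization for the outer curve-parameter search, AIC and
    likelihood-ratio model comparison, empirical bootstrap confidence
    intervals, percentile growth curves, and a synthetic-data harness
    for parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
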