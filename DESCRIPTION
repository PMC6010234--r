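Package: freesat
Title: Saturation, Salience, and Domain Size for Free-List Interview Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing open-ended "free list" interview data:
    reading and normalising ordered multi-response lists, per-item salience
    scoring (prevalence, Smith, and Sutrop indices), new-item accumulation
    curves, thematic-saturation modelling with count GLMs (normal, Poisson,
    negative binomial) selected by AIC, domain-size estimation by geometric
    extrapolation and by closed-population capture-recapture with item
    (salience) heterogeneity, list-truncation experiments comparing limited
    probing to exhaustive listing, binomial design calculators for sample
    size planning, and a synthetic free-list generator with known domain
    size and salience heterogeneity for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
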