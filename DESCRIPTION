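Package: ethnoindices
Title: Quantitative Ethnobotany Indices, Survey Design and Preference Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ethnopharmacological surveys of medicinal
    plant use. Implements finite-population sample-size determination, a
    long-format informant use-report data model with CSV I/O, the five
    standard ethnobotanical indices (use value UV, relative frequency of
    citation RFC, relative importance RI, cultural importance CII and
    cultural value CVI) with species ranking, Nussbaum-capability
    enabler/barrier perception tallies, variance-inflation-factor screening
    and a binary logistic regression of herbal-versus-allopathy preference
    fitted by iteratively reweighted least squares, plus a seeded synthetic
    survey generator so the whole pipeline runs without field data. Ships a
    digitized citation table for 51 medicinal species from a published
    survey of 145 informants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
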