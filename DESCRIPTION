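Package: skintrace
Title: Forensic Skin-Microbiota Matching, Diurnal Variation and Dispersal
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for distance-based forensic matching of surface
    microbiota to skin references, with accuracy accounting across
    sampling delay and time of day; detection of diurnally varying
    species by additive time-series decomposition, a seasonality-strength
    statistic and a permutation null, with negative-control and
    compositional robustness re-analyses; and lag-1 dynamic Bayesian
    network inference of microbial dispersal routes between skin,
    household and public surface sites. Includes a synthetic community
    generator that emulates a twice-daily, multi-location sampling design
    with person-specific signature taxa, planted diurnal species and
    public-to-skin dispersal coupling, for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
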