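Package: descurve
Title: Estimating Undescribed Species Richness from Description Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the total and remaining-undescribed number
    of species in a taxon from historical species-description records.
    Implements a Poisson pool-depletion model in which the number of species
    described per time interval is proportional to taxonomic effort (number
    of active taxonomists), the remaining undescribed pool, and an
    exponentially increasing taxonomic efficiency, fitted by maximum
    likelihood with Wald confidence intervals.  Includes a Gaussian
    comparator with linear efficiency, a Gillespie direct-method simulator
    of the description process (with optional gamma-distributed efficiency
    noise), a simulation-study harness for estimator bias and interval
    coverage, per-realm batch fitting, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
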