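Package: cloudclim
Title: Cloud-Frequency Climatologies and Cloud-Driven Species Distribution Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives fine-grain cloud-cover climatologies from daily binary
    cloud-flag rasters (monthly cloud frequencies, sensor merging, oriented
    stripe-artifact removal, albedo gap-filling, seasonal concentration and
    stability metrics, station validation) and fits the two downstream
    biodiversity models that such climatologies feed: a presence-only
    inhomogeneous point-process model via infinitely weighted logistic
    regression, and a Bayesian zero-inflated binomial occupancy model with
    imperfect detection fitted by Markov chain Monte Carlo. Includes a
    synthetic-data generator with known ground truth so the full pipeline is
    testable end to end, plus Moran's I, Geary's C and correlogram spatial
    autocorrelation diagnostics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
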