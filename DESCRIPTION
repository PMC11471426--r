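Package: nichecast
Title: Ensemble Climate-Niche Models and Range-Change Projection for Squamates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modeling species' fundamental climate-niche space from
    occurrence records and monthly climate surfaces, and for projecting how
    that space moves under alternative climate scenarios. Implements an
    occurrence quality-control pipeline (year window, distance-to-range,
    centroid-proximity and grid-cell deduplication filters), pseudo-absence
    sampling with repeated evaluation splits, a pluggable set of single-model
    techniques (logistic regression, random forest, a rectilinear surface
    range envelope, optionally a generalized additive model) scored by the
    true skill statistic, TSS-weighted ensembles with a TSS > 0.7 inclusion
    cutoff, sensitivity+specificity-maximizing binarization, pixel-level
    gain/loss/maintain accounting with expand/shift/contract/stable
    classification and centroid-shift metrics, stacked richness maps under
    no-dispersal and full-dispersal assumptions, and jurisdiction-level
    presence, turnover and elevation-shift summaries. A synthetic-data module
    generates autocorrelated monthly climate grids across six time-by-climate
    scenarios, virtual species with known niches, and occurrence sets with
    realistic quality defects, so the whole pipeline is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ranger
Suggests:
    mgcv,
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
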