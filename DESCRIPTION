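Package: falff
Title: Fractional Amplitude of Low-Frequency Fluctuations for Resting-State BOLD
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computes the amplitude of low-frequency fluctuations (ALFF) and its
    fractional variant (fALFF) from resting-state BOLD time series via one-sided
    periodograms, standardises fALFF maps against a reference region of interest,
    aggregates to regional means, matches hypertensive and normotensive cohorts by
    propensity score on age, sex and body-mass index, fits two-way analyses of
    covariance (group by region, with covariates) with partial eta-squared effect
    sizes and Bonferroni control, and performs noncentral-F power and sample-size
    analysis for the group-by-region interaction. A synthetic-data generator
    produces BOLD-like voxel time series with band-limited neuronal fluctuations,
    scanner drift, aliased cardiac and respiratory contamination, broadband CSF
    voxels and confounded cohorts, so that the full pipeline can be exercised with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    car,
    RNifti,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
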