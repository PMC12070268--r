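Package: nogowave
Title: Simulation and Oscillatory EEG Analysis for Go/Nogo Response-Inhibition Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse sensor- and source-level EEG from
    Go/Nogo perception-action binding experiments with two groups and two
    feature-overlap conditions. Provides generators for task schedules,
    behavioural outcomes and multichannel EEG epochs (1/f background plus
    band-limited oscillatory bursts), a deterministic preprocessing chain
    (resampling, IIR band-pass and notch filtering, average reference,
    artifact rejection, spherical-spline channel interpolation, baseline
    correction), Morlet wavelet time-frequency decomposition with band
    averaging, cluster-based permutation statistics over sensor and voxel
    adjacency structures, DICS beamforming from multitaper cross-spectral
    densities with DBSCAN peak localization and atlas masking, leave-one-out
    cluster-robustness statistics, and the behavioural statistics of a 2x2
    mixed design (mixed ANOVA with partial eta squared, Shapiro-Wilk-gated
    post hocs, rank-based tests with effect size r, sensitivity power
    analysis, and jackknifed Spearman correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr,
    zoo
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
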