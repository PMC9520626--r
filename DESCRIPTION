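Package: thetagamma
Title: Theta-Gamma Phase-Amplitude Coupling, Learning Curves, and
    Microglial Morphometry for Hippocampal Stimulation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis toolkit for quantifying treatment effects
    in rodent hippocampal recordings: detrending, zero-phase band-pass
    filtering and Welch band-power estimation of local field potentials;
    Hilbert phase/amplitude extraction, phase-binned amplitude
    distributions, the Tort modulation index and phase-amplitude
    comodulograms; sliding-window Y-maze learning curves with
    trials-to-criterion; microglial skeleton morphometry (thinning,
    branch/junction/endpoint counts, soma diameters, stained-area
    fraction); one-way ANOVA with homogeneity-gated LSD or Tamhane-T2
    post-hoc comparisons and Pearson correlation; and a seeded synthetic
    study generator with known ground truth so every stage is testable
    without animal data.
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
    igraph,
    jsonlite,
    png,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
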