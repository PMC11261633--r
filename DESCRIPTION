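Package: aismito
Title: Quantify Mitochondrial Distribution at the Axon Initial Segment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Image-analysis pipeline for quantifying the spatial distribution
    of punctate mitochondrial fluorescence in Drosophila mushroom-body
    neurons. Provides threshold-masked compartment intensity ratios
    (somatodendritic calyx versus axonal lobe), binned and max-normalized
    intensity profiles across the axon initial segment (AIS), the
    chord-enclosed "signal dropout" area statistic together with the
    integrated AIS intensity, replicate-collapsing group statistics
    (Kolmogorov-Smirnov normality gate, t / Mann-Whitney tests, two-way
    ANOVA with Sidak-adjusted contrasts), and a synthetic two-channel
    confocal-stack generator with ground truth so that every stage of the
    pipeline can be validated without real microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    yaml,
    mgcv,
    car,
    emmeans,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
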