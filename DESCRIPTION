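Package: rhythmbiome
Title: Circadian Rhythmicity Analysis of Quantitative Microbiome Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and comparison of circadian rhythms in 16S amplicon
    microbiome time series. Implements fixed-period cosinor and harmonic
    regression, the nonparametric JTK_CYCLE test with an exact
    Jonckheere-Terpstra null distribution, two-group differential
    rhythmicity classification (JTK followed by a DODR-style harmonic
    interaction test), spike-in based quantitative copy-number
    normalization, generalized UniFrac beta diversity with PERMANOVA,
    PCoA and Procrustes ordination comparison, and thresholded Spearman
    taxon-metabolite association. A synthetic-data generator emulates a
    two-group (control versus clock-deficient) repeated-measures study
    design with known ground truth for recovery testing, and a pipeline
    driver orchestrates a full reproducible run.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    tools,
    utils,
    vegan,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
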