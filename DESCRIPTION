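Package: mosaicR7
Title: Photoreceptor Mosaic Quantification and Regulatory Variant Analysis
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end toolkit for studying how a cis-regulatory indel
    shifts the stochastic ON/OFF ratio of the R7 photoreceptor mosaic in the
    fly retina. Provides automated two-channel retina image segmentation and
    ON/OFF counting (homomorphic denoising, Canny edges, convex-hull rough
    segmentation, active-contour refinement, marker-controlled watershed),
    hemizygosity cross simulation with a principal-component-adjusted linear
    association scan and max(T) permutation correction, canonical k-mer
    counting and binding-site affinity statistics for SELEX-seq style reads
    (McNemar read counts, frequency ranks, positional dependence, PWM
    construction and scoring), haplotype-based selection statistics (EHH,
    integrated EHH, a log2 iEHH-ratio IHS, Hudson FST with rank-normal
    Z scores), and preference-index statistics for two-choice phototaxis
    trials. A synthetic-data module generates every input with known ground
    truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    yaml,
    Biostrings,
    grDevices,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
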