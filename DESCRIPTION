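Package: sedmicro
Title: Eutrophication Indices, Community Assembly, and Microbial
    Life-History Traits for Benthic Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking coastal eutrophication to benthic microbial
    community assembly and life-history strategy. Computes the TRIX trophic
    index for overlying water and organic-nitrogen/organic-index pollution
    levels for sediments; alpha diversity, Levins niche breadth, Bray-Curtis
    dissimilarity, distance-decay regressions, mean pairwise phylogenetic
    distance and thresholded Spearman co-occurrence networks from OTU count
    tables; fits the Sloan neutral community model to occurrence-frequency
    data and runs the betaNTI / Raup-Crick (Bray-Curtis) null-model framework
    that partitions community assembly into five ecological processes; and
    estimates community-averaged life-history traits (genome equivalents,
    16S rRNA copy number, genome size, GC content, ENC'-based codon usage
    bias, predicted maximal growth rate, transposase content) from
    metagenome summaries. A synthetic-data module generates neutral and
    selection-structured metacommunities, regional water and sediment
    chemistry, and genome communities with known planted traits so that
    every estimator can be tested closed-loop.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vegan,
    withr
Suggests:
    optparse,
    picante,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
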