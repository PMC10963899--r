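Package: popgenescan
Title: Gene-Wise Population-Genetics Scans for Case/Control Resistance Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for gene-wise selection and
    differentiation scans on targeted-capture variant data from paired
    case/control (e.g. insecticide resistant/susceptible) cohorts. Reads and
    filters multi-sample VCFs, annotates SNP effects codon-aware from CDS
    models, and computes per-gene diversity and neutrality statistics
    (nucleotide diversity, Watterson's theta, Tajima's D with
    synonymous/nonsynonymous partitions, Fu & Li's D* and F*, a composite
    likelihood ratio against a background site-frequency spectrum, and
    Nei-Gojobori piN/piS), gene-wise and per-SNP Weir-Cockerham FST with
    bootstrap and per-chromosome quantile significance calls, a per-SNP
    allele-frequency likelihood-ratio test with false-discovery-rate control,
    and statistical-parsimony haplotype networks. A built-in Hudson coalescent
    simulator with demography, partial-sweep emulation and focal-SNP
    differentiation generates calibration nulls and complete synthetic
    targeted-capture datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    vcfR,
    igraph,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    withr
Config/testthat/edition: 3
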