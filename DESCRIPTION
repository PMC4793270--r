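Package: c3cseq
Title: Capture-3C Sequencing Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of capture-based chromosome conformation capture (Capture-3C)
    sequencing experiments targeting genomic risk loci. Builds EcoRI restriction maps
    and bait probe designs, filters and classifies aligned read pairs into per-bait
    contact profiles, corrects per-probe capture efficiency by median scaling with
    low-efficiency probe removal, masks bait-proximal self-ligation signal, and calls
    statistically significant cis-interactions with a permutation test that shuffles
    observed reads among mappable restriction fragments. Includes downstream
    quantifications (replicate reproducibility, 3C-qPCR contact frequency by the
    delta-delta-Ct method, eQTL linear regression, position-weight-matrix allele
    scoring, epigenomic track overlap) and a synthetic proximity-ligation read
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
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
    jsonlite,
    generics,
    stats,
    utils,
    Biostrings,
    BiocGenerics,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
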