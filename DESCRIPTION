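Package: snpgraph
Title: SNP-Aware Exact Read Alignment to Variation Graphs and Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds biallelic-SNP variation graphs from a reference genome and
    an SNP catalog, aligns reads to the graph exactly with a depth-limited,
    strand-directed seed-and-extend search, and genotypes SNPs from the
    allele-supporting alignments. Includes a GCSA2-style seed index contract
    (locate with id/offset/reverse-complement queries), GFA 1.0 and GAM-style
    JSON interchange, VCF input/output, a diploid read simulator for
    end-to-end testing, and precision/sensitivity/F-measure evaluation against
    a truth set.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    tools,
    utils,
    S4Vectors,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    jsonlite,
    ggplot2,
    generics,
    withr,
    Biostrings,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
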