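Package: finchmeiosis
Title: Germline Mutation and Meiotic Recombination from Multi-Sibling Pedigrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pedigree-based analysis of germline point mutation and meiotic
    recombination in birds with high nucleotide diversity, built around
    multi-sibling three-generation families. Detects and phases de novo
    mutations from trio genotype calls, calls crossovers and non-crossovers
    from phase switches at informative sites, and estimates fine-scale
    recombination parameters: GC-biased gene conversion, exponential
    conversion tract length by composite likelihood, Monte-Carlo detection
    power and power-corrected non-crossover totals, CpG-island enrichment by
    matched-window permutation, and a methylation-aware CpG-island hidden
    Markov model. Ships a fully deterministic synthetic-pedigree generator
    (founder haplotypes, recombining meioses, biased conversion, germline and
    post-zygotic mutations, site-level read counts) so that every stage of
    the pipeline is testable without sequencing data.
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
    IRanges,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
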