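Package: dartsex
Title: Sex-Linked Marker Discovery from DArT-Style Genotype Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovery of sex-specific and sex-linked loci from
    reduced-representation genotyping data (DArTseq-style SNP and
    SilicoDArT presence/absence markers). Implements marker quality
    filtering, threshold classification of loci under XX/XY and ZZ/ZW
    sex-determination hypotheses, locus informativeness statistics
    (Cochran-Armitage trend test, polymorphic information content,
    heterozygosity, pairwise Hamming distances), a spurious sex-linkage
    probability model, Monte Carlo subsampling reproducibility testing,
    chromosome assignment of candidate loci from alignment hits with
    sex-determining-region interval detection, and repeat-class
    composition summaries. Includes a synthetic-data generator with full
    ground truth so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
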