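Package: eldr
Title: Expression Level Dominance and Dosage Compensation in Triploid
    Hybrid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq of an allotriploid hybrid and
    its two diploid parents. Converts read counts to RPKM, performs pairwise
    two-library differential expression with exact tests (conditional
    binomial random-sampling model or Fisher's exact test) under
    Benjamini-Hochberg control, builds in-silico predicted triploid and
    predicted diploid expression levels to quantify dosage compensation,
    assigns each gene one of twelve expression-level-dominance /
    homoeolog-expression-bias categories (plus silencing and novel
    expression), tests gene subsets for category enrichment, and includes
    delta-delta-Ct arithmetic for qPCR validation as well as a
    negative-binomial simulator with planted category structure for
    end-to-end recovery benchmarking.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
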