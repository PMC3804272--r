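Package: barocomp
Title: Comparative Amino-Acid Composition of Barophilic and Nonbarophilic
    Proteomes by Structural Context and Domain Age
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares mean relative amino-acid abundances (MAA) between a
    barophilic (piezophilic) proteome and a nonbarophilic relative,
    stratified by protein structural context: whole sequences, regions of
    shared and species-specific SCOP fold-superfamily (FSF) domains,
    intervening (inter-domain) regions, and matched domains of homologous
    sequence pairs. Domain evolutionary ages are derived from node distances
    on a rooted FSF phylogenomic tree and converted to geological time with
    a linear molecular clock, allowing age-stratified (ancient vs recent)
    comparisons. Group differences are assessed per amino acid with Welch's
    two-sample t-test and summarised against a packaged barophily-rank
    reference. A synthetic-data module generates proteome pairs with planted
    substitution biases so every pipeline stage is verifiable by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
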