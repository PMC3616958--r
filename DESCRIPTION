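Package: pathqtl
Title: Pathway-Level Mapping of Copy-Number Alterations to Signaling-Pathway
    Expression
Version: 0.1.0
Authors@R:
    person("pathqtl", "developers", email = "pathqtl@example.org",
           role = c("aut", "cre"))
Description: Associates genomic copy-number alterations with the expression of
    whole signaling pathways rather than single genes. Pathways are summarised
    per disease sample by a log2 fold-change score over their GSEA leading-edge
    genes; correlated copy-number loci are reduced to representative tag-loci;
    each pathway score is then fitted as a non-linear function of tag-locus
    log2 copy-number alterations with a regression random forest, and the
    normalized permutation importance of every (tag-locus, pathway) pair is
    tested against a permutation null with a Z-test and Benjamini-Hochberg FDR
    control. Includes a synthetic-data generator with planted locus-to-pathway
    effects and recorded ground truth for calibration and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
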