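Package: kzfpcluster
Title: Evolutionary Analysis of KRAB Zinc Finger Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study the evolution of KRAB zinc finger protein (KZFP)
    gene clusters and their co-amplification with endogenous retroviruses
    (ERVs). Includes readers for the standard annotation formats (BED, GFF,
    RepeatMasker .out, PAF, narrowPeak), C2H2 zinc finger detection and
    recognition-helix fingerprint extraction for cross-assembly repertoire
    comparison, base-pair ratio transposable-element enrichment with
    permutation tests, divergence tie-group statistics that separate
    segmental duplication from independent retrotransposition, duplicated
    gene-block detection from 3' exon similarity, reference-guided contig
    curation, a KZFP-unit conservation census, and a stochastic simulator of
    cluster expansion by ERV insertion and non-allelic homologous
    recombination.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
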