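Package: epienrich
Title: Pairwise Epistasis Scanning and Gene-Set Enrichment for Case-Control GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-phase analysis of case-control genome-wide association data:
    exhaustive pairwise SNP interaction scanning with Multifactor Dimensionality
    Reduction (MDR) and permutation-based empirical p-values; window-based
    SNP-to-gene mapping with gene-level overabundance testing by right-tailed
    Fisher's exact test; and gene-set (e.g. Gene Ontology) enrichment with
    two-cohort replication at a fixed significance level. Includes a synthetic
    case-control GWAS generator that plants purely epistatic (minimal marginal
    effect) SNP pairs under Hardy-Weinberg genotype frequencies, together with
    matching gene annotations and gene sets, so the full cascade can be
    exercised and validated end to end. Readers and writers are provided for
    plain TSV genotype matrices, PLINK .raw/.bim/.map, BED gene annotations and
    GMT gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
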