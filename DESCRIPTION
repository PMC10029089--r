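Package: tp53allele
Title: Resolving TP53 Allelic Configuration from Variant Allele
    Frequencies in Myeloid Neoplasia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies TP53-mutated myeloid neoplasia cases into obligatory
    biallelic, probable biallelic and probable monoallelic allelic
    configurations from bulk variant allele frequencies (VAF) and del(17p)
    clonality, alongside the traditional single/double-hit scheme. Provides a
    survival-guided search for the VAF cutoff separating probable monoallelic
    from probable biallelic cases (log-rank split-point search with a
    minimum-node-size constraint, bootstrap subsampling, and repeated
    train/test cross-validation scored by Harrell's concordance), self-contained
    survival utilities (Kaplan-Meier curves, k-sample log-rank test, Harrell's
    C-index, univariate Cox regression, 2x2 odds ratios), and a fully seeded
    synthetic cohort generator producing ground-truthed clonal architectures,
    binomially sampled bulk VAFs, del(17p) calls with a detection floor,
    stratum-dependent survival outcomes and single-cell genotype matrices with
    allelic dropout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
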