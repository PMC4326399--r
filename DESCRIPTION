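Package: her2snp
Title: HER2 Copy-Number Analysis of SNP-Array Data in Breast Tumors
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for assessing HER2 (ERBB2) gene status in
    breast tumors from probe-level SNP-array data. Implements genome-mean
    (baseline-2) intensity normalization, recursive breakpoint segmentation
    with significance, minimum-size and magnitude criteria, threshold-based
    copy-number status calling, HER2-versus-centromere relation labeling, a
    combined intensity/allelic-balance polyploidy inference, a virtual
    HER2/CEP17 FISH ratio, and an IHC/FISH-versus-SNP concordance analysis.
    Includes a synthetic tumor-genome generator (focal amplification,
    co-amplification, polyploidy, copy-neutral LOH, normal-cell admixture)
    and packaged per-sample clinical tables for a 65-tumor cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
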