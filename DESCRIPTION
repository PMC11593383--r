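Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and ROH Islands from
    SNP-Array Genotypes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) in SNP-array genotypes with
    the consecutive-runs method, calibrates per-length-class heterozygote and
    missing-call allowances from assumed genotyping-error and missingness
    rates, computes the genomic inbreeding coefficient F_ROH, and identifies
    population-level ROH islands by z-score outlier thresholding of per-SNP
    ROH incidence, with cross-population sharing of island regions and
    offline candidate-gene overlap. Includes PLINK text and binary genotype
    file support, quality-control filtering, a synthetic genotype generator
    with planted autozygous tracts for end-to-end validation, and a pipeline
    driver producing tab-separated summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
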