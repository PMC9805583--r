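Package: imputemerge
Title: Merge Imputed Genotype Batches with Correct Quality Combination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Streaming merger for imputed genotype data that has been split
    into batches for imputation (for example to respect imputation-server
    sample caps) and must be recombined for joint analysis. Reads
    position-sorted, gzip- or bgzip-compressed per-batch VCF files together
    with Minimac-style info tables, combines per-batch imputation quality
    (Rsq) across batches via Fisher's z-transformation weighted by batch
    sample size, summarises allele frequencies as weighted means with
    minima and maxima, applies missingness and quality filters, manages
    samples duplicated across batches, and writes a single merged
    bgzip-compressed VCF plus retained/excluded variant tables, a
    duplicate-sample list and a log. A synthetic-cohort generator with
    known ground truth supports testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
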