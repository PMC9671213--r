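Package: dcimpute
Title: Reference-Free Genotype Imputation with a Denoising Convolutional Autoencoder
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-free imputation of missing genotypes with a 1D
    convolutional denoising autoencoder trained by a per-batch-loss custom
    loop. Provides VCF input/output for biallelic genotype matrices, one-hot
    encoding with a reserved missing channel, SNP filtering (missingness,
    Hardy-Weinberg equilibrium, minor allele frequency), random masking
    protocols, the concordance rate / Hellinger / scaled-Euclidean-norm /
    imputation-quality-score / dosage-correlation evaluation metrics with
    their aggregation conventions, MAF-stratified evaluation, paired t-test
    model comparison, and a block-LD haplotype-mosaic genotype simulator so
    the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    vcfR,
    generics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
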