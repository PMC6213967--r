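Package: methylsex
Title: Sex Inference and Sex-Chromosome Abnormality Detection from
    Methylation Array Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the sex of DNA-methylation microarray samples (Illumina
    HM450k/EPIC-style data) from the binned distributions of beta-values and
    detection p-values on the sex chromosomes. Female X-chromosome
    inactivation leaves a distinctive intermediate-methylation signature on
    chrX, and the absence of chrY in females leaves high detection p-values
    on chrY probes; per-chromosome principal component analysis and k-means
    clustering against a curated male/female reference panel assign a sex per
    chromosome, and samples whose chrX- and chrY-derived assignments conflict
    are flagged (potential Klinefelter or Turner karyotypes, or mislabelled
    samples). Includes a reference-panel builder with fine pre-binned
    proportion tables re-binnable to any aligned coarse scheme, a
    detection-p-value quality-control filter, a synthetic cohort generator
    for the XX, XY, XXY and X0 karyotypes, diagnostic plots, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
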