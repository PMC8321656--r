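Package: graftrace
Title: Tracing Donor-Derived Malignancy in Organ Transplant Recipients from Variant Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciding whether tumors arising in organ transplant
    recipients are derived from the donor, using whole-exome variant profiles.
    Implements tumor-germline subtraction, population allele-frequency
    filtering against reference catalogs (1000 Genomes, HapMap, dbSNP, ExAC,
    gnomAD), overlap and sex-chromosome discordance analysis against the donor
    tumor, tri-classification of shared coding variants into somatic and
    donor-germline tiers, allelic-fraction based tumor purity estimation,
    MLPA probe-ratio copy-number calling, and a synthetic transplant-cohort
    simulator with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
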