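Package: methylaudit
Title: Privacy Auditing of DNA Methylation Array Data
Version: 0.1.0
Authors@R:
    person("methylaudit", "developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Audits Illumina HumanMethylation450-style beta-value matrices for
    re-identification risk. Tri-modal beta-value binning recovers genotypes at
    CpG sites destroyed by common polymorphisms; candidate loci are screened by
    bin occupancy and a Hardy-Weinberg equilibrium test, ranked by observed
    heterozygosity, and assembled into per-sample genetic fingerprints with
    forensic random-match probabilities. Includes protected-health-information
    flagging at trait-associated CpGs (e.g. the AHRR smoking locus
    cg05575921), in-silico MspI restriction-digest assay design for wet-lab
    genotype validation, redaction of informative probes, and a synthetic-data
    generator with complete truth tables so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
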