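Package: lohconfound
Title: Strain-Specific Germline Variants as Confounders of Mouse Tumor Copy-Number Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and detection toolkit for a systematic artifact in
    mouse cancer genomics: germline deletion variants private to one inbred
    strain, when genetically linked to a driver allele undergoing loss of
    heterozygosity (LOH) in tumors, masquerade as recurrent focal somatic
    deletions in tumor/germline comparisons. The package simulates inbred
    crosses and backcrosses with selection for an engineered driver allele,
    applies somatic copy-neutral LOH and focal-deletion events, and emits
    exome-like observables (binned coverage, per-SNP allele counts, array-CGH
    style probe ratios). On the analysis side it reconstructs germline
    haplotype states from SNP allele frequencies, calls LOH and its mechanism
    (copy-neutral versus deletion), segments tumor/germline coverage
    log-ratios into copy-number calls, and classifies deletion calls at
    cohort level as germline-variant artifacts or somatic candidates using
    breakpoint concordance, a strain-variant registry, and linkage to driver
    LOH.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
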