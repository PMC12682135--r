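Package: ctdnadyn
Title: Longitudinal ctDNA Monitoring from Droplet Digital PCR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring circulating tumor DNA (ctDNA) with
    mutation-specific droplet digital PCR (ddPCR) assays, as used for
    GNAQ/GNA11 hotspot mutations in metastatic uveal melanoma. Converts
    droplet-level partition counts into absolute concentrations and mutant
    allele frequency (MAF) with single-sample 95% confidence intervals via
    Poisson partition statistics, derives a detection floor from
    no-template controls, classifies longitudinal trajectories into
    clearance / decrease / increase (confirmed or unconfirmed) events,
    relates molecular events to radiological progression (lead time,
    cross-tabulated event accounting), computes baseline and landmark
    ctDNA status, and stratifies progression-free and overall survival by
    ctDNA status with Kaplan-Meier estimation and log-rank tests. A
    synthetic cohort generator with known ground truth (tumor-burden
    linked shedding, Poisson droplet partitioning, false-positive
    droplets, imaging schedules, status-linked progression hazards) makes
    the whole pipeline testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
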