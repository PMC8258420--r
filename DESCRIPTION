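Package: bidscurator
Title: Heuristic-Driven BIDS Curation and Auditing of Hierarchical Imaging Projects
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates neuroimaging acquisitions held in a hierarchical
    project store (project, subject, session, acquisition containers with
    DICOM-header metadata and NIfTI files) into the Brain Imaging Data
    Structure (BIDS). Provides a tabulator for DICOM-header-derived
    sequence information, an executable heuristic rule file mapping
    acquisitions to BIDS naming templates, curation with dry-run and
    clean clearing, export to a BIDS directory tree, a subset BIDS
    validator, and a project auditor that reports sequence inventories,
    curation state, pipeline-run outcomes, and per-subject completeness
    against a template subject. A deterministic synthetic-project
    generator supplies demonstration fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    yaml
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
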