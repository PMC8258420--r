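---
title: "Heuristic BIDS curation and project auditing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heuristic BIDS curation and project auditing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bidscurator)
```

## The problem

Neuroimaging studies accumulate scanner output as a hierarchy: a project
holds subjects, subjects hold scanning sessions, sessions hold acquisitions
(one scanning sequence instance each), and acquisitions hold files — the raw
DICOMs and the NIfTI volumes converted from them. Before any standard
analysis pipeline can touch these data they must be curated into the Brain
Imaging Data Structure (BIDS): files renamed into a strict entity grammar
(`sub-01_ses-1_task-rest_bold.nii.gz`), placed into datatype folders
(`anat/`, `func/`, `fmap/`, `dwi/`), and annotated with JSON sidecars.
Doing this by hand is slow and error-prone, and studies drift: subjects miss
sequences, pipeline runs fail silently, curation conventions change
mid-study.

`bidscurator` addresses both halves of this problem for projects held in a
local, file-backed container store:

* **curation** — a tabulator summarizing DICOM-header information, an
  executable *heuristic* rule file mapping acquisitions to BIDS naming
  templates, application of those rules with a dry-run mode, export to a
  BIDS directory tree, a subset validator, and a clean "clear" that undoes
  curation exactly;
* **auditing** — sequence inventories, curation state, pipeline ("gear")
  run outcomes, and per-subject completeness against a *template subject*,
  rendered as a static HTML report plus CSV tables.

## The data model

The store mirrors the hierarchy on disk: one JSON index document per
container (`project.json`, `subjects/<label>/subject.json`, ...), payload
bytes under `files/`. Sibling labels are unique within a parent; insertion
order is preserved, and saving the same record twice is byte-identical, so
whole-store checksums are meaningful. Session labels are scoped per subject
(two subjects may both have a session `"1"`); nothing in the BIDS output
requires project-wide session uniqueness.

Two metadata namespaces on files are special. `dicom_header` carries the
header record derived from the DICOM and is **immutable ground truth**:
every write to it is refused, so curation can always be reproduced from
scratch. `BIDS` carries the resolved BIDS identity of a NIfTI file and is
the only thing curation ever writes. Analyses (gear runs) are records with a
gear name, dotted version, complete/failed status, and timestamps; runtimes
are derived from the timestamps when absent.

## Tabulation

`tabulate_project()` flattens each acquisition's header into one SeqInfo
row: subject and session labels, series number, series description,
protocol and sequence names, image type (multi-valued in DICOM, flattened
by joining with `_`), repetition and echo times, matrix dimensions, and the
file count. Times are converted from the header's milliseconds to seconds,
the unit BIDS sidecars use. `series_id` is
`<subject>_<session>_<series_number>`, which makes heuristic assignments
reproducible run to run.

Unique mode collapses the table to one row per distinct parameter key. The
key is committed as the 10 fields heuristics typically branch on:
description, protocol, sequence name, image type, TR, TE, and the four
dimensions. Missing numeric fields serialize as empty strings rather than
zero — two sequences that each lack a TR should not collide into one "unique"
row on a fake 0.

## The heuristic file

The heuristic is an ordinary R script loaded into an isolated environment.
Any top-level character-scalar assignment declares a naming template, and
the variable name is the template key:

```r
t1w <- "sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"

classify <- function(seqinfo) {
  list(t1w = seqinfo$series_id[grepl("T1w", seqinfo$series_description)])
}
```

`classify()` is the one required reserved name; `ReplaceSubject`,
`ReplaceSession`, `MetadataExtras`, `IntendedFor`, `AttachToProject` and
`AttachToSession` are optional. Because the heuristic is executable code, a
rule may combine any number of SeqInfo fields; because it is plain text, it
can be version-controlled alongside the study.

Decisions where the design was genuinely open:

* **Placeholders** are fixed to `{SubjectLabel}`, `{SessionLabel}` and
  `{item}`. When a key matches *n* > 1 series and its template lacks
  `{item}`, a `run-<i>` entity is inserted before the suffix — BIDS forbids
  duplicate paths, so repeated matches must disambiguate somehow, and `run-`
  is the BIDS-native way.
* **Tie-breaking**: a series matching several keys is kept by the
  first-declared key, with a warning. Within a key, series order is
  ascending series number (acquisition order), not rule-output order.
* **Label hygiene**: the user transform runs first, then every
  non-alphanumeric character is stripped; an empty result is an error, not a
  silent empty entity.
* **`IntendedFor`** is declared as template strings (readable, checkable
  against the declared templates at load time) but stored and emitted as
  subject-relative paths `ses-<L>/<folder>/<file>`, the form BIDS sidecars
  require. Only targets actually planned for the same session are emitted.
* The datatype-folder table covers T1w/T2w/FLAIR (anat), bold/sbref (func),
  dwi (dwi), and epi/magnitude/phasediff/fieldmap (fmap); any other suffix
  resolves to folder `other` with a warning rather than an error, so a
  heuristic under development still produces an inspectable plan.

## Curation semantics

`curate_project()` always builds a full plan first — one row per intended
metadata write, attachment, or skip (e.g. an acquisition with a DICOM but no
converted NIfTI). Duplicate resolved paths abort the plan, naming both
sources. With `dry_run = TRUE` nothing is written; the test-suite asserts
store-checksum equality around every dry run. Applying the plan writes only
`BIDS` namespaces and attachment files, then persists.

Three bookkeeping choices make `clear_bids()` an exact inverse:
attachments created by curation carry a marker in their metadata, the
auto-created dataset description is flagged as generated, and clearing
removes exactly the marked set plus the `BIDS` namespaces. A filtered clear
(specific subjects/sessions) leaves project-level attachments and the
description in place, since other subjects may still depend on them.
Re-curation overwrites a differing identity with a logged diff; applying the
same heuristic twice leaves the store byte-identical.

If an acquisition holds several NIfTI files, the first (store order)
receives the BIDS identity and the rest appear in the plan as skips — the
fixtures, like the typical converted acquisition, hold exactly one.

## Export and validation

`export_bids()` writes `sub-<L>/ses-<L>/<folder>/<filename>` for every
NIfTI with a BIDS identity, one sidecar per image, attachments at their
recorded paths, and `dataset_description.json` (auto-populated with the two
required fields, `Name` and `BIDSVersion`; the committed version string is
`r bidscurator:::BIDS_VERSION`). Sidecar precedence: header-derived fields
(`RepetitionTime`, `EchoTime`, in seconds) first, overridden by any
`MetadataExtras` — extras are deliberate hardcoding and must win — plus the
resolved `IntendedFor` list on fieldmaps. Sessionless layouts are not
produced; every exported path includes `ses-`.

`validate_dataset()` applies a committed subset of BIDS rules with stable
codes — R1 dataset description present/parseable/complete, R2 filename
grammar, R3 entity/directory agreement, R4 suffix-folder consistency, R5
task entity on functional images, R6 `IntendedFor` resolution, R7
alphanumeric labels, R8 duplicate paths — on either an exported tree or the
in-store namespaces. All rule violations are errors; an unknown suffix is
the warning W1. Validation is pure (same input, byte-identical issue
table). The full official BIDS Validator is not reimplemented; the CLI's
`--external-validator` flag delegates to one when available, and the subset
is chosen so that anything this package exports from a collision-free plan
passes its structural rules by construction (a property the test-suite
asserts).

## Auditing

* **Sequence identity** is `SeriesDescription` string equality — the same
  grouping a scanner operator sees.
* **Gear percentages** use subject-level, latest-run semantics: a failed run
  followed by a successful re-run counts the subject complete. Percentages
  are rounded to the nearest integer (19 of 20 subjects is 95%), and
  complete + failed always sums to 100 per gear row.
* **Completeness** columns come from the template subject alone: its
  sequences, its BIDS template keys, and its (gear, version) pairs. A cell
  is complete when the row subject has at least as many matching items as
  the template; for gears the version must match the template's exactly and
  the run must have completed — mixed pipeline versions are a
  reproducibility hazard the audit is specifically meant to expose.
* The report is one static, dependency-free HTML file plus six CSVs; the
  gear runtimes list-column serializes into CSV joined with `;`.

## The synthetic generator

`generate_project()` builds fully self-describing stores from a
configuration: subjects (hex8 or numeric labels), a sequence menu with
per-entry header parameters and repeat counts, per-subject missing
sequences, and per-subject gear outcomes. Determinism is a contract: the
generator runs under a private RNG stream, and NIfTI stubs are written
through a `gzfile()` connection, which stamps a zero mtime so identical
configurations yield byte-identical stores.

Two presets encode the demonstration-study scenarios the package's
worked examples use. `fixture_overview()` has 20 subjects, one session
each, with one T1w, three B0map and one resting-state BOLD acquisition per
session — hence 100 acquisitions and 60 B0map files. `fixture_completeness()`
adds a DWI acquisition and the named incompleteness pattern: subjects
`cec4ba54` and `f53cd86f` lack DWI and a successful QSIPrep run (v0.14.2),
and `f53cd86f` additionally has failed fMRIPrep (v20.2.3) and XCPEngine
(v1.2.3) runs — so fMRIPrep completes for 19 of 20 subjects (95%). The two
fixed labels are force-inserted; remaining labels are drawn from the seeded
hex generator. Header parameter values (TR 2.4 s T1w, TR 0.8 s BOLD, TE
4.92 ms fieldmap, and so on) are typical 3T protocol values; they matter
only insofar as they are distinct, realistic, and stable.

What the fixtures deliberately do **not** emulate: real image content (the
stubs are 2×2×2 uint8 volumes with valid headers; header matrix dimensions
describe the nominal acquisition, not the stub), raw DICOM byte streams
(the header record stands in for a parsed header), scanner vendor quirks,
or multi-site heterogeneity. Passing tests therefore demonstrate the
correctness of the curation/audit logic over the metadata model, not
robustness to malformed real-world DICOMs.

Problem sizes throughout the tests are the 20-subject presets and smaller
handmade projects; the full suite builds each preset once and copies it for
mutation tests, and every end-to-end scenario (generate, curate, export,
validate, audit) completes in seconds.

## Known limitations

* The validator covers the committed rule subset only — no derivatives,
  PET/EEG modalities, `participants.tsv` content checks, or `.bidsignore`.
* The suffix table is the committed set above; other datatypes land in
  `other` and are excluded from export-path guarantees.
* Attachments are treated as text; binary attachments are out of scope.
* The store is single-writer: no locking, no concurrent access.
* Heuristics are executed code; load them only from trusted sources.
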