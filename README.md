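# bidscurator

Heuristic-driven BIDS curation and auditing of hierarchically stored
neuroimaging projects.

## The problem

Scanner output accumulates as a hierarchy — project → subject → session →
acquisition — with DICOM files (whose headers are the ground truth for what
was acquired) and the NIfTI volumes converted from them. Analysis pipelines
expect the Brain Imaging Data Structure (BIDS): strictly named files
(`sub-01_ses-1_task-rest_bold.nii.gz`) in datatype folders with JSON
sidecars. `bidscurator` is for imaging labs who keep such projects in a
local file-backed store and need to

1. **curate** them into BIDS reproducibly — a *heuristic* file written in R
   declares naming templates and Boolean rules over DICOM-header fields
   (`SeriesDescription`, TR, TE, dimensions, ...) that assign each
   acquisition to a template; curation writes the resolved identity into
   the metadata of NIfTI files only, never touching DICOM ground truth, so
   it can be repeated, updated, or cleared at any time; and
2. **audit** them — enumerate collected sequences, BIDS curation state and
   pipeline ("gear") run outcomes, and compare every subject against a
   *template subject* to flag missing data or analyses, as a static HTML
   report plus CSV tables.

The curation cycle is tabulate → write heuristic → curate `--dry-run` →
curate → validate → (optionally) clear and start over; the validator
applies a committed subset of BIDS rules (R1–R8, stable codes) so curation
can be checked without any external tooling.

## Worked example

The package ships a deterministic synthetic-project generator whose presets
reproduce a 20-subject demonstration study (one session each; one T1w,
three B0map fieldmaps and one resting-state BOLD per session; the
completeness preset adds DWI and pipeline-run outcomes).

```r
library(bidscurator)

root <- tempfile()
project <- fixture_overview(root)
project
#> <bc_project> 'demo_project': 20 subjects, 20 sessions, 100 acquisitions

audit_sequences(project)
#> # A tibble: 3 × 2
#>   sequence            files
#>   <chr>               <int>
#> 1 B0map                  60
#> 2 anat_T1w               20
#> 3 func_task-rest_bold    20
```

60 B0map files = 20 subjects × 3 fieldmap acquisitions — the sequence
inventory a curator consults before writing a heuristic. Curate with the
bundled demonstration heuristic, export, and validate:

```r
spec <- load_heuristic(demo_heuristic_path())
curate_project(project, spec)                 # dry_run = TRUE to preview
export_tree <- tempfile()
manifest <- export_bids(load_project(root), export_tree)
manifest
#> <BIDS export manifest> 202 path(s): attachment=1, dataset_description=1, image=100, sidecar=100

glance(validate_dataset(export_tree))
#> # A tibble: 1 × 4
#>   valid n_errors n_warnings n_issues
#>   <lgl>    <int>      <int>    <int>
#> 1 TRUE         0          0        0
```

All 100 images export under grammar-valid paths with sidecars (fieldmap
sidecars carry `IntendedFor` pointing at the BOLD run they correct), and
the tree validates cleanly. Auditing the completeness preset:

```r
p <- fixture_completeness(tempfile())
audit_gears(p)[, 1:5]
#> # A tibble: 3 × 5
#>   gear_name gear_version total_runs percent_complete percent_failed
#>   <chr>     <chr>             <int>            <dbl>          <dbl>
#> 1 QSIPrep   0.14.2               20               90             10
#> 2 XCPEngine 1.2.3                20               95              5
#> 3 fMRIPrep  20.2.3               20               95              5
```

fMRIPrep completed for 95% of subjects (19 of 20). The completeness
matrices against any fully complete template subject flag exactly subjects
`cec4ba54` and `f53cd86f` as incomplete in the DWI sequence column and in
the QSIPrep gear column — the audit's core purpose: naming precisely who is
missing what. `render_report(audit_project(p, template), dir)` writes the
HTML report and six CSV tables; `plot_sequence_counts()` /
`plot_gear_outcomes()` give the corresponding ggplot figures.

## From the shell

```sh
bidscurator synth --preset overview --out /data/demo --seed 20
bidscurator tabulate --project /data/demo --unique -o seq.tsv
bidscurator curate --project /data/demo --heuristic heuristic.R --dry-run
bidscurator curate --project /data/demo --heuristic heuristic.R
bidscurator validate --project /data/demo        # exit 0 iff valid
bidscurator export --project /data/demo --destination /data/demo-bids
bidscurator audit --project /data/demo -o /data/demo-audit
```

All commands operate on the whole project by default and take repeatable
`--subject`/`--session` filters; `--log-json` emits machine-readable logs.

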