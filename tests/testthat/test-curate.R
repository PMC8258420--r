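test_that("a dry run plans changes but leaves the store byte-identical", {
  p <- fresh_fixture("overview")
  root <- project_root(p)
  before <- store_checksum(root)
  plan <- curate_project(p, demo_spec(), dry_run = TRUE)
  expect_gt(nrow(plan), 0)
  expect_true(all(plan$action %in% c("set_bids", "attach_file", "skip")))
  expect_identical(store_checksum(root), before)
})

test_that("applying the heuristic writes BIDS identities onto NIfTI files", {
  p <- fresh_fixture("overview")
  root <- project_root(p)
  suppressMessages(curate_project(p, demo_spec()))
  curated <- load_project(root)

  bolds <- walk_bids_paths(curated)
  expect_true(any(grepl("_task-rest_bold\\.nii\\.gz$", bolds)))
  # every resolved path unique across the applied project
  expect_equal(anyDuplicated(bolds), 0)

  # per-subject filename shape from the naming template
  ses <- select_sessions(curated, subject_labels = "cec4ba54")[[1]]
  acq <- ses$acquisitions[[5]]   # the rest-bold acquisition
  nifti <- Filter(function(f) f$kind == "nifti", acq$files)[[1]]
  expect_equal(nifti$info$BIDS$filename, "sub-cec4ba54_ses-1_task-rest_bold.nii.gz")
  expect_equal(nifti$info$BIDS$folder, "func")

  # MetadataExtras landed on the fieldmaps
  fmap <- Filter(function(f) f$kind == "nifti", ses$acquisitions[[2]]$files)[[1]]
  expect_equal(fmap$info$BIDS$sidecar_extras$Units, "Hz")
  # IntendedFor resolved to a subject-relative path of a planned image
  expect_equal(unlist(fmap$info$BIDS$intended_for),
               "ses-1/func/sub-cec4ba54_ses-1_task-rest_bold.nii.gz")

  # project attachment with recorded path + auto dataset description
  expect_true("README" %in% vapply(curated$files, function(f) f$name, character(1)))
  expect_equal(dataset_description(curated)$Name, "demo_project")
})

test_that("curation is idempotent on the store", {
  p <- fresh_fixture("overview")
  root <- project_root(p)
  suppressMessages(curate_project(p, demo_spec()))
  after_one <- store_checksum(root)
  suppressMessages(curate_project(load_project(root), demo_spec()))
  expect_identical(store_checksum(root), after_one)
})

test_that("clearing after curating restores the pre-curation store", {
  p <- fresh_fixture("overview")
  root <- project_root(p)
  before <- store_checksum(root)
  suppressMessages(curate_project(p, demo_spec()))
  expect_false(identical(store_checksum(root), before))
  n <- clear_bids(load_project(root))
  expect_gt(n, 0)
  expect_identical(store_checksum(root), before)
  expect_equal(clear_bids(load_project(root)), 0)
})

test_that("a filtered clear leaves other subjects' BIDS namespaces intact", {
  p <- fresh_fixture("overview")
  root <- project_root(p)
  suppressMessages(curate_project(p, demo_spec()))
  clear_bids(load_project(root), subject_labels = "cec4ba54")
  curated <- load_project(root)
  tbl <- walk_files(curated)
  niftis <- tbl[tbl$kind == "nifti", ]
  expect_false(any(niftis$has_bids[niftis$subject_label == "cec4ba54"]))
  others <- niftis[niftis$subject_label != "cec4ba54", ]
  expect_true(all(others$has_bids))
  # project-level attachment survives a filtered clear
  expect_true("README" %in% vapply(curated$files, function(f) f$name, character(1)))
})

test_that("an acquisition with a DICOM but no NIfTI is skipped with a reason", {
  root <- tempfile()
  p <- new_project("skip", subjects = list(new_subject("s1", sessions = list(
    new_session("1", acquisitions = list(
      new_acquisition("01_anat_T1w", files = list(
        new_file("d", "dicom", info = list(dicom_header = list(
          SeriesDescription = "anat_T1w", SeriesNumber = 1)))
      ))
    ))
  ))))
  save_project(p, root)
  plan <- curate_project(load_project(root), demo_spec(), dry_run = TRUE)
  skips <- plan[plan$action == "skip", ]
  expect_equal(nrow(skips), 1)
  expect_match(skips$reason, "no NIfTI")
})

test_that("two series resolving to one path is a curation error naming both", {
  clash <- load_heuristic(write_heuristic(c(
    't1w <- "sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"',
    'flair <- "sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"',
    "classify <- function(seqinfo) {",
    "  ids <- seqinfo$series_id[order(seqinfo$series_number)]",
    "  list(t1w = ids[1], flair = ids[2])",
    "}"
  )))
  p <- tiny_project()
  expect_error(curate_project(p, clash, dry_run = TRUE),
               "same path", class = "bc_curation_error")
})

test_that("session attachments are materialized once per selected session", {
  spec <- load_heuristic(write_heuristic(c(
    't1w <- "sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"',
    "classify <- function(seqinfo) list()",
    "AttachToSession <- list(list(",
    '  path = "sub-{SubjectLabel}/ses-{SessionLabel}/func/sub-{SubjectLabel}_ses-{SessionLabel}_task-rest_events.tsv",',
    '  content = "onset\\tduration\\n"))'
  )))
  p <- tiny_project()
  attached <- suppressMessages(attach_extra_files(p, spec))
  expect_equal(nrow(attached), length(select_sessions(p)))
  expect_match(attached$relative_path[[1]], "^sub-001/ses-1/func/")

  # and clear removes exactly what curation added
  root <- project_root(p)
  n <- clear_bids(load_project(root))
  expect_equal(n, nrow(attached))
})

test_that("attachment paths colliding with image paths are rejected", {
  p <- fresh_fixture("overview")
  suppressMessages(curate_project(p, demo_spec()))
  p2 <- load_project(project_root(p))
  clash_path <- walk_bids_paths(p2)[[1]]
  spec <- load_heuristic(write_heuristic(c(
    't1w <- "sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"',
    "classify <- function(seqinfo) list()",
    sprintf('AttachToProject <- list(list(path = "%s", content = "x"))', clash_path)
  )))
  expect_error(attach_extra_files(p2, spec), class = "bc_curation_error")
})
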