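test_that("sequence enumeration counts files per sequence", {
  p <- cached_fixture("overview")
  seqs <- audit_sequences(p)
  expect_equal(seqs$files[seqs$sequence == "B0map"], 60)
  expect_equal(seqs$files[seqs$sequence == "anat_T1w"], 20)
  # oracle: total equals an exhaustive NIfTI walk
  expect_equal(sum(seqs$files), walk_count_nifti(p))
  expect_equal(nrow(audit_sequences(new_project("e"))), 0)
})

test_that("BIDS audit counts distinct subjects per naming template", {
  p <- fresh_fixture("completeness")
  root <- project_root(p)
  suppressMessages(curate_project(p, demo_spec()))
  curated <- load_project(root)

  tbl <- audit_bids(curated)
  expect_equal(tbl$subjects[!is.na(tbl$bids_template) & tbl$bids_template == "t1w"], 20)
  # two subjects lack DWI entirely
  expect_equal(tbl$subjects[!is.na(tbl$bids_template) & tbl$bids_template == "dwi"], 18)

  clear_bids(load_project(root))
  cleared_tbl <- audit_bids(load_project(root))
  expect_true(all(is.na(cleared_tbl$bids_template)))
})

test_that("gear audit reports per-subject completion percentages", {
  p <- cached_fixture("completeness")
  gears <- audit_gears(p)
  fm <- gears[gears$gear_name == "fMRIPrep", ]
  expect_equal(fm$percent_complete, 95)
  expect_equal(fm$complete_subjects, 19)
  expect_equal(fm$percent_complete + fm$percent_failed, 100)
  expect_equal(fm$total_runs, 20)
  expect_true(all(unlist(fm$runtimes) > 0))
  # gears with zero runs are absent
  expect_false("NoSuchGear" %in% gears$gear_name)
  expect_equal(nrow(audit_gears(new_project("e"))), 0)
})

test_that("latest-run semantics: a failure followed by a success counts complete", {
  sub <- new_subject("s1", sessions = list(new_session("1")), analyses = list(
    new_analysis("a1", "prep", "1.0", "failed",
                 "2021-03-01T10:00:00Z", "2021-03-01T11:00:00Z"),
    new_analysis("a2", "prep", "1.0", "complete",
                 "2021-03-02T10:00:00Z", "2021-03-02T11:00:00Z")
  ))
  p <- new_project("g", subjects = list(sub))
  gears <- audit_gears(p)
  expect_equal(gears$percent_complete, 100)
  expect_equal(gears$total_runs, 2)
})

test_that("all-failed gears report the complement", {
  sub <- new_subject("s1", sessions = list(new_session("1")), analyses = list(
    new_analysis("a1", "prep", "1.0", "failed",
                 "2021-03-01T10:00:00Z", "2021-03-01T11:00:00Z")
  ))
  gears <- audit_gears(new_project("g", subjects = list(sub)))
  expect_equal(gears$percent_complete, 0)
  expect_equal(gears$percent_failed, 100)
})

test_that("completeness flags exactly the subjects missing the template's items", {
  p <- cached_fixture("completeness")
  template <- setdiff(subject_labels_of(p), c("cec4ba54", "f53cd86f"))[[1]]
  cm <- completeness(p, template)

  inc_dwi <- cm$sequences$subject_label[cm$sequences$dwi_multishell == "incomplete"]
  expect_setequal(inc_dwi, c("cec4ba54", "f53cd86f"))
  # complete for everything else
  expect_true(all(cm$sequences$anat_T1w == "complete"))

  qcol <- grep("^QSIPrep", names(cm$gears), value = TRUE)
  inc_q <- cm$gears$subject_label[cm$gears[[qcol]] == "incomplete"]
  expect_setequal(inc_q, c("cec4ba54", "f53cd86f"))

  fcol <- grep("^fMRIPrep", names(cm$gears), value = TRUE)
  expect_equal(cm$gears$subject_label[cm$gears[[fcol]] == "incomplete"], "f53cd86f")
  xcol <- grep("^XCPEngine", names(cm$gears), value = TRUE)
  expect_equal(cm$gears$subject_label[cm$gears[[xcol]] == "incomplete"], "f53cd86f")

  expect_error(completeness(p, "nobody"), class = "bc_not_found_error")
})

test_that("identical subjects are complete in every column", {
  p <- cached_fixture("overview")  # every subject has identical data, no gears
  template <- subject_labels_of(p)[[3]]
  cm <- completeness(p, template)
  for (tbl in cm) {
    vals <- unlist(tbl[setdiff(names(tbl), "subject_label")])
    expect_true(all(vals == "complete"))
  }
})

test_that("a matching gear at an older version is incomplete", {
  mk_sub <- function(label, version) {
    new_subject(label, sessions = list(new_session("1")), analyses = list(
      new_analysis("a", "prep", version, "complete",
                   "2021-03-01T10:00:00Z", "2021-03-01T11:00:00Z")
    ))
  }
  p <- new_project("v", subjects = list(mk_sub("tmpl", "2.0"), mk_sub("old", "1.0")))
  cm <- completeness(p, "tmpl")
  expect_equal(cm$gears[["prep 2.0"]], "incomplete")
})

test_that("completeness columns come from the template subject alone", {
  mk_sub <- function(label, seqs) {
    acqs <- lapply(seq_along(seqs), function(i) {
      new_acquisition(sprintf("%02d_%s", i, seqs[[i]]), files = list(
        new_file("d", "dicom", info = list(dicom_header = list(
          SeriesDescription = seqs[[i]], SeriesNumber = i))),
        new_file(paste0(seqs[[i]], ".nii.gz"), "nifti")
      ))
    })
    new_subject(label, sessions = list(new_session("1", acquisitions = acqs)))
  }
  p <- new_project("c", subjects = list(mk_sub("tmpl", "A"), mk_sub("rich", c("A", "B"))))
  cm <- completeness(p, "tmpl")
  expect_identical(setdiff(names(cm$sequences), "subject_label"), "A")
})

test_that("the report writes one HTML file plus six CSV tables", {
  p <- cached_fixture("completeness")
  template <- setdiff(subject_labels_of(p), c("cec4ba54", "f53cd86f"))[[1]]
  bundle <- audit_project(p, template)
  out <- tempfile("report-")
  paths <- render_report(bundle, out)
  expect_equal(sum(grepl("\\.html$", paths$path)), 1)
  expect_equal(sum(grepl("\\.csv$", paths$path)), 6)

  seqs <- readr::read_csv(file.path(out, "sequences.csv"), show_col_types = FALSE)
  expect_equal(plain_df(seqs), plain_df(bundle$sequence_table))
  comp <- readr::read_csv(file.path(out, "completeness_sequences.csv"),
                          show_col_types = FALSE)
  expect_equal(plain_df(comp), plain_df(bundle$completeness$sequences))

  html <- readLines(file.path(out, "report.html"))
  expect_true(any(grepl("Project audit", html)))

  # empty project bundle renders without failure
  empty_out <- tempfile("report-")
  expect_no_error(render_report(audit_project(new_project("e")), empty_out))
  expect_equal(sum(grepl("\\.csv$", list.files(empty_out))), 6)
})

test_that("auditing is read-only and summarized by glance()", {
  p <- cached_fixture("completeness")
  before <- store_checksum(project_root(p))
  bundle <- audit_project(p)
  expect_identical(store_checksum(project_root(p)), before)
  g <- glance(bundle)
  expect_equal(g$n_files, walk_count_nifti(p))
  expect_false(g$has_completeness)
})

test_that("audit plots build", {
  bundle <- audit_project(cached_fixture("completeness"))
  expect_s3_class(plot_sequence_counts(bundle), "ggplot")
  expect_s3_class(plot_gear_outcomes(bundle), "ggplot")
  expect_s3_class(ggplot2::autoplot(bundle), "ggplot")
})
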