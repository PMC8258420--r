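test_that("a minimal heuristic loads with one template and no extras", {
  path <- write_heuristic(c(
    't1w <- "sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"',
    'classify <- function(seqinfo) list(t1w = seqinfo$series_id[grepl("T1w", seqinfo$series_description)])'
  ))
  spec <- load_heuristic(path)
  expect_named(spec$templates, "t1w")
  expect_length(spec$metadata_extras, 0)
  expect_length(spec$intended_for, 0)
  expect_null(spec$replace_subject)
})

test_that("the bundled demonstration heuristic declares IntendedFor wiring", {
  spec <- demo_spec()
  expect_setequal(names(spec$templates), c("t1w", "rest_bold", "b0map", "dwi"))
  expect_named(spec$intended_for, "b0map")
  expect_equal(spec$intended_for$b0map, unname(spec$templates["rest_bold"]))
})

test_that("heuristic contract violations are heuristic errors", {
  no_rule <- write_heuristic('t1w <- "sub-{SubjectLabel}_T1w.nii.gz"')
  expect_error(load_heuristic(no_rule), class = "bc_heuristic_error")

  bad_ph <- write_heuristic(c(
    't1w <- "sub-{WrongName}_T1w.nii.gz"',
    "classify <- function(seqinfo) list()"
  ))
  expect_error(load_heuristic(bad_ph), "WrongName", class = "bc_heuristic_error")

  bad_if <- write_heuristic(c(
    't1w <- "sub-{SubjectLabel}_T1w.nii.gz"',
    "classify <- function(seqinfo) list()",
    'IntendedFor <- list(t1w = "sub-{SubjectLabel}_undeclared_bold.nii.gz")'
  ))
  expect_error(load_heuristic(bad_if), class = "bc_heuristic_error")

  expect_error(load_heuristic(tempfile()), class = "bc_heuristic_error")
})

test_that("loading the same heuristic twice yields equal specs", {
  a <- demo_spec()
  b <- demo_spec()
  expect_identical(a$templates, b$templates)
  expect_identical(a$intended_for, b$intended_for)
  expect_identical(a$metadata_extras, b$metadata_extras)
})

test_that("classification assigns by Boolean rules and orders by series number", {
  p <- cached_fixture("overview")
  spec <- demo_spec()
  ses <- select_sessions(p, subject_labels = "cec4ba54")[[1]]
  si <- extract_seqinfo(ses)
  # shuffle rows: ordering must come from series_number, not input order
  si <- si[rev(seq_len(nrow(si))), ]
  out <- classify_series(spec, si)

  expect_length(out$t1w, 1)
  expect_length(out$b0map, 3)
  nums <- si$series_number[match(out$b0map, si$series_id)]
  expect_identical(nums, sort(nums))

  expect_length(classify_series(spec, si[0, ]), 0)
})

test_that("a series matching two keys goes to the first-declared key", {
  path <- write_heuristic(c(
    'first <- "sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"',
    'second <- "sub-{SubjectLabel}_ses-{SessionLabel}_FLAIR.nii.gz"',
    "classify <- function(seqinfo) list(second = seqinfo$series_id, first = seqinfo$series_id)"
  ))
  spec <- load_heuristic(path)
  si <- tibble::tibble(series_id = "s_1_1", series_number = 1L,
                       series_description = "anat")
  expect_warning(out <- classify_series(spec, si), "first-declared")
  expect_named(out, "first")
})

test_that("classify is a partial function over series", {
  spec <- demo_spec()
  p <- cached_fixture("completeness")
  for (ses in select_sessions(p)[1:5]) {
    si <- extract_seqinfo(ses)
    out <- classify_series(spec, si)
    ids <- unlist(out)
    expect_lte(length(ids), nrow(si))
    expect_equal(anyDuplicated(ids), 0)
    expect_true(all(ids %in% si$series_id))
  }
})

test_that("resolve_bids_name substitutes placeholders and derives the folder", {
  b <- resolve_bids_name("sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz",
                         "01", "A")
  expect_equal(b$filename, "sub-01_ses-A_T1w.nii.gz")
  expect_equal(b$folder, "anat")
  expect_equal(b$relative_path, "sub-01/ses-A/anat/sub-01_ses-A_T1w.nii.gz")

  bold <- resolve_bids_name("sub-{SubjectLabel}_ses-{SessionLabel}_task-rest_bold.nii.gz",
                            "01", "A")
  expect_equal(bold$folder, "func")

  item <- resolve_bids_name("sub-{SubjectLabel}_ses-{SessionLabel}_run-{item}_fieldmap.nii.gz",
                            "01", "A", item = 2, n_items = 3)
  expect_equal(item$filename, "sub-01_ses-A_run-2_fieldmap.nii.gz")
  expect_equal(item$folder, "fmap")
})

test_that("a run entity is inserted when a template lacks {item} but matches several series", {
  b <- resolve_bids_name("sub-{SubjectLabel}_ses-{SessionLabel}_bold.nii.gz",
                         "01", "A", item = 2, n_items = 2)
  expect_equal(b$filename, "sub-01_ses-A_run-2_bold.nii.gz")
})

test_that("unknown suffixes fall back to folder 'other' with a warning", {
  expect_warning(
    b <- resolve_bids_name("sub-{SubjectLabel}_ses-{SessionLabel}_mystery.nii.gz",
                           "01", "A"),
    "other")
  expect_equal(b$folder, "other")
})

test_that("non-alphanumeric labels are rejected by resolution", {
  expect_error(resolve_bids_name("sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz",
                                 "0_1", "A"),
               class = "bc_heuristic_error")
})

test_that("transform_label applies the user transform, then sanitizes", {
  spec <- demo_spec()
  expect_equal(transform_label(spec, "sub_01-x", "subject"), "sub01x")

  upper <- load_heuristic(write_heuristic(c(
    't1w <- "sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"',
    "classify <- function(seqinfo) list()",
    "ReplaceSubject <- toupper"
  )))
  expect_equal(transform_label(upper, "abc", "subject"), "ABC")
  expect_error(transform_label(spec, "___", "subject"), class = "bc_heuristic_error")
})

test_that("resolved names pass the validator grammar for committed folders", {
  spec <- demo_spec()
  grammar <- getFromNamespace("FILENAME_GRAMMAR", "bidscurator")
  for (key in names(spec$templates)) {
    for (item in 1:3) {
      b <- resolve_bids_name(spec$templates[[key]], "ab12", "1",
                             item = item, n_items = 3, template_key = key)
      expect_true(grepl(grammar, b$filename), info = b$filename)
    }
  }
})
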