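test_that("an empty project round-trips through the store", {
  root <- tempfile()
  save_project(new_project("empty"), root)
  p <- load_project(root)
  expect_length(p$subjects, 0)
  expect_equal(p$label, "empty")
})

test_that("loading a missing index is a load error", {
  expect_error(load_project(tempfile()), class = "bc_load_error")
})

test_that("persistence round-trip is the identity on the record graph", {
  p <- new_project(
    "rt", metadata = list(site = "demo", extra = list(a = 1, b = "x")),
    subjects = list(new_subject(
      "s1", metadata = list(age = 31),
      sessions = list(new_session(
        "1",
        acquisitions = list(new_acquisition(
          "01_T1",
          files = list(new_file("t1_dicoms", "dicom", info = list(
            dicom_header = list(SeriesDescription = "anat_T1w", SeriesNumber = 1,
                                ImageType = list("ORIGINAL", "PRIMARY"))
          )))
        ))
      ))
    )),
    files = list(new_file("notes.txt", "text", content_ref = "files/notes.txt",
                          content = "hello"))
  )
  root <- tempfile()
  save_project(p, root)
  p1 <- load_project(root)
  expect_true(projects_equal(p, p1))

  # unknown metadata keys preserved verbatim
  expect_equal(p1$metadata$extra$b, "x")

  # re-saving the loaded record is byte-identical
  root2 <- tempfile()
  save_project(p1, root2)
  expect_identical(store_checksum(root), store_checksum(root2))
})

test_that("saving twice yields byte-identical stores", {
  p <- tiny_project()
  r1 <- tempfile(); r2 <- tempfile()
  save_project(p, r1)
  save_project(p, r2)
  expect_identical(store_checksum(r1), store_checksum(r2))
})

test_that("save manifest mirrors the hierarchy, analyses under their parent", {
  ses <- new_session("1")
  ana <- new_analysis("qc", "QCgear", "1.0.0", "complete",
                      "2021-03-01T10:00:00Z", "2021-03-01T10:30:00Z")
  ses$analyses <- list(ana)
  p <- new_project("m", subjects = list(new_subject("s1", sessions = list(ses))))
  manifest <- save_project(p, tempfile())
  expect_equal(sum(grepl("subject\\.json$", manifest$path)), 1)
  expect_true("subjects/s1/sessions/1/analyses/001_qc.json" %in% manifest$path)
})

test_that("analysis runtime is derived from timestamps and must be nonnegative", {
  a <- new_analysis("x", "g", "1.0", "complete",
                    "2021-03-01T10:00:00Z", "2021-03-01T11:00:00Z")
  expect_equal(a$runtime_seconds, 3600)
  expect_error(
    new_analysis("x", "g", "1.0", "complete",
                 "2021-03-01T11:00:00Z", "2021-03-01T10:00:00Z"),
    class = "bc_integrity_error"
  )
})

test_that("duplicate sibling labels are an integrity error", {
  expect_error(new_project("d", subjects = list(new_subject("a"), new_subject("a"))),
               class = "bc_integrity_error")
  expect_error(new_subject("s", sessions = list(new_session("1"), new_session("1"))),
               class = "bc_integrity_error")
})

test_that("the 20-subject fixture enumerates 100 acquisitions", {
  p <- cached_fixture("overview")
  n_acq <- sum(vapply(p$subjects, function(s) {
    sum(vapply(s$sessions, function(x) length(x$acquisitions), integer(1)))
  }, integer(1)))
  expect_equal(n_acq, 100)
})

test_that("select_sessions filters intersect and default to everything", {
  p <- cached_fixture("overview")
  all_ses <- select_sessions(p)
  expect_length(all_ses, 20)

  # oracle: union over subjects of their sessions, in store order
  oracle <- unlist(lapply(p$subjects, function(s) {
    vapply(s$sessions, function(x) paste(s$label, x$label), character(1))
  }))
  got <- vapply(all_ses, function(s) paste(attr(s, "subject_label"), s$label),
                character(1))
  expect_identical(got, oracle)

  one <- select_sessions(p, subject_labels = "cec4ba54")
  expect_length(one, 1)
  expect_equal(attr(one[[1]], "subject_label"), "cec4ba54")

  expect_warning(none <- select_sessions(p, subject_labels = "nonexistent"),
                 "unknown subject")
  expect_length(none, 0)

  both <- select_sessions(p, subject_labels = "cec4ba54", session_labels = "1")
  expect_length(both, 1)
  expect_length(
    suppressWarnings(select_sessions(p, subject_labels = "cec4ba54",
                                     session_labels = "notases")), 0)
})

test_that("set_file_info replaces exactly one namespace", {
  p <- tiny_project()
  acq_path <- "subjects/001/sessions/1/acquisitions/01_anat_T1w"
  acq <- get_container_pub(p, acq_path)
  dicom_name <- acq$files[[1]]$name
  header_before <- acq$files[[1]]$info$dicom_header

  nifti_name <- acq$files[[2]]$name
  p2 <- set_file_info(p, acq_path, nifti_name, "BIDS", list(filename = "x.nii.gz"))
  acq2 <- get_container_pub(p2, acq_path)
  expect_equal(acq2$files[[2]]$info$BIDS$filename, "x.nii.gz")
  expect_identical(acq2$files[[1]]$info$dicom_header, header_before)

  # write then delete restores the original record
  p3 <- set_file_info(p2, acq_path, nifti_name, "BIDS", NULL)
  expect_true(projects_equal(p, p3))

  expect_error(set_file_info(p, acq_path, nifti_name, "dicom_header", list(a = 1)),
               class = "bc_permission_error")
  expect_error(set_file_info(p, acq_path, "no_such_file", "BIDS", list()),
               class = "bc_not_found_error")
})

test_that("DICOM files can never carry a BIDS namespace", {
  expect_error(new_file("d", "dicom", info = list(BIDS = list())),
               class = "bc_integrity_error")
})
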