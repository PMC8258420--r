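# Deterministic synthetic-project generator. Fixtures emulate a demonstration
# study: hex-labeled subjects, a small sequence menu (T1w, repeated B0map,
# resting-state BOLD, optionally DWI), per-subject pipeline-run outcomes, and
# tiny-but-valid NIfTI-1 payloads.

## ---- minimal NIfTI-1 writer -------------------------------------------------

#' Write a minimal valid NIfTI-1 volume
#'
#' Emits a complete 348-byte NIfTI-1 header plus uint8 voxel data through a
#' `gzfile()` connection, which stamps a zero mtime into the gzip header —
#' so identical inputs produce byte-identical `.nii.gz` files, a property the
#' whole fixture suite relies on. The volumes are structurally valid (readable
#' by standard NIfTI libraries) but carry no meaningful image content.
#'
#' @param path Output `.nii.gz` path.
#' @param dim Integer vector of voxel dimensions (up to 7).
#' @param fill Byte value (0-255) for every voxel.
#' @return `path`, invisibly.
#' @export
write_nifti_stub <- function(path, dim = c(2L, 2L, 2L, 1L), fill = 1L) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  ndim <- length(dim)
  stopifnot(ndim >= 1, ndim <= 7, all(dim >= 1), fill >= 0, fill <= 255)
  writeBin(348L, con, size = 4)                                  # sizeof_hdr
  writeBin(raw(36), con)                                         # legacy fields
  writeBin(as.integer(c(ndim, dim, rep(1L, 7 - ndim))), con, size = 2)  # dim[8]
  writeBin(numeric(3), con, size = 4)                            # intent_p1..3
  writeBin(c(0L, 2L, 8L, 0L), con, size = 2)    # intent_code, dtype=uint8, bitpix, slice_start
  writeBin(c(1, rep(1, 7)), con, size = 4)                       # pixdim
  writeBin(352, con, size = 4)                                   # vox_offset
  writeBin(c(1, 0), con, size = 4)                               # scl_slope/inter
  writeBin(0L, con, size = 2)                                    # slice_end
  writeBin(as.raw(c(0L, 10L)), con)                              # slice_code, xyzt=mm|s
  writeBin(c(0, 0, 0, 0), con, size = 4)         # cal_max, cal_min, slice_dur, toffset
  writeBin(c(0L, 0L), con, size = 4)                             # glmax, glmin
  writeBin(raw(104), con)                                        # descrip + aux_file
  writeBin(c(0L, 1L), con, size = 2)                             # qform=0, sform=1
  writeBin(numeric(6), con, size = 4)                            # quatern/qoffset
  writeBin(c(1, 0, 0, 0, 0, 1, 0, 0, 0, 0, 1, 0), con, size = 4) # srow (identity)
  writeBin(raw(16), con)                                         # intent_name
  writeBin(c(charToRaw("n+1"), raw(1)), con)                     # magic
  writeBin(raw(4), con)                                          # extender
  writeBin(as.raw(rep(fill, prod(dim))), con)
  invisible(path)
}

## ---- configuration ----------------------------------------------------------

#' Describe one sequence on a fixture menu
#'
#' @param series_description DICOM series description (sequence identity).
#' @param repeats Acquisitions of this sequence per session.
#' @param tr_ms,te_ms Repetition/echo time in milliseconds, as DICOM headers
#'   record them.
#' @param dims Length-4 integer matrix size (rows, columns, slices, volumes).
#' @param sequence_name,protocol_name,image_type Further header fields.
#' @return A sequence-menu entry for [fixture_config()].
#' @export
sequence_entry <- function(series_description, repeats = 1L, tr_ms, te_ms,
                           dims, sequence_name = "seq",
                           protocol_name = series_description,
                           image_type = c("ORIGINAL", "PRIMARY", "M")) {
  stopifnot(length(dims) == 4)
  if (repeats < 1) abort("sequence repeats must be >= 1", class = "bc_config_error")
  list(series_description = series_description, repeats = as.integer(repeats),
       tr_ms = tr_ms, te_ms = te_ms, dims = as.integer(dims),
       sequence_name = sequence_name, protocol_name = protocol_name,
       image_type = as.list(image_type))
}

#' Build a fixture configuration
#'
#' Describes a synthetic project: how many subjects and sessions, which
#' sequences each session contains (with their header parameters and repeat
#' counts), which subjects are missing which sequences, and the outcome of
#' each pipeline ("gear") run per subject. Generation is fully determined by
#' `seed`.
#'
#' @param n_subjects Number of subjects.
#' @param label_scheme `"hex8"` (eight lowercase hex characters) or
#'   `"numeric"` (zero-padded integers).
#' @param sessions_per_subject Sessions per subject, labelled `"1"`, `"2"`, ...
#' @param sequence_menu List of entries from [sequence_entry()].
#' @param missing Named list: subject label -> character vector of
#'   `series_description`s to omit for that subject.
#' @param gear_outcomes Named list: gear name -> `list(version =, failed =
#'   c(), absent = c(), runtime_range = c(lo, hi))`. Subjects in `absent`
#'   get no run; subjects in `failed` get a failed run; everyone else a
#'   complete run.
#' @param seed Integer seed governing labels, fill bytes and runtimes.
#' @param force_labels Labels guaranteed to appear (at the head of the
#'   subject list), e.g. to reproduce named example subjects.
#' @return A `bc_fixture_config`.
#' @export
fixture_config <- function(n_subjects, label_scheme = c("hex8", "numeric"),
                           sessions_per_subject = 1L,
                           sequence_menu = default_sequence_menu(),
                           missing = list(), gear_outcomes = list(),
                           seed = 1L, force_labels = character(0)) {
  label_scheme <- match.arg(label_scheme)
  if (n_subjects < 1) abort("n_subjects must be >= 1", class = "bc_config_error")
  if (sessions_per_subject < 1) {
    abort("sessions_per_subject must be >= 1", class = "bc_config_error")
  }
  if (length(force_labels) > n_subjects) {
    abort("more force_labels than subjects", class = "bc_config_error")
  }
  menu_descs <- map_chr(sequence_menu, "series_description")
  for (labs in missing) {
    bad <- setdiff(labs, menu_descs)
    if (length(bad)) {
      abort(sprintf("missing refers to sequences not on the menu: %s",
                    paste(bad, collapse = ", ")), class = "bc_config_error")
    }
  }
  structure(
    list(n_subjects = as.integer(n_subjects), label_scheme = label_scheme,
         sessions_per_subject = as.integer(sessions_per_subject),
         sequence_menu = sequence_menu, missing = missing,
         gear_outcomes = gear_outcomes, seed = as.integer(seed),
         force_labels = force_labels),
    class = "bc_fixture_config"
  )
}

#' Read a fixture configuration from YAML or JSON
#'
#' @param path A YAML (or JSON, which YAML subsumes) file whose keys mirror
#'   the arguments of [fixture_config()]; `sequence_menu` entries use the
#'   [sequence_entry()] fields.
#' @return A `bc_fixture_config`.
#' @export
read_fixture_config <- function(path) {
  raw <- yaml::read_yaml(path)
  menu <- map(raw$sequence_menu %||% list(), function(e) {
    sequence_entry(e$series_description, e$repeats %||% 1L, e$tr_ms, e$te_ms,
                   unlist(e$dims), e$sequence_name %||% "seq",
                   e$protocol_name %||% e$series_description,
                   unlist(e$image_type %||% list("ORIGINAL", "PRIMARY", "M")))
  })
  fixture_config(
    n_subjects = raw$n_subjects,
    label_scheme = raw$label_scheme %||% "hex8",
    sessions_per_subject = raw$sessions_per_subject %||% 1L,
    sequence_menu = if (length(menu)) menu else default_sequence_menu(),
    missing = raw$missing %||% list(),
    gear_outcomes = raw$gear_outcomes %||% list(),
    seed = raw$seed %||% 1L,
    force_labels = unlist(raw$force_labels %||% character(0))
  )
}

# The demonstration-study menu: structural T1w, three repeated B0 fieldmaps,
# one resting-state BOLD run; DWI is added by the completeness fixture.
default_sequence_menu <- function(include_dwi = FALSE) {
  menu <- list(
    sequence_entry("anat_T1w", 1L, tr_ms = 2400, te_ms = 2.2,
                   dims = c(256, 256, 176, 1), sequence_name = "tfl3d1"),
    sequence_entry("B0map", 3L, tr_ms = 580, te_ms = 4.92,
                   dims = c(64, 64, 44, 1), sequence_name = "fm2d2r"),
    sequence_entry("func_task-rest_bold", 1L, tr_ms = 800, te_ms = 30,
                   dims = c(64, 64, 44, 420), sequence_name = "epfid2d1_64")
  )
  if (include_dwi) {
    menu <- c(menu, list(
      sequence_entry("dwi_multishell", 1L, tr_ms = 3000, te_ms = 80,
                     dims = c(140, 140, 92, 103), sequence_name = "ep_b0")
    ))
  }
  menu
}

# evaluate fn with a private RNG stream, restoring the caller's state
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

gen_labels <- function(config) {
  n <- config$n_subjects
  labels <- switch(config$label_scheme,
    hex8 = {
      pool <- c(as.character(0:9), letters[1:6])
      labs <- character(0)
      while (length(labs) < n) {
        labs <- unique(c(labs, paste(sample(pool, 8, replace = TRUE), collapse = "")))
      }
      labs
    },
    numeric = sprintf("%03d", seq_len(n))
  )
  k <- length(config$force_labels)
  if (k > 0) labels[seq_len(k)] <- config$force_labels
  check_unique(labels, "generated subject labels")
  labels
}

## ---- generation -------------------------------------------------------------

#' Generate and persist a synthetic project
#'
#' Builds the full container hierarchy described by the configuration, writes
#' one NIfTI stub per acquisition plus a payload-free DICOM file carrying the
#' header record, materializes gear outcomes as analysis records on each
#' subject, and persists the store. Byte-identical for identical
#' configurations.
#'
#' @param config A [fixture_config()].
#' @param root Destination store directory.
#' @param label Project label.
#' @return The persisted `bc_project` (re-loaded from disk).
#' @export
generate_project <- function(config, root, label = "demo_project") {
  if (!inherits(config, "bc_fixture_config")) {
    abort("config must come from fixture_config()", class = "bc_config_error")
  }
  with_seed(config$seed, function() {
    labels <- gen_labels(config)
    bad_missing <- setdiff(names(config$missing), labels)
    if (length(bad_missing)) {
      abort(sprintf("missing refers to unknown subject label(s): %s",
                    paste(bad_missing, collapse = ", ")),
            class = "bc_config_error")
    }
    dir.create(root, recursive = TRUE, showWarnings = FALSE)
    t0 <- as.POSIXct("2021-03-01 08:00:00", tz = "UTC")

    subjects <- list()
    for (si in seq_along(labels)) {
      sub_l <- labels[[si]]
      omit <- config$missing[[sub_l]] %||% character(0)
      sessions <- list()
      for (ki in seq_len(config$sessions_per_subject)) {
        ses_l <- as.character(ki)
        acqs <- list()
        series_number <- 0L
        for (entry in config$sequence_menu) {
          if (entry$series_description %in% omit) next
          for (rep_i in seq_len(entry$repeats)) {
            series_number <- series_number + 1L
            header <- list(
              SeriesDescription = entry$series_description,
              ProtocolName = entry$protocol_name,
              SequenceName = entry$sequence_name,
              ImageType = entry$image_type,
              RepetitionTime = entry$tr_ms,
              EchoTime = entry$te_ms,
              SeriesNumber = series_number,
              Rows = entry$dims[[1]], Columns = entry$dims[[2]],
              Slices = entry$dims[[3]], Volumes = entry$dims[[4]]
            )
            acq_l <- sprintf("%02d_%s", series_number, entry$series_description)
            nifti_name <- sprintf("%s_%d.nii.gz",
                                  gsub("[^A-Za-z0-9]+", "_", entry$series_description),
                                  series_number)
            ref <- file.path("files", sub_l, ses_l, acq_l, nifti_name)
            write_nifti_stub(file.path(root, ref),
                             fill = ((si * 7L + series_number) %% 250L) + 1L)
            acqs[[length(acqs) + 1]] <- new_acquisition(
              acq_l,
              files = list(
                new_file(paste0(entry$series_description, "_dicoms"), "dicom",
                         info = list(dicom_header = header)),
                new_file(nifti_name, "nifti", content_ref = ref)
              )
            )
          }
        }
        sessions[[length(sessions) + 1]] <- new_session(ses_l, acquisitions = acqs)
      }
      analyses <- list()
      for (gear in names(config$gear_outcomes)) {
        g <- config$gear_outcomes[[gear]]
        if (sub_l %in% (g$absent %||% character(0))) next
        status <- if (sub_l %in% (g$failed %||% character(0))) "failed" else "complete"
        rng <- g$runtime_range %||% c(1800, 7200)
        runtime <- round(stats::runif(1, rng[[1]], rng[[2]]))
        started <- t0 + (si - 1) * 3600 + length(analyses) * 60
        analyses[[length(analyses) + 1]] <- new_analysis(
          label = sprintf("%s_%s", gear, sub_l),
          gear_name = gear, gear_version = g$version %||% "1.0.0",
          status = status,
          started = format_utc(started),
          finished = format_utc(started + runtime),
          parent_ref = sprintf("subjects/%s", sub_l)
        )
      }
      subjects[[length(subjects) + 1]] <- new_subject(sub_l, sessions = sessions,
                                                      analyses = analyses)
    }
    project <- new_project(label, subjects = subjects)
    attr(project, "root") <- root
    save_project(project, root)
    load_project(root)
  })
}

## ---- presets ----------------------------------------------------------------

#' Demonstration-study fixtures
#'
#' `fixture_overview()` builds the sequence-enumeration scenario: 20 subjects,
#' one session each, with one T1w, three B0map and one resting-state BOLD
#' acquisition per session (so 100 acquisitions, 60 of them B0map).
#'
#' `fixture_completeness()` adds a DWI acquisition to the menu and the named
#' incompleteness pattern: subjects `cec4ba54` and `f53cd86f` lack DWI and a
#' successful QSIPrep run, and `f53cd86f` additionally lacks successful
#' fMRIPrep and XCPEngine runs; every other subject is complete.
#'
#' @param root Destination store directory.
#' @param seed Integer seed (labels beyond the two fixed ones, runtimes).
#' @return The persisted `bc_project`.
#' @export
fixture_overview <- function(root = tempfile("overview-"), seed = 20L) {
  generate_project(
    fixture_config(
      n_subjects = 20L, label_scheme = "hex8", sessions_per_subject = 1L,
      sequence_menu = default_sequence_menu(include_dwi = FALSE),
      seed = seed, force_labels = c("cec4ba54", "f53cd86f")
    ),
    root = root
  )
}

#' @rdname fixture_overview
#' @export
fixture_completeness <- function(root = tempfile("completeness-"), seed = 20L) {
  incomplete_dwi <- c("cec4ba54", "f53cd86f")
  generate_project(
    fixture_config(
      n_subjects = 20L, label_scheme = "hex8", sessions_per_subject = 1L,
      sequence_menu = default_sequence_menu(include_dwi = TRUE),
      missing = stats::setNames(
        list("dwi_multishell", "dwi_multishell"), incomplete_dwi),
      gear_outcomes = list(
        fMRIPrep = list(version = "20.2.3", failed = "f53cd86f",
                        runtime_range = c(6 * 3600, 12 * 3600)),
        QSIPrep = list(version = "0.14.2", failed = incomplete_dwi,
                       runtime_range = c(4 * 3600, 9 * 3600)),
        XCPEngine = list(version = "1.2.3", failed = "f53cd86f",
                         runtime_range = c(1800, 7200))
      ),
      seed = seed, force_labels = incomplete_dwi
    ),
    root = root
  )
}

#' Path of the bundled demonstration heuristic
#'
#' A heuristic matching the fixture sequence menu: T1w, task-rest BOLD,
#' repeated B0map fieldmaps (with `IntendedFor` pointing at the BOLD run and
#' hardcoded `Units`), DWI, plus a project-level README attachment.
#'
#' @return Path to the installed heuristic file.
#' @export
demo_heuristic_path <- function() {
  system.file("extdata", "demo_heuristic.R", package = "bidscurator", mustWork = TRUE)
}
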