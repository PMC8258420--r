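#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_lgl imap keep discard compact walk iwalk map2
NULL

# Reserved file-info namespaces. "dicom_header" is immutable ground truth:
# curation derives everything from it and never writes to it.
NS_DICOM <- "dicom_header"
NS_BIDS <- "BIDS"

FILE_KINDS <- c("dicom", "nifti", "tabular", "text", "other")

## ---- constructors -----------------------------------------------------------

#' Create a file record
#'
#' A file record attaches named bytes plus namespaced metadata (`info`) to a
#' container. The `dicom_header` namespace holds the DICOM-derived header
#' record and is immutable once set; the `BIDS` namespace holds the resolved
#' BIDS identity and appears only on NIfTI-kind files after curation.
#'
#' @param name File name, unique within its container.
#' @param kind One of `"dicom"`, `"nifti"`, `"tabular"`, `"text"`, `"other"`.
#' @param info Named list of metadata namespaces.
#' @param content_ref Relative path of the payload under the store root, or
#'   `NULL` for metadata-only files (e.g. a DICOM header record kept without
#'   its bytes).
#' @param content Optional character payload for small generated files
#'   (attachments); written to `content_ref` on save.
#' @return A `bc_file` record.
#' @export
new_file <- function(name, kind, info = list(), content_ref = NULL,
                     content = NULL) {
  stopifnot(is.character(name), nzchar(name))
  kind <- match.arg(kind, FILE_KINDS)
  if (kind == "dicom" && NS_BIDS %in% names(info)) {
    abort("DICOM files never carry a 'BIDS' namespace", class = "bc_integrity_error")
  }
  structure(
    list(name = name, kind = kind, info = as_ns_map(info),
         content_ref = content_ref, content = content),
    class = "bc_file"
  )
}

#' Create an analysis record
#'
#' Analyses record one run of a versioned pipeline ("gear") against any
#' container. Runtime is derived from the started/finished timestamps when
#' not supplied.
#'
#' @param label Human-readable label.
#' @param gear_name,gear_version Pipeline identity; version is a dotted string.
#' @param status `"complete"` or `"failed"`.
#' @param started,finished ISO-8601 UTC timestamp strings.
#' @param runtime_seconds Nonnegative duration; derived from the timestamps
#'   if `NULL`.
#' @param parent_ref Container path the analysis is attached to (filled in on
#'   save/load).
#' @param outputs List of [new_file()] records produced by the run.
#' @return A `bc_analysis` record.
#' @export
new_analysis <- function(label, gear_name, gear_version,
                         status = c("complete", "failed"),
                         started, finished, runtime_seconds = NULL,
                         parent_ref = NULL, outputs = list()) {
  status <- match.arg(status)
  if (is.null(runtime_seconds)) {
    runtime_seconds <- as.numeric(difftime(parse_utc(finished), parse_utc(started),
                                           units = "secs"))
  }
  if (runtime_seconds < 0) {
    abort("analysis runtime must be nonnegative", class = "bc_integrity_error")
  }
  structure(
    list(label = label, gear_name = gear_name, gear_version = gear_version,
         status = status, started = started, finished = finished,
         runtime_seconds = runtime_seconds, parent_ref = parent_ref,
         outputs = outputs),
    class = "bc_analysis"
  )
}

new_container <- function(label, metadata, files, analyses, children, child_field,
                          class) {
  if (!is.character(label) || !nzchar(label)) {
    abort("container labels must be nonempty strings", class = "bc_integrity_error")
  }
  check_unique(map_chr(files, "name"), sprintf("file names in '%s'", label))
  if (!is.null(child_field)) {
    check_unique(map_chr(children, "label"),
                 sprintf("%s labels in '%s'", sub("s$", "", child_field), label))
  }
  x <- list(label = label, metadata = as_ns_map(metadata), files = files,
            analyses = analyses)
  if (!is.null(child_field)) x[[child_field]] <- children
  structure(x, class = c(class, "bc_container"))
}

#' Create container records
#'
#' Containers form the project > subject > session > acquisition hierarchy.
#' Sibling labels are unique within a parent; ordering is insertion order and
#' is preserved by persistence.
#'
#' @param label Container label (nonempty).
#' @param metadata Named list of metadata.
#' @param subjects,sessions,acquisitions Ordered child lists.
#' @param files List of [new_file()] records.
#' @param analyses List of [new_analysis()] records.
#' @return A record of class `bc_project`, `bc_subject`, `bc_session` or
#'   `bc_acquisition`.
#' @export
new_project <- function(label, metadata = list(), subjects = list(),
                        files = list(), analyses = list()) {
  new_container(label, metadata, files, analyses, subjects, "subjects", "bc_project")
}

#' @rdname new_project
#' @export
new_subject <- function(label, metadata = list(), sessions = list(),
                        files = list(), analyses = list()) {
  new_container(label, metadata, files, analyses, sessions, "sessions", "bc_subject")
}

#' @rdname new_project
#' @export
new_session <- function(label, metadata = list(), acquisitions = list(),
                        files = list(), analyses = list()) {
  new_container(label, metadata, files, analyses, acquisitions, "acquisitions",
                "bc_session")
}

#' @rdname new_project
#' @export
new_acquisition <- function(label, metadata = list(), files = list(),
                            analyses = list()) {
  n_dicom <- sum(map_chr(files, "kind") == "dicom")
  if (n_dicom > 1) {
    abort(sprintf("acquisition '%s' holds more than one DICOM file", label),
          class = "bc_integrity_error")
  }
  new_container(label, metadata, files, analyses, NULL, NULL, "bc_acquisition")
}

## ---- small helpers ----------------------------------------------------------

check_unique <- function(x, what) {
  if (anyDuplicated(x)) {
    abort(sprintf("duplicate %s: %s", what,
                  paste(unique(x[duplicated(x)]), collapse = ", ")),
          class = "bc_integrity_error")
  }
  invisible(x)
}

# Named-list normal form for metadata/info maps: scalars stay scalars,
# longer atomic vectors become lists so they round-trip through JSON.
as_ns_map <- function(x) {
  if (is.null(x) || length(x) == 0) return(structure(list(), names = character()))
  stopifnot(!is.null(names(x)), all(nzchar(names(x))))
  lapply(x, function(v) {
    if (is.atomic(v) && length(v) > 1) as.list(v) else v
  })
}

parse_utc <- function(x) {
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%SZ")
  if (is.na(out)) abort(sprintf("bad ISO-8601 UTC timestamp: '%s'", x),
                        class = "bc_integrity_error")
  out
}

format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

safe_segment <- function(label) {
  if (grepl("[/\\\\]", label) || startsWith(label, ".")) {
    abort(sprintf("label '%s' is not usable as a path segment", label),
          class = "bc_integrity_error")
  }
  label
}

project_root <- function(project) attr(project, "root", exact = TRUE)

## ---- container path addressing ---------------------------------------------

# Container paths: "" (project), "subjects/<l>", "subjects/<l>/sessions/<l>",
# "subjects/<l>/sessions/<l>/acquisitions/<l>".
split_container_path <- function(path) {
  if (identical(path, "")) return(character(0))
  strsplit(path, "/", fixed = TRUE)[[1]]
}

get_container <- function(project, path) {
  parts <- split_container_path(path)
  node <- project
  i <- 1
  while (i < length(parts)) {
    field <- parts[[i]]
    label <- parts[[i + 1]]
    kids <- node[[field]]
    hit <- which(map_chr(kids, "label") == label)
    if (length(hit) != 1) {
      abort(sprintf("no container at path '%s'", path), class = "bc_not_found_error")
    }
    node <- kids[[hit]]
    i <- i + 2
  }
  node
}

modify_container <- function(project, path, fn) {
  parts <- split_container_path(path)
  rec <- function(node, parts) {
    if (length(parts) == 0) return(fn(node))
    field <- parts[[1]]
    label <- parts[[2]]
    kids <- node[[field]]
    hit <- which(map_chr(kids, "label") == label)
    if (length(hit) != 1) {
      abort(sprintf("no container at path '%s'", path), class = "bc_not_found_error")
    }
    kids[[hit]] <- rec(kids[[hit]], parts[-(1:2)])
    node[[field]] <- kids
    node
  }
  out <- rec(project, parts)
  attributes(out) <- attributes(project)
  out
}

child_field_of <- function(node) {
  intersect(c("subjects", "sessions", "acquisitions"), names(node))
}

# Depth-first enumeration of container paths, store order.
container_paths <- function(project) {
  rec <- function(node, path) {
    field <- child_field_of(node)
    kid_paths <- if (length(field) == 1) {
      unlist(map(node[[field]], function(k) {
        rec(k, paste0(if (nzchar(path)) paste0(path, "/") else "", field, "/", k$label))
      }))
    } else character(0)
    c(path, kid_paths)
  }
  rec(project, "")
}

#' Enumerate every file in a project as a tibble
#'
#' Walks the hierarchy depth-first in store order and returns one row per
#' file record, with its container path and the labels of the enclosing
#' subject/session where applicable.
#'
#' @param project A `bc_project`.
#' @return A tibble with columns `container_path`, `subject_label`,
#'   `session_label`, `acquisition_label`, `file_name`, `kind`, `has_bids`.
#' @export
walk_files <- function(project) {
  rows <- list()
  for (path in container_paths(project)) {
    node <- get_container(project, path)
    parts <- split_container_path(path)
    sub_l <- if (length(parts) >= 2) parts[[2]] else NA_character_
    ses_l <- if (length(parts) >= 4) parts[[4]] else NA_character_
    acq_l <- if (length(parts) >= 6) parts[[6]] else NA_character_
    for (f in node$files) {
      rows[[length(rows) + 1]] <- tibble(
        container_path = path, subject_label = sub_l, session_label = ses_l,
        acquisition_label = acq_l, file_name = f$name, kind = f$kind,
        has_bids = NS_BIDS %in% names(f$info)
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(container_path = character(), subject_label = character(),
                  session_label = character(), acquisition_label = character(),
                  file_name = character(), kind = character(), has_bids = logical()))
  }
  bind_rows(rows)
}

get_file <- function(container, file_name) {
  hit <- which(map_chr(container$files, "name") == file_name)
  if (length(hit) != 1) return(NULL)
  container$files[[hit]]
}

## ---- JSON (de)serialization -------------------------------------------------

# Fixed field order + jsonlite defaults give byte-stable documents.
file_to_doc <- function(f) {
  list(name = f$name, kind = f$kind, info = f$info,
       content_ref = f$content_ref, content = f$content)
}

doc_to_file <- function(d) {
  new_file(d$name, d$kind, info = d$info %||% list(),
           content_ref = d$content_ref, content = d$content)
}

analysis_to_doc <- function(a) {
  list(label = a$label, gear_name = a$gear_name, gear_version = a$gear_version,
       status = a$status, started = a$started, finished = a$finished,
       runtime_seconds = a$runtime_seconds, parent_ref = a$parent_ref,
       outputs = map(a$outputs, file_to_doc))
}

doc_to_analysis <- function(d, parent_ref) {
  new_analysis(d$label, d$gear_name, d$gear_version, d$status,
               d$started, d$finished, runtime_seconds = d$runtime_seconds,
               parent_ref = parent_ref, outputs = map(d$outputs, doc_to_file))
}

write_doc <- function(x, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", na = "null",
                           digits = NA, pretty = 2)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

read_doc <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = FALSE)
}

canonical_json <- function(x) {
  if (inherits(x, "bc_project")) x <- unclass_record(x)
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", na = "null",
                                digits = NA))
}

unclass_record <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, unclass_record)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Structural equality of two project records
#'
#' Field-by-field comparison through a canonical JSON form, so that integer
#' versus double storage of the same number does not break equality.
#'
#' @param a,b `bc_project` records.
#' @return `TRUE` or `FALSE`.
#' @export
projects_equal <- function(a, b) {
  identical(canonical_json(unclass_record(a)), canonical_json(unclass_record(b)))
}

## ---- persistence ------------------------------------------------------------

analysis_doc_name <- function(i, label) {
  sprintf("%03d_%s.json", i, gsub("[^A-Za-z0-9._-]", "-", label))
}

#' Persist a project to a directory store
#'
#' Writes one index document per container in a mirrored directory tree
#' (`project.json`, `subjects/<label>/subject.json`, ...), analysis documents
#' under their parent container's path, and payload bytes under `files/`.
#' Output is deterministic: saving the same record twice yields byte-identical
#' stores.
#'
#' @param project A `bc_project`.
#' @param root Destination directory; defaults to the root the project was
#'   loaded from.
#' @return Invisibly, a tibble manifest of written relative paths with a
#'   `type` column (`"document"` or `"payload"`).
#' @export
save_project <- function(project, root = project_root(project)) {
  if (is.null(root)) abort("no destination root given", class = "bc_io_error")
  source_root <- project_root(project)
  payloads <- collect_payloads(project, source_root)
  dir.create(root, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(root) || file.access(root, 2) != 0) {
    abort(sprintf("root '%s' is not writable", root), class = "bc_io_error")
  }
  # wipe managed subtrees so cleared/removed records leave no stale documents
  unlink(file.path(root, c("project.json", "subjects", "files")), recursive = TRUE)

  manifest <- list()
  emit <- function(rel, type) manifest[[length(manifest) + 1]] <<- tibble(path = rel, type = type)

  write_container <- function(node, rel_dir, doc_name, child_field) {
    doc <- list(label = node$label, metadata = node$metadata,
                files = map(node$files, file_to_doc))
    if (length(child_field) == 1) {
      doc[[paste0(sub("s$", "", child_field), "_labels")]] <-
        map(node[[child_field]], "label")
    }
    doc$analyses <- imap(node$analyses, function(a, i) analysis_doc_name(i, a$label))
    rel <- file.path(rel_dir, doc_name)
    write_doc(doc, file.path(root, rel))
    emit(if (rel_dir == ".") doc_name else rel, "document")
    iwalk(node$analyses, function(a, i) {
      arel <- file.path(rel_dir, "analyses", analysis_doc_name(i, a$label))
      adoc <- analysis_to_doc(a)
      adoc$parent_ref <- if (rel_dir == ".") "" else rel_dir
      write_doc(adoc, file.path(root, arel))
      emit(sub("^\\./", "", arel), "document")
    })
    if (length(child_field) == 1) {
      walk(node[[child_field]], function(kid) {
        kdir <- file.path(if (rel_dir == ".") child_field else file.path(rel_dir, child_field),
                          safe_segment(kid$label))
        write_container(kid, kdir,
                        paste0(sub("s$", "", child_field_name(kid)), ".json"),
                        child_field_of(kid))
      })
    }
  }
  write_container(project, ".", "project.json", "subjects")

  for (ref in names(payloads)) {
    dest <- file.path(root, ref)
    dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
    writeBin(payloads[[ref]], dest)
    emit(ref, "payload")
  }
  out <- if (length(manifest)) bind_rows(manifest) else tibble(path = character(), type = character())
  invisible(out)
}

child_field_name <- function(node) {
  switch(class(node)[[1]],
         bc_project = "projects", bc_subject = "subjects",
         bc_session = "sessions", bc_acquisition = "acquisitions")
}

collect_payloads <- function(project, source_root) {
  out <- list()
  for (path in container_paths(project)) {
    node <- get_container(project, path)
    for (f in node$files) {
      if (is.null(f$content_ref)) next
      if (!is.null(f$content)) {
        out[[f$content_ref]] <- charToRaw(f$content)
      } else {
        src <- if (!is.null(source_root)) file.path(source_root, f$content_ref) else NULL
        if (is.null(src) || !file.exists(src)) {
          abort(sprintf("missing payload bytes for '%s' (%s)", f$name,
                        f$content_ref %||% "no ref"),
                class = "bc_io_error")
        }
        out[[f$content_ref]] <- readBin(src, "raw", file.info(src)$size)
      }
    }
  }
  out
}

#' Load a project from a directory store
#'
#' Reads the index documents written by [save_project()] and materializes the
#' full hierarchy. Unknown metadata keys are preserved verbatim; analysis
#' runtimes are derived from timestamps when the stored document lacks them.
#'
#' @param root Store directory containing `project.json`.
#' @return A `bc_project` with the store root attached as an attribute.
#' @export
load_project <- function(root) {
  index <- file.path(root, "project.json")
  if (!file.exists(index)) {
    abort(sprintf("no project index at '%s'", index), class = "bc_load_error")
  }
  read_container <- function(rel_dir, doc_name, level) {
    doc <- read_doc(file.path(root, rel_dir, doc_name))
    files <- map(doc$files, doc_to_file)
    parent_ref <- if (rel_dir == ".") "" else rel_dir
    analyses <- map(doc$analyses, function(aname) {
      doc_to_analysis(read_doc(file.path(root, rel_dir, "analyses", aname)), parent_ref)
    })
    kids <- switch(level,
      project = map(doc$subject_labels, function(l) {
        read_container(file.path(if (rel_dir == ".") "subjects" else file.path(rel_dir, "subjects"), l),
                       "subject.json", "subject")
      }),
      subject = map(doc$session_labels, function(l) {
        read_container(file.path(rel_dir, "sessions", l), "session.json", "session")
      }),
      session = map(doc$acquisition_labels, function(l) {
        read_container(file.path(rel_dir, "acquisitions", l), "acquisition.json", "acquisition")
      }),
      acquisition = NULL
    )
    switch(level,
      project = new_project(doc$label, doc$metadata %||% list(), kids, files, analyses),
      subject = new_subject(doc$label, doc$metadata %||% list(), kids, files, analyses),
      session = new_session(doc$label, doc$metadata %||% list(), kids, files, analyses),
      acquisition = new_acquisition(doc$label, doc$metadata %||% list(), files, analyses)
    )
  }
  project <- read_container(".", "project.json", "project")
  attr(project, "root") <- root
  project
}

## ---- queries and metadata writes -------------------------------------------

#' Select sessions by subject/session label filters
#'
#' With no filters every session is returned, in store order. Filters
#' intersect: a session is kept when its subject label is in
#' `subject_labels` (if given) and its own label is in `session_labels`
#' (if given). Unknown labels yield an empty selection plus a warning.
#'
#' @param project A `bc_project`.
#' @param subject_labels,session_labels Optional character filters.
#' @return A list of `bc_session` records, each carrying `subject_label` and
#'   `path` attributes locating it in the project.
#' @export
select_sessions <- function(project, subject_labels = NULL, session_labels = NULL) {
  known_subjects <- map_chr(project$subjects, "label")
  if (!is.null(subject_labels)) {
    missing <- setdiff(subject_labels, known_subjects)
    if (length(missing)) {
      warn(sprintf("unknown subject label(s): %s", paste(missing, collapse = ", ")))
    }
  }
  out <- list()
  seen_sessions <- character(0)
  for (sub in project$subjects) {
    if (!is.null(subject_labels) && !(sub$label %in% subject_labels)) next
    for (ses in sub$sessions) {
      seen_sessions <- c(seen_sessions, ses$label)
      if (!is.null(session_labels) && !(ses$label %in% session_labels)) next
      attr(ses, "subject_label") <- sub$label
      attr(ses, "path") <- sprintf("subjects/%s/sessions/%s", sub$label, ses$label)
      out[[length(out) + 1]] <- ses
    }
  }
  if (!is.null(session_labels)) {
    missing <- setdiff(session_labels, seen_sessions)
    if (length(missing)) {
      warn(sprintf("unknown session label(s): %s", paste(missing, collapse = ", ")))
    }
  }
  out
}

#' Write or delete one metadata namespace on a file
#'
#' Replaces exactly the named namespace of the file's `info` map, leaving all
#' other namespaces untouched. The `dicom_header` namespace is ground truth
#' and can never be written or deleted.
#'
#' @param project A `bc_project`.
#' @param container_path Path of the container holding the file.
#' @param file_name File name within the container.
#' @param namespace Namespace key to replace.
#' @param record Named list to store, or `NULL` to delete the namespace.
#' @return The updated `bc_project`.
#' @export
set_file_info <- function(project, container_path, file_name, namespace, record) {
  if (identical(namespace, NS_DICOM)) {
    abort("the 'dicom_header' namespace is immutable ground truth",
          class = "bc_permission_error")
  }
  modify_container(project, container_path, function(node) {
    hit <- which(map_chr(node$files, "name") == file_name)
    if (length(hit) != 1) {
      abort(sprintf("no file '%s' in container '%s'", file_name, container_path),
            class = "bc_not_found_error")
    }
    f <- node$files[[hit]]
    if (is.null(record)) {
      f$info[[namespace]] <- NULL
    } else {
      f$info[[namespace]] <- as_ns_map(record)
    }
    node$files[[hit]] <- f
    node
  })
}

#' Checksum of an on-disk project store
#'
#' Combines per-file MD5 digests (with their relative paths) over the whole
#' store into one fingerprint. Used throughout the test-suite to assert that
#' read-only operations and dry runs leave the store byte-identical.
#'
#' @param root Store directory.
#' @return A single character checksum.
#' @export
store_checksum <- function(root) {
  files <- sort(list.files(root, recursive = TRUE, all.files = TRUE, full.names = FALSE))
  if (length(files) == 0) return("empty")
  sums <- tools::md5sum(file.path(root, files))
  combined <- paste(files, unname(sums), collapse = "\n", sep = ":")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(combined, tf, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

#' @export
print.bc_project <- function(x, ...) {
  n_ses <- sum(map_int(x$subjects, ~ length(.x$sessions)))
  n_acq <- sum(map_int(x$subjects, function(s) sum(map_int(s$sessions, ~ length(.x$acquisitions)))))
  cat(sprintf("<bc_project> '%s': %d subjects, %d sessions, %d acquisitions\n",
              x$label, length(x$subjects), n_ses, n_acq))
  invisible(x)
}
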