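# Export: materialize the curated project as a BIDS directory tree with
# JSON sidecars, attachments, and dataset_description.json.

#' Ensure the project carries a BIDS dataset description
#'
#' If the project metadata lacks a `dataset_description`, one is created with
#' the two required fields — `Name` (the project label) and `BIDSVersion` —
#' and flagged as auto-generated so an unfiltered [clear_bids()] can remove
#' it again. An existing description is returned untouched.
#'
#' @param project A `bc_project`.
#' @return The (possibly updated) `bc_project`; read the record itself with
#'   [dataset_description()].
#' @export
ensure_dataset_description <- function(project) {
  if (!is.null(project$metadata$dataset_description)) return(project)
  project$metadata$dataset_description <- list(Name = project$label,
                                               BIDSVersion = BIDS_VERSION)
  project$metadata$dataset_description_generated <- TRUE
  project
}

#' @rdname ensure_dataset_description
#' @export
dataset_description <- function(project) {
  project$metadata$dataset_description
}

sidecar_for <- function(header, bids) {
  sidecar <- structure(list(), names = character())
  # header-derived fields first, in seconds; MetadataExtras override them
  tr <- header_num(header %||% list(), "RepetitionTime")
  te <- header_num(header %||% list(), "EchoTime")
  if (!is.na(tr)) sidecar$RepetitionTime <- tr / 1000
  if (!is.na(te)) sidecar$EchoTime <- te / 1000
  for (k in names(bids$sidecar_extras)) sidecar[[k]] <- bids$sidecar_extras[[k]]
  if (identical(bids$folder, "fmap") && length(bids$intended_for)) {
    sidecar$IntendedFor <- as.list(unlist(bids$intended_for))
  }
  sidecar
}

#' Export the curated project as a BIDS directory tree
#'
#' Writes every NIfTI file carrying a BIDS identity to
#' `sub-<L>/ses-<L>/<folder>/<filename>` under `destination`, one JSON
#' sidecar per image (header-derived `RepetitionTime`/`EchoTime` in seconds,
#' overridden by any hardcoded extras, plus the resolved `IntendedFor` list
#' on fieldmaps), all curation attachments at their recorded BIDS paths, and
#' `dataset_description.json`. NIfTI files without a BIDS identity are
#' skipped with a warning. The store itself is read-only to this operation.
#'
#' @param project A `bc_project` loaded from a store.
#' @param destination Output directory (created if needed).
#' @param subject_labels,session_labels Optional filters.
#' @return A `bc_manifest` tibble of written relative paths with a `type`
#'   column (`image`, `sidecar`, `attachment`, `dataset_description`) and the
#'   datatype `folder` for images.
#' @export
export_bids <- function(project, destination, subject_labels = NULL,
                        session_labels = NULL) {
  root <- project_root(project)
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(destination) || file.access(destination, 2) != 0) {
    abort(sprintf("destination '%s' is not writable", destination),
          class = "bc_io_error")
  }
  manifest <- list()
  written <- character(0)
  emit <- function(rel, type, folder = NA_character_) {
    if (rel %in% written) {
      abort(sprintf("export path collision at '%s'", rel), class = "bc_export_error")
    }
    written <<- c(written, rel)
    manifest[[length(manifest) + 1]] <<- tibble(path = rel, type = type,
                                                folder = folder)
  }
  write_text <- function(rel, content) {
    out <- file.path(destination, rel)
    dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
    writeLines(content, out, useBytes = TRUE, sep = "")
  }

  desc <- dataset_description(ensure_dataset_description(project))
  write_text("dataset_description.json",
             paste0(jsonlite::toJSON(desc, auto_unbox = TRUE, pretty = 2, digits = NA), "\n"))
  emit("dataset_description.json", "dataset_description")

  write_attachment <- function(f) {
    rel <- f$info[[NS_BIDS]]$relative_path
    content <- f$content
    if (is.null(content)) {
      src <- file.path(root, f$content_ref)
      if (is.null(f$content_ref) || !file.exists(src)) {
        abort(sprintf("missing payload bytes for attachment '%s'", f$name),
              class = "bc_export_error")
      }
      content <- rawToChar(readBin(src, "raw", file.info(src)$size))
    }
    write_text(rel, content)
    emit(rel, "attachment")
  }
  for (f in project$files) {
    if (!is.null(f$info[[NS_BIDS]]$relative_path)) write_attachment(f)
  }

  for (ses in select_sessions(project, subject_labels, session_labels)) {
    ses_path <- attr(ses, "path")
    for (f in ses$files) {
      if (!is.null(f$info[[NS_BIDS]]$relative_path)) write_attachment(f)
    }
    for (acq in ses$acquisitions) {
      header <- NULL
      for (ff in acq$files) {
        if (!is.null(ff$info[[NS_DICOM]])) { header <- ff$info[[NS_DICOM]]; break }
      }
      for (f in acq$files) {
        if (f$kind != "nifti") next
        bids <- f$info[[NS_BIDS]]
        if (is.null(bids)) {
          warn(sprintf("NIfTI '%s' in %s has no BIDS identity; skipped",
                       f$name, ses_path))
          next
        }
        if (isTRUE(bids$ignore)) next
        src <- if (!is.null(f$content_ref) && !is.null(root)) {
          file.path(root, f$content_ref)
        }
        if (is.null(src) || !file.exists(src)) {
          abort(sprintf("missing payload bytes for image '%s' (%s)", f$name,
                        bids$relative_path), class = "bc_export_error")
        }
        out <- file.path(destination, bids$relative_path)
        dir.create(dirname(out), recursive = TRUE, showWarnings = FALSE)
        file.copy(src, out, overwrite = FALSE)
        emit(bids$relative_path, "image", bids$folder)
        sidecar <- sidecar_for(header, bids)
        if (length(sidecar)) {
          rel <- sub("\\.nii\\.gz$", ".json", bids$relative_path)
          write_text(rel, paste0(jsonlite::toJSON(sidecar, auto_unbox = TRUE,
                                                  pretty = 2, digits = NA), "\n"))
          emit(rel, "sidecar")
        }
      }
    }
  }
  out <- bind_rows(manifest)
  structure(out, class = c("bc_manifest", class(out)))
}

#' @export
print.bc_manifest <- function(x, ...) {
  counts <- x |> count(.data$type)
  cat(sprintf("<BIDS export manifest> %d path(s): %s\n", nrow(x),
              paste(sprintf("%s=%d", counts$type, counts$n), collapse = ", ")))
  NextMethod()
}
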