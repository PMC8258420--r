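# Curation: apply a heuristic to a project, writing resolved BIDS identities
# into the "BIDS" namespace of NIfTI files, materializing extra BIDS files,
# and supporting dry runs and clean clearing. DICOM files and their headers
# are never touched.

BIDS_VERSION <- "1.8.0"

bidsinfo_to_record <- function(b) {
  list(template_key = b$template_key, filename = b$filename, folder = b$folder,
       relative_path = b$relative_path, sidecar_extras = as_ns_map(b$sidecar_extras),
       intended_for = as.list(b$intended_for), ignore = isTRUE(b$ignore))
}

attachment_kind <- function(path) {
  if (grepl("\\.tsv$|\\.csv$", path)) "tabular"
  else if (grepl("\\.(txt|md|json)$|^README$|^CHANGES$", path)) "text"
  else "other"
}

substitute_labels <- function(x, subject_label = NULL, session_label = NULL) {
  if (!is.null(subject_label)) x <- gsub("{SubjectLabel}", subject_label, x, fixed = TRUE)
  if (!is.null(session_label)) x <- gsub("{SessionLabel}", session_label, x, fixed = TRUE)
  x
}

plan_row <- function(container_path, file_name, action, relative_path = NA_character_,
                     reason = NA_character_, payload = list(NULL)) {
  tibble(container_path = container_path, file_name = file_name, action = action,
         relative_path = relative_path, reason = reason, payload = payload)
}

# map series_id -> acquisition label + NIfTI file names, mirroring the
# series_id construction used by extract_seqinfo()
session_series_index <- function(session, subject_label) {
  rows <- list()
  for (acq in session$acquisitions) {
    header <- NULL
    for (f in acq$files) {
      if (!is.null(f$info[[NS_DICOM]])) { header <- f$info[[NS_DICOM]]; break }
    }
    if (is.null(header)) next
    nifti_names <- map_chr(keep(acq$files, ~ .x$kind == "nifti"), "name")
    rows[[length(rows) + 1]] <- list(
      series_id = sprintf("%s_%s_%d", subject_label, session$label,
                          header_int(header, "SeriesNumber")),
      acq_label = acq$label,
      nifti_names = nifti_names,
      header = header
    )
  }
  rows
}

#' Plan and apply BIDS curation of a project
#'
#' For every selected session the heuristic classifies the session's SeqInfo
#' rows into naming-template keys, resolves each match into a BIDS identity,
#' and plans a `"BIDS"`-namespace write onto the acquisition's NIfTI file.
#' `MetadataExtras` are merged into the planned sidecar fields, `IntendedFor`
#' declarations are resolved to subject-relative paths of planned images in
#' the same session, and heuristic attachments are planned at project and
#' session level. With `dry_run = TRUE` the plan is returned and the store is
#' left byte-identical; otherwise the plan is applied and persisted.
#' Re-curation overwrites an existing differing BIDS identity (with an
#' informative message), so curation can be repeated or updated at any time;
#' applying the same heuristic twice is a no-op on the store.
#'
#' @param project A `bc_project` loaded from a store.
#' @param spec A `bc_heuristic` from [load_heuristic()].
#' @param subject_labels,session_labels Optional filters.
#' @param dry_run Evaluate without mutating the store?
#' @return A `bc_plan` tibble (one row per planned change: `container_path`,
#'   `file_name`, `action`, `relative_path`, `reason`, `payload`), with the
#'   updated project in attribute `"project"` when applied.
#' @export
curate_project <- function(project, spec, subject_labels = NULL,
                           session_labels = NULL, dry_run = FALSE) {
  sessions <- select_sessions(project, subject_labels, session_labels)
  plan <- list()

  for (ses in sessions) {
    raw_sub <- attr(ses, "subject_label")
    seqinfo <- extract_seqinfo(ses, raw_sub)
    assignments <- classify_series(spec, seqinfo)
    if (length(assignments) == 0 && length(ses$acquisitions) == 0) next
    sub_l <- transform_label(spec, raw_sub, "subject")
    ses_l <- transform_label(spec, ses$label, "session")
    index <- session_series_index(ses, raw_sub)
    index_ids <- map_chr(index, "series_id")
    ses_path <- attr(ses, "path")

    ses_rows <- list()
    for (key in names(assignments)) {
      ids <- assignments[[key]]
      for (i in seq_along(ids)) {
        info <- index[[match(ids[[i]], index_ids)]]
        acq_path <- sprintf("%s/acquisitions/%s", ses_path, info$acq_label)
        if (length(info$nifti_names) == 0) {
          ses_rows[[length(ses_rows) + 1]] <- plan_row(
            acq_path, NA_character_, "skip",
            reason = sprintf("acquisition '%s' has a DICOM header but no NIfTI file",
                             info$acq_label))
          next
        }
        bids <- resolve_bids_name(spec$templates[[key]], sub_l, ses_l,
                                  item = i, n_items = length(ids),
                                  template_key = key)
        bids$sidecar_extras <- as_ns_map(spec$metadata_extras[[key]] %||% list())
        ses_rows[[length(ses_rows) + 1]] <- plan_row(
          acq_path, info$nifti_names[[1]], "set_bids",
          relative_path = bids$relative_path, payload = list(bids))
        for (extra in info$nifti_names[-1]) {
          ses_rows[[length(ses_rows) + 1]] <- plan_row(
            acq_path, extra, "skip",
            reason = "additional NIfTI in acquisition left unnamed")
        }
      }
    }

    # IntendedFor: match planned images in this session by template string
    if (length(spec$intended_for) && length(ses_rows)) {
      key_of <- map_chr(ses_rows, function(r) {
        if (r$action == "set_bids") r$payload[[1]]$template_key else NA_character_
      })
      for (fkey in names(spec$intended_for)) {
        targets <- spec$intended_for[[fkey]]
        target_keys <- names(spec$templates)[spec$templates %in% targets]
        target_paths <- map_chr(
          keep(ses_rows, function(r) r$action == "set_bids" &&
                 r$payload[[1]]$template_key %in% target_keys),
          function(r) sub(sprintf("^sub-%s/", sub_l), "", r$payload[[1]]$relative_path))
        if (length(target_paths) == 0) next
        for (j in which(key_of == fkey)) {
          ses_rows[[j]]$payload[[1]]$intended_for <- as.list(target_paths)
        }
      }
    }

    # session-level attachments
    for (att in spec$session_attachments) {
      path <- substitute_labels(att$path, sub_l, ses_l)
      content <- substitute_labels(att$content %||% "", sub_l, ses_l)
      ses_rows[[length(ses_rows) + 1]] <- plan_row(
        ses_path, gsub("/", "__", path), "attach_file", relative_path = path,
        payload = list(list(relative_path = path, content = content)))
    }
    plan <- c(plan, ses_rows)
  }

  for (att in spec$project_attachments) {
    if (length(template_placeholders(att$path))) {
      abort(sprintf("project attachment path '%s' may not use placeholders", att$path),
            class = "bc_curation_error")
    }
    plan[[length(plan) + 1]] <- plan_row(
      "", gsub("/", "__", att$path), "attach_file", relative_path = att$path,
      payload = list(list(relative_path = att$path, content = att$content %||% "")))
  }

  plan_tbl <- if (length(plan)) bind_rows(plan) else
    plan_row(character(0), character(0), character(0))[0, ]

  paths <- plan_tbl$relative_path[!is.na(plan_tbl$relative_path)]
  if (anyDuplicated(paths)) {
    dup <- unique(paths[duplicated(paths)])
    srcs <- plan_tbl |>
      filter(.data$relative_path %in% dup) |>
      mutate(src = paste0(.data$container_path, ":", .data$file_name))
    abort(sprintf("curation plan resolves several files to the same path(s): %s [%s]",
                  paste(dup, collapse = ", "), paste(srcs$src, collapse = "; ")),
          class = "bc_curation_error")
  }

  applied <- project
  if (!isTRUE(dry_run)) {
    applied <- apply_plan(project, plan_tbl)
    save_project(applied)
    inform(sprintf("applied %d change(s) to '%s'",
                   sum(plan_tbl$action != "skip"), project_root(project) %||% "<memory>"))
  }
  structure(plan_tbl, class = c("bc_plan", class(plan_tbl)),
            dry_run = isTRUE(dry_run), project = applied)
}

apply_plan <- function(project, plan_tbl) {
  p <- ensure_dataset_description(project)
  for (i in seq_len(nrow(plan_tbl))) {
    row <- plan_tbl[i, ]
    if (row$action == "set_bids") {
      existing <- get_file(get_container(p, row$container_path), row$file_name)
      new_rec <- bidsinfo_to_record(row$payload[[1]])
      old_rec <- existing$info[[NS_BIDS]]
      if (!is.null(old_rec) && !identical(canonical_json(old_rec), canonical_json(new_rec))) {
        inform(sprintf("re-curation overwrites BIDS identity of %s/%s: %s -> %s",
                       row$container_path, row$file_name,
                       old_rec$relative_path %||% "?", new_rec$relative_path))
      }
      p <- set_file_info(p, row$container_path, row$file_name, NS_BIDS, new_rec)
    } else if (row$action == "attach_file") {
      p <- attach_one(p, row$container_path, row$file_name, row$payload[[1]])
    }
  }
  p
}

attach_one <- function(project, container_path, file_name, att) {
  modify_container(project, container_path, function(node) {
    ref_dir <- file.path("files", "attachments",
                         if (nzchar(container_path)) gsub("/", "_", container_path) else "project")
    rec <- new_file(file_name, attachment_kind(att$relative_path),
                    info = list(BIDS = list(relative_path = att$relative_path,
                                            generated_by_curation = TRUE)),
                    content_ref = file.path(ref_dir, file_name),
                    content = att$content)
    hit <- which(map_chr(node$files, "name") == file_name)
    if (length(hit) == 1) {
      old <- node$files[[hit]]
      if (!isTRUE(old$info[[NS_BIDS]]$generated_by_curation)) {
        abort(sprintf("attachment '%s' collides with an existing non-generated file",
                      file_name), class = "bc_curation_error")
      }
      node$files[[hit]] <- rec
    } else {
      node$files[[length(node$files) + 1]] <- rec
    }
    node
  })
}

#' Attach the heuristic's extra BIDS files
#'
#' Materializes `AttachToProject` entries on the project container and
#' `AttachToSession` entries on each selected session, recording each file's
#' relative BIDS path (and a curation marker, so [clear_bids()] can remove
#' exactly what curation added) in its metadata. Changes are persisted.
#'
#' @inheritParams curate_project
#' @return A tibble of attached files (`container_path`, `file_name`,
#'   `relative_path`).
#' @export
attach_extra_files <- function(project, spec, subject_labels = NULL,
                               session_labels = NULL) {
  p <- project
  rows <- list()
  image_paths <- curated_relative_paths(project)
  add <- function(container_path, att, sub_l = NULL, ses_l = NULL) {
    path <- substitute_labels(att$relative_path %||% att$path, sub_l, ses_l)
    content <- substitute_labels(att$content %||% "", sub_l, ses_l)
    if (path %in% image_paths) {
      abort(sprintf("attachment path '%s' collides with a curated image path", path),
            class = "bc_curation_error")
    }
    p <<- attach_one(p, container_path, gsub("/", "__", path),
                     list(relative_path = path, content = content))
    rows[[length(rows) + 1]] <<- tibble(container_path = container_path,
                                        file_name = gsub("/", "__", path),
                                        relative_path = path)
  }
  for (att in spec$project_attachments) add("", att)
  for (ses in select_sessions(p, subject_labels, session_labels)) {
    sub_l <- transform_label(spec, attr(ses, "subject_label"), "subject")
    ses_l <- transform_label(spec, ses$label, "session")
    for (att in spec$session_attachments) add(attr(ses, "path"), att, sub_l, ses_l)
  }
  if (length(rows)) save_project(p)
  out <- if (length(rows)) bind_rows(rows) else
    tibble(container_path = character(), file_name = character(),
           relative_path = character())
  attr(out, "project") <- p
  out
}

curated_relative_paths <- function(project) {
  out <- character(0)
  for (path in container_paths(project)) {
    node <- get_container(project, path)
    for (f in node$files) {
      rp <- f$info[[NS_BIDS]]$relative_path
      if (!is.null(rp)) out <- c(out, rp)
    }
  }
  out
}

#' Clear BIDS curation cleanly and safely
#'
#' Removes the `"BIDS"` namespace from every selected NIfTI file and deletes
#' the attachments that curation generated (identified by their marker), so
#' that clearing after curating restores the pre-curation store byte for
#' byte. Project-level attachments and an auto-generated dataset description
#' are removed only when no subject/session filter is given. All other
#' metadata is untouched.
#'
#' @inheritParams curate_project
#' @return The number of BIDS namespaces and generated attachments removed.
#' @export
clear_bids <- function(project, subject_labels = NULL, session_labels = NULL) {
  p <- project
  count <- 0L
  strip_generated_files <- function(container_path) {
    node <- get_container(p, container_path)
    for (f in node$files) {
      if (isTRUE(f$info[[NS_BIDS]]$generated_by_curation)) {
        p <<- modify_container(p, container_path, function(n) {
          n$files <- discard(n$files, ~ .x$name == f$name)
          n
        })
        count <<- count + 1L
      }
    }
  }
  for (ses in select_sessions(p, subject_labels, session_labels)) {
    ses_path <- attr(ses, "path")
    for (acq in ses$acquisitions) {
      acq_path <- sprintf("%s/acquisitions/%s", ses_path, acq$label)
      for (f in acq$files) {
        if (f$kind == "nifti" && NS_BIDS %in% names(f$info)) {
          p <- set_file_info(p, acq_path, f$name, NS_BIDS, NULL)
          count <- count + 1L
        }
      }
    }
    strip_generated_files(ses_path)
  }
  if (is.null(subject_labels) && is.null(session_labels)) {
    strip_generated_files("")
    if (isTRUE(p$metadata$dataset_description_generated)) {
      p$metadata$dataset_description <- NULL
      p$metadata$dataset_description_generated <- NULL
    }
  }
  if (count > 0 || isTRUE(project$metadata$dataset_description_generated)) {
    save_project(p)
  }
  count
}

#' @export
print.bc_plan <- function(x, ...) {
  cat(sprintf("<curation plan> %d change(s)%s\n", nrow(x),
              if (isTRUE(attr(x, "dry_run"))) " [dry run]" else ""))
  NextMethod()
}
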