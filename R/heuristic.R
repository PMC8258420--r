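# The heuristic rule file: an executable R script declaring BIDS naming
# templates as character variables plus a classify() function mapping SeqInfo
# rows to template keys, with reserved identifiers for label transforms,
# hardcoded sidecar metadata, fieldmap IntendedFor wiring, and attachments.

RESERVED_NAMES <- c("classify", "ReplaceSubject", "ReplaceSession",
                    "MetadataExtras", "IntendedFor",
                    "AttachToProject", "AttachToSession")

# committed suffix -> BIDS datatype folder table
SUFFIX_FOLDERS <- c(
  T1w = "anat", T2w = "anat", FLAIR = "anat",
  bold = "func", sbref = "func",
  dwi = "dwi",
  epi = "fmap", magnitude = "fmap", phasediff = "fmap", fieldmap = "fmap"
)

KNOWN_PLACEHOLDERS <- c("SubjectLabel", "SessionLabel", "item")

template_placeholders <- function(template) {
  m <- gregexpr("\\{([A-Za-z]+)\\}", template)[[1]]
  if (m[1] == -1) return(character(0))
  unique(gsub("[{}]", "", regmatches(template, gregexpr("\\{[A-Za-z]+\\}", template))[[1]]))
}

check_template <- function(key, template) {
  bad <- setdiff(template_placeholders(template), KNOWN_PLACEHOLDERS)
  if (length(bad)) {
    abort(sprintf("template '%s' references unknown placeholder(s): %s",
                  key, paste(bad, collapse = ", ")),
          class = "bc_heuristic_error")
  }
  invisible(template)
}

#' Load a heuristic rule file
#'
#' The heuristic is a plain R script evaluated in an isolated environment.
#' Every top-level character-scalar assignment declares a BIDS naming
#' template (its variable name is the template key); declaration order is
#' retained and breaks ties when a series matches several keys. Reserved
#' identifiers, all optional except `classify`:
#'
#' * `classify(seqinfo)` — required; takes the SeqInfo tibble of one session
#'   and returns a named list mapping template keys to `series_id` vectors.
#' * `ReplaceSubject`, `ReplaceSession` — pure label -> label functions applied
#'   before sanitization.
#' * `MetadataExtras` — named list mapping a template key to hardcoded JSON
#'   sidecar fields.
#' * `IntendedFor` — named list mapping a fieldmap template key to the
#'   template strings of the images the fieldmap corrects.
#' * `AttachToProject`, `AttachToSession` — lists of
#'   `list(path =, content =)` extra BIDS files (README, participants TSV,
#'   events TSV, ...); session attachment paths/contents may use the
#'   `{SubjectLabel}`/`{SessionLabel}` placeholders.
#'
#' @param path Path to the heuristic file.
#' @return A `bc_heuristic` specification.
#' @export
load_heuristic <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("heuristic file '%s' not found", path), class = "bc_heuristic_error")
  }
  env <- new.env(parent = globalenv())
  exprs <- parse(path)
  template_order <- character(0)
  for (ex in exprs) {
    eval(ex, env)
    if (is.call(ex) && as.character(ex[[1]]) %in% c("<-", "=")) {
      nm <- as.character(ex[[2]])
      val <- get0(nm, envir = env, inherits = FALSE)
      if (!nm %in% RESERVED_NAMES && is.character(val) && length(val) == 1) {
        template_order <- union(template_order, nm)
      }
    }
  }
  templates <- vapply(template_order, function(nm) get(nm, envir = env),
                      character(1))
  for (key in names(templates)) check_template(key, templates[[key]])

  classify <- get0("classify", envir = env, inherits = FALSE)
  if (!is.function(classify)) {
    abort("heuristic must define a classify(seqinfo) function",
          class = "bc_heuristic_error")
  }
  intended_for <- get0("IntendedFor", envir = env, inherits = FALSE) %||% list()
  for (key in names(intended_for)) {
    targets <- unlist(intended_for[[key]])
    undeclared <- setdiff(targets, unname(templates))
    if (length(undeclared)) {
      abort(sprintf("IntendedFor['%s'] targets undeclared template string(s): %s",
                    key, paste(undeclared, collapse = ", ")),
            class = "bc_heuristic_error")
    }
  }
  structure(
    list(
      templates = templates,
      classify = classify,
      replace_subject = get0("ReplaceSubject", envir = env, inherits = FALSE),
      replace_session = get0("ReplaceSession", envir = env, inherits = FALSE),
      metadata_extras = get0("MetadataExtras", envir = env, inherits = FALSE) %||% list(),
      intended_for = lapply(intended_for, function(x) as.character(unlist(x))),
      project_attachments = get0("AttachToProject", envir = env, inherits = FALSE) %||% list(),
      session_attachments = get0("AttachToSession", envir = env, inherits = FALSE) %||% list(),
      path = path
    ),
    class = "bc_heuristic"
  )
}

#' Classify SeqInfo rows into naming-template keys
#'
#' Runs the heuristic's Boolean classification rule and normalizes its
#' output: keys must be declared templates, a series lands under at most one
#' key (first-declared key wins, with a warning), and within a key series are
#' ordered by ascending series number. Unmatched series are simply absent.
#'
#' @param spec A `bc_heuristic`.
#' @param seqinfo SeqInfo tibble, e.g. from [extract_seqinfo()].
#' @return Named list of `series_id` character vectors.
#' @export
classify_series <- function(spec, seqinfo) {
  raw <- spec$classify(seqinfo)
  if (length(raw) == 0) return(stats::setNames(list(), character(0)))
  unknown <- setdiff(names(raw), names(spec$templates))
  if (length(unknown)) {
    abort(sprintf("classify returned unknown template key(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "bc_heuristic_error")
  }
  order_by_series <- function(ids) {
    ids <- as.character(unlist(ids))
    bad <- setdiff(ids, seqinfo$series_id)
    if (length(bad)) {
      warn(sprintf("classify returned unknown series_id(s): %s; dropped",
                   paste(bad, collapse = ", ")))
      ids <- intersect(ids, seqinfo$series_id)
    }
    nums <- seqinfo$series_number[match(ids, seqinfo$series_id)]
    ids[order(nums)]
  }
  # walk keys in template-declaration order so tie-breaking is deterministic
  keys <- intersect(names(spec$templates), names(raw))
  out <- list()
  assigned <- character(0)
  for (key in keys) {
    ids <- order_by_series(raw[[key]])
    dup <- intersect(ids, assigned)
    if (length(dup)) {
      warn(sprintf("series %s matched several keys; keeping first-declared assignment",
                   paste(dup, collapse = ", ")))
      ids <- setdiff(ids, assigned)
    }
    if (length(ids)) {
      out[[key]] <- ids
      assigned <- c(assigned, ids)
    }
  }
  out
}

#' Resolve a naming template into a BIDS identity
#'
#' Substitutes `{SubjectLabel}`, `{SessionLabel}` and, when present,
#' `{item}`; derives the datatype folder from the filename suffix. When a key
#' matched several series but its template lacks `{item}`, a `run-<item>`
#' entity is inserted before the suffix so resolved paths stay unique.
#'
#' @param template Template string (e.g.
#'   `"sub-{SubjectLabel}_ses-{SessionLabel}_T1w.nii.gz"`).
#' @param subject_label,session_label Sanitized labels (see
#'   [transform_label()]).
#' @param item 1-based index of this series within its key.
#' @param n_items Number of series matched by the key.
#' @param template_key Key the template was declared under.
#' @return A `bc_bidsinfo` list: `template_key`, `filename`, `folder`,
#'   `relative_path`, `sidecar_extras`, `intended_for`, `ignore`.
#' @export
resolve_bids_name <- function(template, subject_label, session_label,
                              item = 1L, n_items = 1L, template_key = NA_character_) {
  for (l in c(subject_label, session_label)) {
    if (!grepl("^[A-Za-z0-9]+$", l)) {
      abort(sprintf("label '%s' is not alphanumeric; run transform_label() first", l),
            class = "bc_heuristic_error")
    }
  }
  filename <- template
  filename <- gsub("{SubjectLabel}", subject_label, filename, fixed = TRUE)
  filename <- gsub("{SessionLabel}", session_label, filename, fixed = TRUE)
  had_item <- grepl("{item}", template, fixed = TRUE)
  if (had_item) {
    filename <- gsub("{item}", as.character(item), filename, fixed = TRUE)
  } else if (n_items > 1) {
    filename <- sub("_([A-Za-z0-9]+)(\\.nii\\.gz)$",
                    sprintf("_run-%d_\\1\\2", item), filename)
  }
  leftover <- template_placeholders(filename)
  if (length(leftover)) {
    abort(sprintf("unresolved placeholder(s) in '%s': %s", filename,
                  paste(leftover, collapse = ", ")),
          class = "bc_heuristic_error")
  }
  suffix <- sub("^.*_([A-Za-z0-9]+)\\.nii\\.gz$", "\\1", filename)
  folder <- unname(SUFFIX_FOLDERS[suffix])
  if (is.na(folder)) {
    warn(sprintf("suffix '%s' has no committed datatype folder; using 'other'", suffix))
    folder <- "other"
  }
  structure(
    list(
      template_key = template_key,
      filename = filename,
      folder = folder,
      relative_path = sprintf("sub-%s/ses-%s/%s/%s",
                              subject_label, session_label, folder, filename),
      sidecar_extras = structure(list(), names = character()),
      intended_for = list(),
      ignore = FALSE
    ),
    class = "bc_bidsinfo"
  )
}

#' Transform and sanitize a container label for BIDS use
#'
#' Applies the heuristic's optional `ReplaceSubject`/`ReplaceSession`
#' transform, then strips every non-alphanumeric character (BIDS entity
#' labels admit nothing else).
#'
#' @param spec A `bc_heuristic`.
#' @param raw_label The container label.
#' @param which `"subject"` or `"session"`.
#' @return The sanitized label.
#' @export
transform_label <- function(spec, raw_label, which = c("subject", "session")) {
  which <- match.arg(which)
  fn <- switch(which, subject = spec$replace_subject, session = spec$replace_session)
  lab <- if (is.function(fn)) fn(raw_label) else raw_label
  lab <- gsub("[^A-Za-z0-9]", "", as.character(lab))
  if (!length(lab) || !nzchar(lab)) {
    abort(sprintf("%s label '%s' is empty after transformation and sanitization",
                  which, raw_label),
          class = "bc_heuristic_error")
  }
  lab
}
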