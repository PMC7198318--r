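#' Canonical encoding of a database view
#'
#' Encodes the membership of a view as a deterministic string: the sorted,
#' deduplicated member node ids joined by `"|"`.  Two views with equal
#' member sets encode identically regardless of construction order, which
#' is what lets the change detector compare a stored snapshot with a
#' freshly collected view.
#'
#' @param view A [collect_view()] result, or a character vector of member
#'   node ids.
#' @return A single string.
#' @export
encode_view <- function(view) {
  members <- if (inherits(view, "view_content")) view$members else view
  members <- sort(unique(as.character(members)))
  if (length(members) == 0L) {
    stop_citesum("cannot encode an empty view", "citesum_bad_input")
  }
  paste(members, collapse = "|")
}

#' Snapshot ledger entry for a published summary
#'
#' The persisted record that decides whether a view needs a new summary:
#' the database version at generation time, the authorship snapshot, the
#' outgoing-reference snapshot, and the canonical view encoding, together
#' with the summary's own version label.
#'
#' @param view_id Root node id of the view.
#' @param db_version Database version label at generation time.
#' @param authors Character vector of author ids on the summary.
#' @param ref_ids Character vector of reference ids on the summary.
#' @param view_encoding Canonical encoding from [encode_view()].
#' @param summary_version Version label of the summary.
#' @return An object of class `ledger_entry`.
#' @export
ledger_entry <- function(view_id, db_version, authors, ref_ids,
                         view_encoding, summary_version) {
  structure(
    list(
      view_id = as.character(view_id),
      db_version = as.character(db_version),
      authors = as_author_set(authors),
      ref_ids = sort(unique(as.character(ref_ids))),
      view_encoding = as.character(view_encoding),
      summary_version = as.character(summary_version)
    ),
    class = "ledger_entry"
  )
}

#' Build the ledger entry recorded for a rendered summary
#'
#' @param s A [render_summary()] result.
#' @return A [ledger_entry()].
#' @export
summary_ledger_entry <- function(s) {
  stopifnot(inherits(s, "citation_summary"))
  ledger_entry(
    view_id = s$view$root,
    db_version = s$db_version,
    authors = s$authors,
    ref_ids = s$references$ref_id,
    view_encoding = encode_view(s$view),
    summary_version = s$version
  )
}

#' Decide whether a view needs a regenerated summary
#'
#' A new summary is needed exactly when something a citation graph cares
#' about changed since the stored snapshot: the author set, the outgoing
#' reference set, or the view membership itself.  Description or other
#' content edits alone are deemed insignificant and never trigger on their
#' own; curators can override with `force` (e.g. for a substantial content
#' change).
#'
#' @param prev A [ledger_entry()] for the most recent published summary.
#' @param view The freshly collected [collect_view()] for the same view id.
#' @param force Regenerate regardless of detected changes?
#' @return A list with `decision` (logical) and `reasons` (character vector
#'   among `authors_changed`, `references_changed`, `membership_changed`,
#'   `forced`).
#' @export
needs_new_summary <- function(prev, view, force = FALSE) {
  stopifnot(inherits(prev, "ledger_entry"), inherits(view, "view_content"))
  if (!identical(prev$view_id, view$root)) {
    stop_citesum(paste0("ledger entry is for view ", prev$view_id,
                        " but the collected view is rooted at ", view$root),
                 "citesum_view_mismatch")
  }
  reasons <- character(0)
  if (!setequal(prev$authors, view$authors)) {
    reasons <- c(reasons, "authors_changed")
  }
  if (!setequal(prev$ref_ids, view$references$ref_id)) {
    reasons <- c(reasons, "references_changed")
  }
  if (!identical(prev$view_encoding, encode_view(view))) {
    reasons <- c(reasons, "membership_changed")
  }
  if (force) reasons <- c(reasons, "forced")
  list(decision = length(reasons) > 0L, reasons = reasons)
}

#' Next summary version label
#'
#' Versions form a strictly increasing sequence.  The `"integer"` scheme
#' counts `"1", "2", ...`; the `"dotted"` scheme increments the final
#' numeric component of a database-coupled label (`"2020.1"` becomes
#' `"2020.2"`).
#'
#' @param prev Previous label, or `NULL` for the first version.
#' @param scheme `"integer"` (default) or `"dotted"`.
#' @return The next label as a string.
#' @export
next_version <- function(prev = NULL, scheme = c("integer", "dotted")) {
  scheme <- match.arg(scheme)
  if (is.null(prev) || is.na(prev) || !nzchar(prev)) return("1")
  prev <- as.character(prev)
  if (scheme == "integer") {
    if (!grepl("^[0-9]+$", prev)) {
      stop_citesum(paste0("malformed version label: ", prev),
                   "citesum_bad_version")
    }
    as.character(as.integer(prev) + 1L)
  } else {
    if (!grepl("^[0-9]+(\\.[0-9]+)+$", prev)) {
      stop_citesum(paste0("malformed dotted version label: ", prev),
                   "citesum_bad_version")
    }
    parts <- strsplit(prev, ".", fixed = TRUE)[[1L]]
    parts[length(parts)] <- as.character(as.integer(parts[length(parts)]) + 1L)
    paste(parts, collapse = ".")
  }
}

#' Read and write the offline ledger file
#'
#' The ledger mirrors, as local JSON keyed by view id, the snapshot payload
#' that [render_metadata()] also embeds in each published record.
#'
#' @param path Path to the JSON ledger file.
#' @return `read_ledger()` returns a named list of [ledger_entry()] objects.
#' @export
read_ledger <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(raw, function(e) {
    ledger_entry(e$view_id, e$db_version, e$authors %||% character(0),
                 e$ref_ids %||% character(0), e$view_encoding,
                 e$summary_version)
  })
  names(out) <- vapply(out, `[[`, character(1), "view_id")
  out
}

#' @rdname read_ledger
#' @param entries A list of [ledger_entry()] objects.
#' @export
write_ledger <- function(entries, path) {
  if (inherits(entries, "ledger_entry")) entries <- list(entries)
  names(entries) <- vapply(entries, `[[`, character(1), "view_id")
  payload <- lapply(entries, function(e) {
    list(view_id = e$view_id, db_version = e$db_version,
         authors = e$authors, ref_ids = e$ref_ids,
         view_encoding = e$view_encoding,
         summary_version = e$summary_version)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
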