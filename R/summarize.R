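#' Collect the content of a citable view
#'
#' Materialises the view rooted at a node: its member nodes (deterministic
#' depth-first order), the merged author list, and the union of the members'
#' outgoing references, deduplicated by reference id and ordered by year,
#' first author, then title.  Merged authors are ordered by how many member
#' nodes each contributed to (descending), ties broken by name, so the
#' ordering is reproducible.
#'
#' @param h A [hierarchy()] with contributors and references merged.
#' @param root Node id of the view root.
#' @param include_objects Include object-level members?
#' @param author_fallback When no member node carries authors: `"union"` is
#'   meaningless here (the union is empty), so `"error"` (default) refuses
#'   to build an unattributable view.
#' @return An object of class `view_content`: `root`, `members`, `authors`,
#'   `author_counts`, `references` (a data frame of reference records),
#'   `abstract_text`, `links`.
#' @export
collect_view <- function(h, root, include_objects = TRUE,
                         author_fallback = c("error", "none")) {
  stopifnot(inherits(h, "hierarchy"))
  author_fallback <- match.arg(author_fallback)
  members <- descendants(h, root, include_objects = include_objects)

  counts <- table(unlist(h$authors[members], use.names = FALSE))
  if (length(counts) == 0L && author_fallback == "error") {
    stop_citesum(paste0("view at ", root, " has no authors"),
                 "citesum_empty_authors")
  }
  ord <- order(-as.integer(counts), names(counts))
  authors <- names(counts)[ord]

  ref_ids <- sort(unique(unlist(h$refs[members], use.names = FALSE)))
  refs <- h$references[h$references$ref_id %in% ref_ids, , drop = FALSE]
  if (nrow(refs)) {
    first_author <- vapply(strsplit(refs$authors, ";", fixed = TRUE),
                           function(a) if (length(a)) a[[1L]] else "",
                           character(1))
    refs <- refs[order(refs$year, first_author, refs$title), , drop = FALSE]
    rownames(refs) <- NULL
  }

  desc_text <- h$nodes$description[match(root, h$nodes$node_id)]
  label <- h$nodes$label[match(root, h$nodes$node_id)]
  if (is.na(desc_text) || !nzchar(desc_text)) {
    fam_members <- members[level_kind(h, members) == "family"]
    desc_text <- paste0(
      "This summary describes the curated content of ", label,
      ", covering ", length(fam_members), " famil",
      if (length(fam_members) == 1L) "y" else "ies",
      " and ", sum(level_kind(h, members) == "object"), " objects."
    )
  }

  structure(
    list(
      root = root,
      label = label,
      members = members,
      authors = authors,
      author_counts = stats::setNames(as.integer(counts)[ord], authors),
      references = refs,
      abstract_text = desc_text,
      links = paste0("https://database.example.org/node/", members)
    ),
    class = "view_content"
  )
}

#' @export
print.view_content <- function(x, ...) {
  cat("<view_content> root", x$root, "-", length(x$members), "members,",
      length(x$authors), "authors,", nrow(x$references), "references\n")
  invisible(x)
}

summary_rationale <- function() {
  paste(
    "This document is a machine-generated citation summary of a view of a",
    "curated database. Its purpose is to create a node in citation graphs:",
    "to register the database, its contributors and its outgoing references",
    "in bibliometric measures. Readers should follow the links to the",
    "database itself for current content."
  )
}

#' Render a citation summary document for a view
#'
#' Produces the publication-shaped record that citation analyzers can index.
#' Every summary carries eight elements: a title containing the database
#' version, an author block with affiliations, an abstract, links back to
#' the database, the publisher, a fixed rationale statement, a numbered
#' outgoing-reference list, and a DOI (a deterministic placeholder unless
#' one is supplied).  Rendering is a pure function of its inputs: the same
#' view, version and publisher always produce byte-identical output.
#'
#' @param view A [collect_view()] result.
#' @param db_version Database version label; it appears verbatim in the
#'   title so that successive summaries are distinguishable.
#' @param publisher Publisher string.
#' @param summary_version Version label of this summary (see
#'   [next_version()]).
#' @param doi Optional DOI; default is a deterministic placeholder built
#'   from the view id and summary version.
#' @param affiliations Optional named character vector mapping author ids to
#'   affiliation strings.
#' @return An object of class `citation_summary` with the eight content
#'   elements plus `markdown` (the portable document) and `view` (the
#'   originating view content).
#' @export
render_summary <- function(view, db_version, publisher,
                           summary_version = "1", doi = NULL,
                           affiliations = NULL) {
  stopifnot(inherits(view, "view_content"))
  if (missing(db_version) || is.null(db_version) || !nzchar(db_version)) {
    stop_citesum("db_version is required: the title must carry it",
                 "citesum_bad_input")
  }
  if (is.null(doi)) {
    doi <- paste0("10.5555/citesum.", view$root, ".v", summary_version)
  }
  affil <- vapply(view$authors, function(a) {
    if (!is.null(affiliations) && a %in% names(affiliations)) {
      affiliations[[a]]
    } else {
      paste0("Contributor, ", publisher)
    }
  }, character(1))

  s <- structure(
    list(
      title = paste0(view$label, ": a citation summary (database version ",
                     db_version, ", summary version ", summary_version, ")"),
      authors = view$authors,
      affiliations = affil,
      abstract = view$abstract_text,
      links = view$links,
      publisher = publisher,
      rationale = summary_rationale(),
      references = view$references,
      doi = doi,
      db_version = db_version,
      version = summary_version,
      view = view
    ),
    class = "citation_summary"
  )
  s$markdown <- summary_markdown(s)
  s
}

format_reference <- function(r) {
  auth <- gsub(";", ", ", r$authors, fixed = TRUE)
  ext <- if (!is.na(r$external_id) && nzchar(r$external_id)) {
    paste0(" ", r$external_id, ".")
  } else ""
  paste0(auth, " (", r$year, "). ", r$title, ". ", r$venue, ".", ext)
}

summary_markdown <- function(s) {
  refs <- s$references
  ref_lines <- if (nrow(refs)) {
    vapply(seq_len(nrow(refs)), function(i) {
      paste0(i, ". ", format_reference(refs[i, ]))
    }, character(1))
  } else character(0)
  c(
    paste0("# ", s$title),
    "",
    "## Authors",
    "",
    paste0("- ", s$authors, " (", s$affiliations, ")"),
    "",
    "## Abstract",
    "",
    s$abstract,
    "",
    "## Database links",
    "",
    paste0("- <", s$links, ">"),
    "",
    paste0("Publisher: ", s$publisher),
    "",
    paste0("DOI: ", s$doi),
    "",
    "## Rationale",
    "",
    s$rationale,
    "",
    "## References",
    "",
    ref_lines
  )
}

summary_html <- function(s) {
  doc <- xml2::xml_new_root("html")
  head <- xml2::xml_add_child(doc, "head")
  xml2::xml_add_child(head, "title", s$title)
  body <- xml2::xml_add_child(doc, "body")
  xml2::xml_add_child(body, "h1", s$title)
  authors <- xml2::xml_add_child(body, "ul", class = "authors")
  for (i in seq_along(s$authors)) {
    xml2::xml_add_child(authors, "li",
                        paste0(s$authors[i], " (", s$affiliations[i], ")"))
  }
  xml2::xml_add_child(body, "p", s$abstract, class = "abstract")
  links <- xml2::xml_add_child(body, "ul", class = "links")
  for (u in s$links) {
    li <- xml2::xml_add_child(links, "li")
    xml2::xml_add_child(li, "a", u, href = u)
  }
  xml2::xml_add_child(body, "p", paste0("Publisher: ", s$publisher))
  xml2::xml_add_child(body, "p", paste0("DOI: ", s$doi))
  xml2::xml_add_child(body, "p", s$rationale, class = "rationale")
  refs <- xml2::xml_add_child(body, "ol", class = "references")
  if (nrow(s$references)) {
    for (i in seq_len(nrow(s$references))) {
      xml2::xml_add_child(refs, "li", format_reference(s$references[i, ]))
    }
  }
  doc
}

#' @export
print.citation_summary <- function(x, ...) {
  cat("<citation_summary>", x$title, "\n")
  cat(" ", length(x$authors), "authors,", nrow(x$references),
      "references, DOI", x$doi, "\n")
  invisible(x)
}

#' Check that a summary carries all eight content elements
#'
#' @param s A [render_summary()] result.
#' @return Named logical vector over the eight elements: title with
#'   version, authors with affiliations, abstract, links, publisher,
#'   rationale, references, DOI.
#' @export
summary_elements <- function(s) {
  stopifnot(inherits(s, "citation_summary"))
  c(
    title_with_version = grepl(s$db_version, s$title, fixed = TRUE),
    authors_with_affiliations = length(s$authors) > 0L &&
      length(s$affiliations) == length(s$authors) && all(nzchar(s$affiliations)),
    abstract = nzchar(s$abstract),
    links = length(s$links) > 0L,
    publisher = nzchar(s$publisher),
    rationale = nzchar(s$rationale),
    references = is.data.frame(s$references),
    doi = nzchar(s$doi)
  )
}

#' Write the rendered summary to disk
#'
#' Writes the portable document (`<root>.md`) and its markup sibling
#' (`<root>.html`), mirroring the paper-plus-web-page pairing that journal
#' hosting expects.
#'
#' @param s A [render_summary()] result.
#' @param dir Output directory (created if missing).
#' @return Character vector of the two paths, invisibly.
#' @export
write_summary <- function(s, dir) {
  stopifnot(inherits(s, "citation_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  md <- file.path(dir, paste0(s$view$root, ".md"))
  html <- file.path(dir, paste0(s$view$root, ".html"))
  writeLines(s$markdown, md)
  xml2::write_html(summary_html(s), html)
  invisible(c(md, html))
}

citation_key <- function(s) {
  gsub("[^A-Za-z0-9]", "_", paste0(s$view$root, "_v", s$version))
}

#' Export a summary citation in a bibliographic format
#'
#' @param s A [render_summary()] result.
#' @param format One of `"bibtex"`, `"ris"`, `"plain"`.
#' @return A character vector of lines forming one record.
#' @export
export_citation <- function(s, format = c("bibtex", "ris", "plain")) {
  stopifnot(inherits(s, "citation_summary"))
  format <- match.arg(format)
  year <- format(Sys.Date(), "%Y")
  switch(format,
    bibtex = c(
      paste0("@article{", citation_key(s), ","),
      paste0("  title = {", s$title, "},"),
      paste0("  author = {", paste(s$authors, collapse = " and "), "},"),
      paste0("  publisher = {", s$publisher, "},"),
      paste0("  year = {", year, "},"),
      paste0("  doi = {", s$doi, "}"),
      "}"
    ),
    ris = c(
      "TY  - JOUR",
      paste0("AU  - ", s$authors),
      paste0("TI  - ", s$title),
      paste0("PY  - ", year),
      paste0("PB  - ", s$publisher),
      paste0("DO  - ", s$doi),
      "ER  - "
    ),
    plain = paste0(
      paste(s$authors, collapse = ", "), " (", year, "). ", s$title, ". ",
      s$publisher, ". doi:", s$doi
    )
  )
}

# minimal parser for the BibTeX dialect written by export_citation();
# used to round-trip-check exports
parse_bibtex_entry <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  m <- regmatches(txt, regexec("@(\\w+)\\{([^,]+),", txt))[[1L]]
  if (length(m) < 3L) {
    stop_citesum("not a BibTeX entry", "citesum_bad_input")
  }
  fields <- regmatches(txt,
                       gregexpr("(\\w+)\\s*=\\s*\\{([^{}]*)\\}", txt))[[1L]]
  vals <- lapply(fields, function(f) {
    fm <- regmatches(f, regexec("(\\w+)\\s*=\\s*\\{([^{}]*)\\}", f))[[1L]]
    stats::setNames(fm[3L], fm[2L])
  })
  out <- unlist(vals)
  attr(out, "entry_type") <- m[2L]
  attr(out, "key") <- m[3L]
  out
}

#' Render the journal-import metadata record for a summary
#'
#' Emits a Dublin-Core-flavoured XML record carrying title, creators,
#' abstract, identifiers, publisher and references, plus a `ledger` payload
#' (database version, author ids, reference ids, canonical view encoding,
#' summary version) so that the state needed for change detection can later
#' be retrieved from the published metadata instead of being stored in the
#' source database.
#'
#' @param s A [render_summary()] result.
#' @return An `xml_document`.
#' @seealso [parse_metadata()] for the inverse, [ledger_entry()].
#' @export
render_metadata <- function(s) {
  stopifnot(inherits(s, "citation_summary"))
  doc <- xml2::xml_new_root(
    "record",
    "xmlns:dc" = "http://purl.org/dc/elements/1.1/"
  )
  xml2::xml_add_child(doc, "dc:title", s$title)
  for (a in s$authors) xml2::xml_add_child(doc, "dc:creator", a)
  xml2::xml_add_child(doc, "dc:description", s$abstract)
  xml2::xml_add_child(doc, "dc:publisher", s$publisher)
  xml2::xml_add_child(doc, "dc:identifier", s$doi)
  for (u in s$links) xml2::xml_add_child(doc, "dc:relation", u)
  if (nrow(s$references)) {
    for (i in seq_len(nrow(s$references))) {
      xml2::xml_add_child(doc, "dc:references",
                          format_reference(s$references[i, ]))
    }
  }
  led <- xml2::xml_add_child(doc, "ledger")
  xml2::xml_add_child(led, "view_id", s$view$root)
  xml2::xml_add_child(led, "db_version", s$db_version)
  xml2::xml_add_child(led, "summary_version", s$version)
  xml2::xml_add_child(led, "authors", paste(sort(s$authors), collapse = ";"))
  xml2::xml_add_child(led, "references",
                      paste(sort(s$references$ref_id), collapse = ";"))
  xml2::xml_add_child(led, "view_encoding", encode_view(s$view))
  doc
}

#' Parse a metadata record back into its ledger entry
#'
#' @param x An `xml_document` produced by [render_metadata()], or a path to
#'   one on disk.
#' @return A list with the Dublin Core fields (`title`, `creators`,
#'   `description`, `publisher`, `identifier`) and the [ledger_entry()]
#'   stored in the record.
#' @export
parse_metadata <- function(x) {
  doc <- if (inherits(x, "xml_document")) x else xml2::read_xml(x)
  text1 <- function(xp) xml2::xml_text(xml2::xml_find_first(doc, xp))
  split_ids <- function(txt) {
    if (is.na(txt) || !nzchar(txt)) character(0)
    else strsplit(txt, ";", fixed = TRUE)[[1L]]
  }
  entry <- ledger_entry(
    view_id = text1(".//ledger/view_id"),
    db_version = text1(".//ledger/db_version"),
    authors = split_ids(text1(".//ledger/authors")),
    ref_ids = split_ids(text1(".//ledger/references")),
    view_encoding = text1(".//ledger/view_encoding"),
    summary_version = text1(".//ledger/summary_version")
  )
  list(
    title = text1(".//dc:title"),
    creators = xml2::xml_text(xml2::xml_find_all(doc, ".//dc:creator")),
    description = text1(".//dc:description"),
    publisher = text1(".//dc:publisher"),
    identifier = text1(".//dc:identifier"),
    ledger = entry
  )
}
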