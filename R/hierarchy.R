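#' Construct a curated-database hierarchy
#'
#' Builds and validates the family/object hierarchy at the heart of the
#' package: a DAG of nodes of three kinds — top-level `group`s, `family`
#' nodes (possibly nested), and leaf `object`s (the curated things
#' themselves).  Multi-parent nodes are allowed; cycles, dangling parents
#' and duplicate identifiers are rejected with the offending identifier in
#' the message.
#'
#' @param nodes A data frame with columns `node_id`, `label`, `level_kind`
#'   (one of `"group"`, `"family"`, `"object"`), `parents` (semicolon
#'   separated parent ids, empty for roots) and optionally `description`.
#' @return An object of class `hierarchy`: node table plus parent/child
#'   maps, per-node author sets (empty until [merge_contributors()]) and
#'   per-node reference-id sets (empty until [merge_references()]).
#' @seealso [read_hierarchy()] and [write_hierarchy()] for the interchange
#'   format; [descendants()] for traversal.
#' @export
hierarchy <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  required <- c("node_id", "label", "level_kind", "parents")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols)) {
    stop_citesum(paste0("missing hierarchy columns: ",
                        paste(missing_cols, collapse = ", ")),
                 "citesum_bad_input")
  }
  if (is.null(nodes$description)) nodes$description <- ""
  nodes$description[is.na(nodes$description)] <- ""
  nodes$node_id <- as.character(nodes$node_id)

  dup <- nodes$node_id[duplicated(nodes$node_id)]
  if (length(dup)) {
    stop_citesum(paste0("duplicate node_id: ", paste(unique(dup), collapse = ", ")),
                 "citesum_duplicate_id")
  }
  bad_kind <- setdiff(unique(nodes$level_kind), c("group", "family", "object"))
  if (length(bad_kind)) {
    stop_citesum(paste0("unknown level_kind: ", paste(bad_kind, collapse = ", ")),
                 "citesum_bad_input")
  }

  parents <- lapply(nodes$parents, function(p) {
    if (is.na(p) || !nzchar(p)) character(0)
    else sort(unique(strsplit(p, ";", fixed = TRUE)[[1]]))
  })
  names(parents) <- nodes$node_id

  dangling <- setdiff(unlist(parents, use.names = FALSE), nodes$node_id)
  if (length(dangling)) {
    stop_citesum(paste0("dangling parent id: ", paste(dangling, collapse = ", ")),
                 "citesum_dangling_parent")
  }

  children <- lapply(nodes$node_id, function(id) character(0))
  names(children) <- nodes$node_id
  for (id in nodes$node_id) {
    for (p in parents[[id]]) children[[p]] <- c(children[[p]], id)
  }
  children <- lapply(children, sort)

  # cycle check: Kahn's algorithm on the parent -> child relation
  indeg <- lengths(parents)
  queue <- names(indeg)[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < nrow(nodes)) {
    cyc <- names(indeg)[indeg > 0L]
    stop_citesum(paste0("cycle detected involving: ", paste(cyc, collapse = ", ")),
                 "citesum_cycle")
  }

  roots <- nodes$node_id[lengths(parents) == 0L]
  not_group <- roots[nodes$level_kind[match(roots, nodes$node_id)] != "group"]
  if (length(not_group)) {
    stop_citesum(paste0("root node is not a group: ",
                        paste(not_group, collapse = ", ")),
                 "citesum_bad_root")
  }
  obj_parents <- nodes$node_id[nodes$level_kind == "object"]
  with_children <- obj_parents[lengths(children[obj_parents]) > 0L]
  if (length(with_children)) {
    stop_citesum(paste0("object node has children: ",
                        paste(with_children, collapse = ", ")),
                 "citesum_bad_input")
  }

  empty <- lapply(nodes$node_id, function(id) character(0))
  names(empty) <- nodes$node_id
  structure(
    list(
      nodes = nodes[, c("node_id", "label", "level_kind", "description")],
      parents = parents,
      children = children,
      roots = sort(roots),
      authors = empty,
      refs = empty,
      references = empty_reference_table()
    ),
    class = "hierarchy"
  )
}

#' @export
print.hierarchy <- function(x, ...) {
  kinds <- table(factor(x$nodes$level_kind, c("group", "family", "object")))
  authored <- sum(lengths(x$authors) > 0L)
  cat("<hierarchy>", nrow(x$nodes), "nodes:",
      kinds[["group"]], "groups,", kinds[["family"]], "families,",
      kinds[["object"]], "objects\n")
  cat("  authored nodes:", authored,
      " distinct authors:", length(unique(unlist(x$authors, use.names = FALSE))),
      "\n")
  cat("  reference links:", sum(lengths(x$refs)),
      " reference records:", nrow(x$references), "\n")
  invisible(x)
}

level_kind <- function(h, ids) {
  h$nodes$level_kind[match(ids, h$nodes$node_id)]
}

check_node_ids <- function(h, ids) {
  unknown <- setdiff(ids, h$nodes$node_id)
  if (length(unknown)) {
    stop_citesum(paste0("unknown node_id: ",
                        paste(utils::head(unknown, 5L), collapse = ", ")),
                 "citesum_unknown_node")
  }
  invisible(TRUE)
}

#' Attach contributor relations to a hierarchy
#'
#' Replaces each node's author set with the set of authors paired with it in
#' the contributor table (rows `(author_id, node_id)`).  Nodes absent from
#' the table get an empty author set; duplicate rows are idempotent (set
#' semantics).
#'
#' @param h A [hierarchy()].
#' @param contributors A data frame with columns `author_id` and `node_id`.
#' @return The hierarchy with `authors` filled in.
#' @export
merge_contributors <- function(h, contributors) {
  stopifnot(inherits(h, "hierarchy"))
  contributors <- as.data.frame(contributors, stringsAsFactors = FALSE)
  if (!all(c("author_id", "node_id") %in% names(contributors))) {
    stop_citesum("contributor table needs columns author_id, node_id",
                 "citesum_bad_input")
  }
  check_node_ids(h, unique(contributors$node_id))
  empty <- lapply(h$nodes$node_id, function(id) character(0))
  names(empty) <- h$nodes$node_id
  h$authors <- empty
  if (nrow(contributors)) {
    by_node <- split(as.character(contributors$author_id),
                     as.character(contributors$node_id))
    for (id in names(by_node)) h$authors[[id]] <- as_author_set(by_node[[id]])
  }
  h
}

empty_reference_table <- function() {
  data.frame(ref_id = character(0), title = character(0),
             authors = character(0), venue = character(0),
             year = integer(0), external_id = character(0),
             stringsAsFactors = FALSE)
}

#' Attach outgoing bibliographic references to a hierarchy
#'
#' @param h A [hierarchy()].
#' @param references Data frame of reference records: `ref_id`, `title`,
#'   `authors` (semicolon-separated names, in citation order), `venue`,
#'   `year`, `external_id` (DOI/PMID, may be empty).
#' @param links Data frame of node-to-reference links: `node_id`, `ref_id`.
#' @return The hierarchy with `refs` (per-node ref-id sets) and the
#'   reference record table filled in.
#' @export
merge_references <- function(h, references, links) {
  stopifnot(inherits(h, "hierarchy"))
  references <- as.data.frame(references, stringsAsFactors = FALSE)
  links <- as.data.frame(links, stringsAsFactors = FALSE)
  if (!all(c("node_id", "ref_id") %in% names(links))) {
    stop_citesum("link table needs columns node_id, ref_id", "citesum_bad_input")
  }
  if (anyDuplicated(references$ref_id)) {
    stop_citesum("duplicate ref_id in reference table", "citesum_duplicate_id")
  }
  if (any(!is.na(references$year) & references$year <= 0)) {
    stop_citesum("reference year must be positive", "citesum_bad_input")
  }
  check_node_ids(h, unique(links$node_id))
  unknown_ref <- setdiff(unique(links$ref_id), references$ref_id)
  if (length(unknown_ref)) {
    stop_citesum(paste0("link to unknown ref_id: ",
                        paste(utils::head(unknown_ref, 5L), collapse = ", ")),
                 "citesum_unknown_ref")
  }
  empty <- lapply(h$nodes$node_id, function(id) character(0))
  names(empty) <- h$nodes$node_id
  h$refs <- empty
  if (nrow(links)) {
    by_node <- split(as.character(links$ref_id), as.character(links$node_id))
    for (id in names(by_node)) h$refs[[id]] <- sort(unique(by_node[[id]]))
  }
  h$references <- references
  h
}

#' Descendants of a node, in deterministic depth-first order
#'
#' Returns the node itself plus everything reachable through child links,
#' visiting children in lexicographic id order and listing each node once
#' even when it is reachable through several parents.
#'
#' @param h A [hierarchy()].
#' @param root A node id present in `h`.
#' @param include_objects Keep `object`-level nodes in the result?
#' @return Character vector of node ids, starting with `root`.
#' @export
descendants <- function(h, root, include_objects = TRUE) {
  stopifnot(inherits(h, "hierarchy"))
  check_node_ids(h, root)
  out <- character(0)
  visited <- new.env(parent = emptyenv())
  stack <- root
  while (length(stack)) {
    v <- stack[[1L]]; stack <- stack[-1L]
    if (!is.null(visited[[v]])) next
    visited[[v]] <- TRUE
    out <- c(out, v)
    # prepend children to keep depth-first order
    stack <- c(h$children[[v]], stack)
  }
  if (!include_objects) out <- out[level_kind(h, out) != "object"]
  out
}

#' Read a hierarchy from its tab-separated interchange file
#'
#' One record per node with columns `node_id`, `label`, `level_kind`,
#' `parents` (semicolon separated), `description`; header required.
#'
#' @param path Path to the file.
#' @return A validated [hierarchy()].
#' @export
read_hierarchy <- function(path) {
  nodes <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character", na.strings = NULL)
  hierarchy(nodes)
}

#' Write a hierarchy back to its interchange file
#'
#' @param h A [hierarchy()].
#' @param path Output path.
#' @return `path`, invisibly.  `read_hierarchy(write_hierarchy(h, p))`
#'   round-trips to an equal hierarchy.
#' @export
write_hierarchy <- function(h, path) {
  stopifnot(inherits(h, "hierarchy"))
  out <- h$nodes
  out$parents <- vapply(h$parents[out$node_id], paste, character(1),
                        collapse = ";")
  out <- out[, c("node_id", "label", "level_kind", "parents", "description")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write the contributor relation
#'
#' Two-column tab-separated text (`author_id`, `node_id`), header required.
#'
#' @param path Path to the file.
#' @return `read_contributors()` returns the data frame;
#'   `write_contributors()` returns `path` invisibly.
#' @export
read_contributors <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
}

#' @rdname read_contributors
#' @param contributors Data frame with columns `author_id`, `node_id`.
#' @export
write_contributors <- function(contributors, path) {
  utils::write.table(contributors[, c("author_id", "node_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write reference records and node-reference links
#'
#' `references.tsv` carries the reference fields (`ref_id`, `title`,
#' `authors` semicolon-separated, `venue`, `year`, `external_id`);
#' `links.tsv` is two columns (`node_id`, `ref_id`).
#'
#' @param path Path to the file.
#' @return Data frames; writers return `path` invisibly.
#' @export
read_references <- function(path) {
  refs <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                            quote = "")
  refs$ref_id <- as.character(refs$ref_id)
  refs$year <- as.integer(refs$year)
  refs
}

#' @rdname read_references
#' @param references Data frame of reference records.
#' @export
write_references <- function(references, path) {
  utils::write.table(references, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_references
#' @export
read_ref_links <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = NULL)
}

#' @rdname read_references
#' @param links Data frame with columns `node_id`, `ref_id`.
#' @export
write_ref_links <- function(links, path) {
  utils::write.table(links[, c("node_id", "ref_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# bottom-level families: family nodes with no family children
bottom_families <- function(h) {
  fams <- h$nodes$node_id[h$nodes$level_kind == "family"]
  fams[vapply(fams, function(f) {
    kids <- h$children[[f]]
    !any(level_kind(h, kids) == "family")
  }, logical(1))]
}
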