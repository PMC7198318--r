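# Effective author set of a subtree: the node's own authors if it has any,
# otherwise the union of all descendant author sets.
effective_authors <- function(h, id, include_objects = TRUE) {
  own <- h$authors[[id]]
  if (length(own)) return(own)
  desc <- setdiff(descendants(h, id, include_objects = include_objects), id)
  as_author_set(unlist(h$authors[desc], use.names = FALSE))
}

# multiset of author sets of all authored descendants of `id` (excluding id)
descendant_author_sets <- function(h, id, include_objects = TRUE) {
  desc <- setdiff(descendants(h, id, include_objects = include_objects), id)
  sets <- h$authors[desc]
  sets[lengths(sets) > 0L]
}

#' Per-node stress diagnostics for a hierarchy
#'
#' For every node, computes
#' \describe{
#'   \item{`sub_stress`}{the (alpha-weighted) stress of the multiset of
#'     author sets of all authored descendants — how disparate the
#'     authorship below the node is;}
#'   \item{`stress_value`}{the same multiset with the node's own author set
#'     added when it is non-empty.}
#' }
#' Both are `NA` where the corresponding multiset is empty (no authored
#' content): stress is undefined there, and the recommendation procedure
#' treats such nodes as carrying no authorship signal.  By monotonicity
#' under multiset inclusion, `sub_stress <= stress_value` wherever both are
#' defined.
#'
#' @param h A [hierarchy()] with contributors merged in.
#' @param alpha Weight function (name or function) passed to
#'   [stress_alpha()]; the default `"indicator"` gives plain [stress()].
#' @param include_objects Include object-level author sets in the
#'   descendant multisets?
#' @return A data frame of class `stress_report` with columns `node_id`,
#'   `level_kind`, `n_authors` (the node's own), `n_descendant_sets`,
#'   `sub_stress`, `stress_value`.
#' @export
stress_report <- function(h, alpha = "indicator", include_objects = TRUE) {
  stopifnot(inherits(h, "hierarchy"))
  alpha_name <- if (is.character(alpha)) alpha else "custom"
  alpha_fun <- alpha_function(alpha)
  ids <- h$nodes$node_id
  sub <- rep(NA_real_, length(ids))
  full <- rep(NA_real_, length(ids))
  ndesc <- integer(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    sets <- if (h$nodes$level_kind[k] == "object") list()
            else descendant_author_sets(h, id, include_objects)
    ndesc[k] <- length(sets)
    if (length(sets)) sub[k] <- stress_alpha(sets, alpha_fun)
    own <- h$authors[[id]]
    all_sets <- if (length(own)) c(list(own), sets) else sets
    if (length(all_sets)) full[k] <- stress_alpha(all_sets, alpha_fun)
  }
  out <- data.frame(
    node_id = ids,
    level_kind = h$nodes$level_kind,
    n_authors = lengths(h$authors[ids]),
    n_descendant_sets = ndesc,
    sub_stress = sub,
    stress_value = full,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha_name
  attr(out, "include_objects") <- include_objects
  class(out) <- c("stress_report", "data.frame")
  out
}

#' Per-level stress statistics
#'
#' Summarises a [stress_report()] with one row per hierarchy level: node
#' counts, how many nodes carry their own authors, and the means of stress
#' and sub-stress over the nodes where they are defined.
#'
#' @param report A [stress_report()].
#' @return A data frame with columns `level_kind`, `n_nodes`, `n_authored`,
#'   `n_stress_defined`, `mean_stress`, `n_sub_defined`, `mean_sub_stress`.
#' @export
level_table <- function(report) {
  stopifnot(inherits(report, "stress_report"))
  levels_ <- c("group", "family", "object")
  rows <- lapply(levels_, function(lv) {
    r <- report[report$level_kind == lv, , drop = FALSE]
    data.frame(
      level_kind = lv,
      n_nodes = nrow(r),
      n_authored = sum(r$n_authors > 0L),
      n_stress_defined = sum(!is.na(r$stress_value)),
      mean_stress = if (any(!is.na(r$stress_value)))
        mean(r$stress_value, na.rm = TRUE) else NA_real_,
      n_sub_defined = sum(!is.na(r$sub_stress)),
      mean_sub_stress = if (any(!is.na(r$sub_stress)))
        mean(r$sub_stress, na.rm = TRUE) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Recommend citable view roots by a bottom-up stress sweep
#'
#' Walks the hierarchy in post-order (children before parents) and decides,
#' for every family and group node, whether the authorship below it is
#' coherent enough for a single citation summary.  With `N` the current node
#' and `N1, ..., Nk` its child subtrees (each child contributing its
#' effective author set):
#' \describe{
#'   \item{case `1a`}{`N` authorless, every child's stress low and the joint
#'     stress of the children's author sets low: one summary rooted at `N`
#'     (replaces the children's roots) — flagged `needs_review`;}
#'   \item{case `1b`}{`N` authorless, otherwise: the children keep their
#'     roots;}
#'   \item{case `2a`}{`N` authored and the joint stress of `N`'s authors
#'     with the children's sets is low: one summary rooted at `N`;}
#'   \item{case `2b`}{`N` authored but the joint stress is high: the
#'     children keep their roots and `N` is flagged `needs_review` for the
#'     curators (its own authorship is not covered by any child view).}
#' }
#' Bottom-level families are the default granularity: an authored
#' bottom-level family always becomes a root (objects never do), flagged
#' unless its own joint stress is low.  "Low" means `<= low`.  Top-level
#' groups never become roots — authorship is not recorded at that level and
#' a group-wide summary would defeat the granularity goal — so the merge
#' cases apply to family nodes only.
#'
#' @param h A [hierarchy()] with contributors merged.
#' @param report A matching [stress_report()] (used for the per-child stress
#'   values); computed on the fly when `NULL`.
#' @param low Stress threshold in `(0, 1)` below which authorship is
#'   considered coherent; default 0.3.
#' @param alpha Weight function used for the joint-stress evaluations.
#' @param include_objects Include object author sets when judging a
#'   bottom-level family?
#' @return An object of class `summary_plan`: a data frame `roots`
#'   (`node_id`, `case`, `flag`), plus `rationale` and `flags` maps over all
#'   visited nodes.  The roots form an antichain and cover every authored
#'   bottom-level family exactly once.
#' @export
recommend_views <- function(h, report = NULL, low = 0.3, alpha = "indicator",
                            include_objects = TRUE) {
  stopifnot(inherits(h, "hierarchy"))
  if (low <= 0 || low >= 1) {
    stop_citesum("low-stress threshold must be in (0, 1)", "citesum_bad_input")
  }
  if (is.null(report)) {
    report <- stress_report(h, alpha = alpha,
                            include_objects = include_objects)
  }
  alpha_fun <- alpha_function(alpha)
  stress_of <- stats::setNames(report$stress_value, report$node_id)

  roots_under <- list()    # node_id -> character vector of chosen roots below
  rationale <- character(0)
  flags <- character(0)
  root_case <- character(0)

  is_low <- function(s) !is.na(s) && s <= low

  # post-order over family/group nodes: children first
  order_ids <- unlist(lapply(h$roots, function(r) {
    ids <- descendants(h, r, include_objects = FALSE)
    rev(ids)
  }), use.names = FALSE)
  order_ids <- order_ids[!duplicated(order_ids)]

  for (id in order_ids) {
    own <- h$authors[[id]]
    kids <- h$children[[id]]
    fam_kids <- kids[level_kind(h, kids) != "object"]
    obj_kids <- setdiff(kids, fam_kids)

    # top-level groups are never citable roots: authorship is not recorded
    # at that level and a group-wide summary defeats the granularity goal
    if (level_kind(h, id) == "group") {
      roots_under[[id]] <- unlist(roots_under[fam_kids], use.names = FALSE) %||%
        character(0)
      next
    }

    if (length(fam_kids) == 0L) {
      # bottom-level family (or childless group): lowest permissible root
      obj_sets <- if (include_objects) {
        s <- h$authors[obj_kids]
        s[lengths(s) > 0L]
      } else list()
      if (!length(own) && !length(obj_sets)) {
        roots_under[[id]] <- character(0)   # no authored content: no view
        next
      }
      if (length(own)) {
        joint <- stress_alpha(c(list(own), obj_sets), alpha_fun)
        case <- if (joint <= low) "2a" else "2b"
      } else {
        joint <- stress_alpha(obj_sets, alpha_fun)
        case <- if (joint <= low) "1a" else "1b"
      }
      roots_under[[id]] <- id
      root_case[id] <- case
      rationale[id] <- case
      flags[id] <- if (case == "2a") "auto" else "needs_review"
      next
    }

    kid_roots <- unlist(roots_under[fam_kids], use.names = FALSE)
    authored_kids <- fam_kids[vapply(fam_kids, function(k) {
      length(effective_authors(h, k, include_objects)) > 0L
    }, logical(1))]
    kid_sets <- lapply(authored_kids, effective_authors, h = h,
                       include_objects = include_objects)
    obj_sets <- if (include_objects) {
      s <- h$authors[obj_kids]
      s[lengths(s) > 0L]
    } else list()

    if (!length(own) && !length(kid_sets) && !length(obj_sets)) {
      roots_under[[id]] <- kid_roots    # nothing authored here
      next
    }

    if (length(own) == 0L) {
      kid_stresses <- stress_of[authored_kids]
      all_kids_low <- length(authored_kids) > 0L &&
        all(vapply(kid_stresses, is_low, logical(1)))
      joint_low <- length(c(kid_sets, obj_sets)) > 0L &&
        is_low(stress_alpha(c(kid_sets, obj_sets), alpha_fun))
      if (all_kids_low && joint_low) {
        roots_under[[id]] <- id
        root_case[id] <- "1a"
        rationale[id] <- "1a"
        flags[id] <- "needs_review"
      } else {
        roots_under[[id]] <- kid_roots
        rationale[id] <- "1b"
        flags[id] <- "auto"
      }
    } else {
      joint <- stress_alpha(c(list(own), kid_sets, obj_sets), alpha_fun)
      if (joint <= low) {
        roots_under[[id]] <- id
        root_case[id] <- "2a"
        rationale[id] <- "2a"
        flags[id] <- "auto"
      } else {
        roots_under[[id]] <- kid_roots
        rationale[id] <- "2b"
        flags[id] <- "needs_review"
      }
    }
  }

  final_roots <- sort(unique(unlist(roots_under[h$roots], use.names = FALSE)))
  plan <- data.frame(
    node_id = final_roots,
    case = unname(root_case[final_roots]),
    flag = unname(flags[final_roots]),
    stringsAsFactors = FALSE
  )
  structure(
    list(roots = plan, rationale = rationale, flags = flags,
         low = low, alpha = attr(report, "alpha") %||% "indicator"),
    class = "summary_plan"
  )
}

#' @export
print.summary_plan <- function(x, ...) {
  cat("<summary_plan>", nrow(x$roots), "view roots (low-stress threshold",
      x$low, ")\n")
  print(table(case = x$roots$case, flag = x$roots$flag))
  invisible(x)
}
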