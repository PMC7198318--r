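#' Construct a signed (+/-) similarity graph
#'
#' A signed graph holds vertices and edges labelled positive (similar) or
#' negative (dissimilar).  Correlation clustering partitions such a graph so
#' that, as far as possible, positive edges stay within blocks and negative
#' edges cross blocks.
#'
#' @param vertices Character vector of vertex ids.
#' @param positive,negative Two-column matrices or data frames of vertex-id
#'   pairs.  Self-loops and endpoints outside `vertices` are errors; a pair
#'   listed in both is an error.
#' @return An object of class `signed_graph` holding the vertex set and a
#'   symmetric sign matrix (`+1`, `-1`, or `0` for no edge).
#' @seealso [build_signed_graph()] to derive signs from author-set
#'   similarity; [cluster_exact()], [cluster_pivot()].
#' @export
signed_graph <- function(vertices, positive = NULL, negative = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) {
    stop_citesum("duplicate vertex ids", "citesum_duplicate_id")
  }
  n <- length(vertices)
  sign <- matrix(0L, n, n, dimnames = list(vertices, vertices))
  add <- function(pairs, value) {
    if (is.null(pairs) || NROW(pairs) == 0L) return()
    pairs <- as.matrix(pairs)
    storage.mode(pairs) <- "character"
    bad <- setdiff(as.vector(pairs), vertices)
    if (length(bad)) {
      stop_citesum(paste0("edge endpoint is not a vertex: ",
                          paste(bad, collapse = ", ")), "citesum_bad_input")
    }
    if (any(pairs[, 1L] == pairs[, 2L])) {
      stop_citesum("self-loops are not allowed", "citesum_bad_input")
    }
    i <- match(pairs[, 1L], vertices); j <- match(pairs[, 2L], vertices)
    prev <- sign[cbind(i, j)]
    if (any(prev != 0L & prev != value)) {
      stop_citesum("an edge cannot be both positive and negative",
                   "citesum_bad_input")
    }
    sign[cbind(i, j)] <<- value
    sign[cbind(j, i)] <<- value
  }
  add(positive, 1L)
  add(negative, -1L)
  structure(list(vertices = vertices, sign = sign), class = "signed_graph")
}

#' @export
print.signed_graph <- function(x, ...) {
  up <- x$sign[upper.tri(x$sign)]
  cat("<signed_graph>", length(x$vertices), "vertices,",
      sum(up == 1L), "positive /", sum(up == -1L), "negative edges\n")
  invisible(x)
}

#' Build the authorship-similarity signed graph
#'
#' Forms the complete graph on the given items and labels each edge by the
#' Jaccard distance between the two author sets: distances below the
#' threshold are positive (similar), the rest negative.  Items with empty
#' author sets must be filtered out by the caller — similarity is undefined
#' for them.
#'
#' @param author_sets Named list of non-empty character author sets, one per
#'   item (at least two items).
#' @param threshold Distance cut-off in `(0, 1]`; default 0.5.
#' @param comparison `"lt"` (default) labels an edge positive when the
#'   distance is strictly below the threshold; `"le"` uses `<=`.
#' @return A [signed_graph()] on `names(author_sets)`.
#' @export
build_signed_graph <- function(author_sets, threshold = 0.5,
                               comparison = c("lt", "le")) {
  comparison <- match.arg(comparison)
  if (is.null(names(author_sets)) || anyDuplicated(names(author_sets))) {
    stop_citesum("author_sets must be a uniquely named list", "citesum_bad_input")
  }
  if (length(author_sets) < 2L) {
    stop_citesum("need at least two items to build a signed graph",
                 "citesum_bad_input")
  }
  author_sets <- lapply(author_sets, as_author_set)
  if (any(lengths(author_sets) == 0L)) {
    empty <- names(author_sets)[lengths(author_sets) == 0L]
    stop_citesum(paste0("item with empty author set: ",
                        paste(utils::head(empty, 5L), collapse = ", ")),
                 "citesum_empty_authors")
  }
  if (threshold <= 0 || threshold > 1) {
    stop_citesum("threshold must be in (0, 1]", "citesum_bad_input")
  }
  items <- names(author_sets)
  authors <- sort(unique(unlist(author_sets, use.names = FALSE)))
  m <- matrix(0, length(items), length(authors),
              dimnames = list(items, authors))
  for (k in seq_along(items)) m[k, author_sets[[k]]] <- 1
  inter <- tcrossprod(m)
  sizes <- rowSums(m)
  uni <- outer(sizes, sizes, `+`) - inter
  d <- 1 - inter / uni
  pos <- if (comparison == "lt") d < threshold else d <= threshold
  sign <- matrix(-1L, length(items), length(items),
                 dimnames = list(items, items))
  sign[pos] <- 1L
  diag(sign) <- 0L
  structure(list(vertices = items, sign = sign), class = "signed_graph")
}

# normalise a partition argument to an integer membership vector over
# g$vertices; accepts a list of blocks or a named membership vector
as_membership <- function(g, blocks) {
  v <- g$vertices
  if (is.list(blocks)) {
    flat <- unlist(blocks, use.names = FALSE)
    if (anyDuplicated(flat) || !setequal(flat, v)) {
      stop_citesum("blocks must partition the vertex set", "citesum_bad_partition")
    }
    memb <- integer(length(v)); names(memb) <- v
    for (b in seq_along(blocks)) memb[as.character(blocks[[b]])] <- b
    memb
  } else {
    if (is.null(names(blocks)) || !setequal(names(blocks), v)) {
      stop_citesum("membership vector must be named by the vertex set",
                   "citesum_bad_partition")
    }
    as.integer(factor(blocks[v]))
  }
}

#' Count the disagreements of a partition on a signed graph
#'
#' A disagreement ("misplaced edge") is a negative edge inside a block or a
#' positive edge between blocks.  This is the objective that correlation
#' clustering minimises.
#'
#' @param g A [signed_graph()].
#' @param blocks A partition of the vertices: either a list of character
#'   vectors or a named membership vector.
#' @return An object of class `clustering`: the blocks (each sorted, blocks
#'   ordered by first member), the counts `misplaced_negative`,
#'   `misplaced_positive`, their sum `disagreement_count`, and the offending
#'   edges themselves.
#' @export
disagreements <- function(g, blocks) {
  stopifnot(inherits(g, "signed_graph"))
  memb <- as_membership(g, blocks)
  n <- length(g$vertices)
  same <- outer(memb, memb, `==`)
  up <- upper.tri(g$sign)
  bad_neg <- which(up & same & g$sign == -1L, arr.ind = TRUE)
  bad_pos <- which(up & !same & g$sign == 1L, arr.ind = TRUE)
  block_list <- split(g$vertices, memb)
  block_list <- lapply(block_list, sort)
  block_list <- block_list[order(vapply(block_list, `[`, character(1), 1L))]
  names(block_list) <- NULL
  edge_names <- function(idx) {
    if (nrow(idx) == 0L) {
      return(matrix(character(0), 0L, 2L))
    }
    cbind(g$vertices[idx[, 1L]], g$vertices[idx[, 2L]])
  }
  structure(
    list(
      blocks = block_list,
      membership = stats::setNames(memb, g$vertices),
      misplaced_negative = nrow(bad_neg),
      misplaced_positive = nrow(bad_pos),
      disagreement_count = nrow(bad_neg) + nrow(bad_pos),
      misplaced_negative_edges = edge_names(bad_neg),
      misplaced_positive_edges = edge_names(bad_pos)
    ),
    class = "clustering"
  )
}

#' @export
print.clustering <- function(x, ...) {
  cat("<clustering>", length(x$blocks), "blocks,",
      x$disagreement_count, "disagreements (",
      x$misplaced_negative, "negative inside /",
      x$misplaced_positive, "positive across )\n")
  invisible(x)
}

# --- exact minimisation by enumeration over set partitions ----------------

partition_cache <- new.env(parent = emptyenv())

# all set partitions of n elements as restricted growth strings (rows)
set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(partition_cache[[key]])) return(partition_cache[[key]])
  if (n == 1L) {
    res <- matrix(1L, 1L, 1L)
  } else {
    out <- vector("list", 0L)
    cur <- integer(n); cur[1L] <- 1L
    rec <- function(i, m) {
      if (i > n) {
        out[[length(out) + 1L]] <<- cur
        return(invisible())
      }
      for (b in seq_len(m + 1L)) {
        cur[i] <<- b
        rec(i + 1L, max(m, b))
      }
    }
    rec(2L, 1L)
    res <- do.call(rbind, out)
  }
  partition_cache[[key]] <- res
  res
}

#' Exact correlation clustering by exhaustive search
#'
#' Enumerates every partition of the vertex set (Bell-number many — the
#' default cap of 10 vertices means at most 115 975 partitions) and returns
#' one minimising the disagreement count.  Ties are broken in favour of
#' fewer blocks, then lexicographically on the canonical partition encoding.
#' Serves as the oracle against which the [cluster_pivot()] heuristic is
#' validated.
#'
#' @param g A [signed_graph()].
#' @param max_n Refuse instances with more vertices than this.
#' @return A `clustering` (see [disagreements()]).
#' @export
cluster_exact <- function(g, max_n = 10L) {
  stopifnot(inherits(g, "signed_graph"))
  n <- length(g$vertices)
  if (n > max_n) {
    stop_citesum(paste0("instance too large for exhaustive search (n = ", n,
                        " > max_n = ", max_n, ")"), "citesum_too_large")
  }
  P <- set_partitions(n)
  cost <- integer(nrow(P))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- g$sign[i, j]
      if (s == 0L) next
      same <- P[, i] == P[, j]
      cost <- cost + if (s == 1L) !same else same
    }
  }
  best <- which(cost == min(cost))
  if (length(best) > 1L) {
    nblocks <- apply(P[best, , drop = FALSE], 1L, max)
    best <- best[nblocks == min(nblocks)]
    # rows of set_partitions() are generated in lexicographic order already
    best <- best[1L]
  }
  memb <- stats::setNames(P[best, ], g$vertices)
  disagreements(g, memb)
}

# one randomized pivot pass: visit vertices in random order, each unassigned
# pivot absorbs its unassigned positive neighbours
pivot_once <- function(sign, n) {
  memb <- integer(n)
  b <- 0L
  for (v in sample.int(n)) {
    if (memb[v] == 0L) {
      b <- b + 1L
      grab <- which(memb == 0L & sign[v, ] == 1L)
      memb[grab] <- b
      memb[v] <- b
    }
  }
  memb
}

cost_of_membership <- function(sign, memb) {
  same <- outer(memb, memb, `==`)
  up <- upper.tri(sign)
  sum(up & same & sign == -1L) + sum(up & !same & sign == 1L)
}

# best-one-element-move local search: repeatedly move single vertices to the
# block (or a fresh singleton) that lowers the disagreement count most
local_search <- function(sign, memb) {
  n <- length(memb)
  pos <- sign == 1L
  neg <- sign == -1L
  repeat {
    improved <- FALSE
    for (v in seq_len(n)) {
      nblocks <- max(memb)
      pos_in <- tabulate(memb[pos[v, ]], nbins = nblocks)
      neg_in <- tabulate(memb[neg[v, ]], nbins = nblocks)
      # cost of v sitting in block b: negatives inside + positives outside
      tot_pos <- sum(pos[v, ])
      cost_b <- neg_in + (tot_pos - pos_in)
      cost_single <- tot_pos
      best_b <- which.min(cost_b)
      if (cost_single < cost_b[best_b]) {
        if (sum(memb == memb[v]) > 1L) {          # real move to a singleton
          memb[v] <- nblocks + 1L
          improved <- TRUE
        }
      } else if (cost_b[best_b] < cost_b[memb[v]]) {
        memb[v] <- best_b
        improved <- TRUE
      }
      if (improved) memb <- as.integer(factor(memb))  # compact labels
    }
    if (!improved) break
  }
  memb
}

#' Randomized pivot correlation clustering with restarts
#'
#' The standard randomized pivot heuristic for minimising disagreements:
#' pick a random unclustered vertex, form a block from it and its
#' unclustered positive neighbours, repeat.  Each restart is followed (by
#' default) by best-one-element-move local search, and the best of all
#' restarts is returned.  Deterministic for a given `seed`.
#'
#' @param g A [signed_graph()].
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param restarts Number of independent randomized runs.
#' @param refine Apply local search after each pivot run?  On small
#'   instances this makes the heuristic match the exhaustive optimum almost
#'   always; disable for very large graphs if speed matters more.
#' @return A `clustering` (see [disagreements()]).
#' @export
cluster_pivot <- function(g, seed = NULL, restarts = 50L, refine = TRUE) {
  stopifnot(inherits(g, "signed_graph"))
  n <- length(g$vertices)
  sign <- g$sign
  run <- function() {
    best_memb <- NULL
    best_cost <- Inf
    for (r in seq_len(restarts)) {
      memb <- pivot_once(sign, n)
      if (refine) memb <- local_search(sign, memb)
      cc <- cost_of_membership(sign, memb)
      if (cc < best_cost) {
        best_cost <- cc
        best_memb <- memb
      }
    }
    best_memb
  }
  memb <- with_seed(seed, run())
  disagreements(g, stats::setNames(memb, g$vertices))
}

#' Classify clustering blocks against the hierarchy
#'
#' Labels each block of a clustering by how it relates to the family
#' hierarchy, mirroring the situations seen when authorship clusters are
#' compared with a curated classification:
#' \describe{
#'   \item{`singleton`}{one member.}
#'   \item{`superfamily`}{a family together with all of its descendants
#'     (restricted to the clustered items).}
#'   \item{`multi_parent_anomaly`}{contains a node whose multiple parents
#'     were assigned to different blocks.}
#'   \item{`parent_partial_children`}{a node plus a proper, non-empty subset
#'     of its children.}
#'   \item{`sibling_subset`}{members share a parent but are not a complete
#'     superfamily.}
#'   \item{`siblings_plus_other_relatives`}{all members within two levels
#'     below a common ancestor (siblings plus "aunts").}
#'   \item{`unrelated`}{anything else.}
#' }
#'
#' @param clustering A `clustering` whose vertex ids are node ids of `h`.
#' @param h A [hierarchy()].
#' @return Character vector of category labels, one per block, in block
#'   order.
#' @export
classify_clusters <- function(clustering, h) {
  stopifnot(inherits(clustering, "clustering"), inherits(h, "hierarchy"))
  universe <- names(clustering$membership)
  check_node_ids(h, universe)
  memb <- clustering$membership
  vapply(clustering$blocks, function(B) {
    if (length(B) == 1L) return("singleton")
    # superfamily: a unique top member whose in-universe descendant set is B
    tops <- B[vapply(B, function(v) !any(h$parents[[v]] %in% B), logical(1))]
    if (length(tops) == 1L) {
      desc <- intersect(descendants(h, tops), universe)
      if (setequal(desc, B)) return("superfamily")
    }
    # multi-parent member whose parents ended up in different blocks
    for (v in B) {
      ps <- intersect(h$parents[[v]], universe)
      if (length(ps) >= 2L && length(unique(memb[ps])) > 1L) {
        return("multi_parent_anomaly")
      }
    }
    # a parent plus some but not all of its children
    for (p in B) {
      rest <- setdiff(B, p)
      kids <- h$children[[p]]
      if (length(rest) && all(rest %in% kids) &&
          !all(intersect(kids, universe) %in% B)) {
        return("parent_partial_children")
      }
    }
    # common parent for every member
    shared_parent <- Reduce(intersect, h$parents[B])
    if (length(shared_parent)) return("sibling_subset")
    # common ancestor within two levels (siblings plus aunts)
    up2 <- lapply(B, function(v) {
      p1 <- h$parents[[v]]
      unique(c(p1, unlist(h$parents[p1], use.names = FALSE)))
    })
    if (length(Reduce(intersect, up2))) return("siblings_plus_other_relatives")
    "unrelated"
  }, character(1))
}
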