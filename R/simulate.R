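#' Parameters for the synthetic curated-database generator
#'
#' Describes a hierarchy with planted authorship blocks: every bottom-level
#' family, together with its objects, is assigned one core author set drawn
#' from a common pool, optionally perturbed by noise.  The defaults emulate
#' the shape of a large pharmacology classification database: 7 top-level
#' groups, two family levels of branching 10 and 11 (770 bottom-level
#' families), about 2.6 objects per family (~2000 objects), an author pool
#' of 1000, and about 12 outgoing references per node (~34 000 distinct
#' references overall).
#'
#' @param n_groups Number of top-level groups.
#' @param families_per_group Branching factor per family level: a vector of
#'   length `depth` (a scalar is recycled).
#' @param objects_per_family Mean number of objects per bottom-level family
#'   (Poisson).
#' @param depth Number of family levels between groups and objects.
#' @param author_pool Size of the global author pool.
#' @param block_size Mean core-set size per planted block; per-block sizes
#'   follow a truncated long-tail (negative binomial, capped at 33).
#' @param noise Per-node probability of perturbing the core set by dropping
#'   one core author or adding one pool author.
#' @param refs_per_node Mean outgoing references per node (Poisson).
#' @param multi_parent_rate Probability that an object receives a second
#'   parent family within its group.
#' @param seed Integer seed; generation is deterministic given it.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(n_groups = 7L,
                             families_per_group = c(10L, 11L),
                             objects_per_family = 2.6,
                             depth = length(families_per_group),
                             author_pool = 1000L,
                             block_size = 3.5,
                             noise = 0,
                             refs_per_node = 12,
                             multi_parent_rate = 0.01,
                             seed = 1L) {
  if (length(families_per_group) == 1L) {
    families_per_group <- rep(families_per_group, depth)
  }
  p <- list(n_groups = as.integer(n_groups),
            families_per_group = as.integer(families_per_group),
            objects_per_family = objects_per_family,
            depth = as.integer(depth),
            author_pool = as.integer(author_pool),
            block_size = block_size,
            noise = noise,
            refs_per_node = refs_per_node,
            multi_parent_rate = multi_parent_rate,
            seed = as.integer(seed))
  if (p$noise < 0 || p$noise > 1 || p$multi_parent_rate < 0 ||
      p$multi_parent_rate > 1) {
    stop_citesum("probabilities must lie in [0, 1]", "citesum_bad_input")
  }
  if (p$n_groups < 1L || any(p$families_per_group < 1L) ||
      p$objects_per_family < 0 || p$author_pool < 1L || p$block_size < 1 ||
      p$refs_per_node < 0) {
    stop_citesum("counts must be positive", "citesum_bad_input")
  }
  if (p$block_size > p$author_pool) {
    stop_citesum("infeasible parameters: block_size exceeds author_pool",
                 "citesum_bad_input")
  }
  if (length(p$families_per_group) != p$depth) {
    stop_citesum("families_per_group must have one entry per family level",
                 "citesum_bad_input")
  }
  class(p) <- "generator_params"
  p
}

#' @rdname generator_params
#' @export
gtopdb_scale_params <- function(seed = 1L, noise = 0) {
  generator_params(seed = seed, noise = noise)
}

perturb_set <- function(core, pool, noise) {
  if (noise > 0 && stats::runif(1) < noise) {
    if (stats::runif(1) < 0.5 && length(core) > 0L) {
      core <- core[-sample.int(length(core), 1L)]
    } else {
      core <- union(core, sample(pool, 1L))
    }
  }
  core
}

#' Generate a synthetic curated database with planted authorship blocks
#'
#' Produces a hierarchy, a contributor relation and an outgoing-reference
#' relation whose authorship has known block structure: each bottom-level
#' family and its objects share one core author set (the "planted block"),
#' perturbed independently per node with probability `noise`.  References
#' are drawn per node, partly from a block-shared pool (so members of a
#' block share some citations) and partly fresh.  At `noise = 0` every
#' block is internally stress-free, so the recommendation procedure should
#' recover the planted blocks exactly.
#'
#' @param params A [generator_params()].
#' @return A list of class `synthetic_db` with elements `hierarchy` (a
#'   [hierarchy()] with contributors and references merged), `contributors`,
#'   `references`, `links` (the three interchange tables), `blocks` (named
#'   vector: node id of each bottom family/object to its planted block id)
#'   and `params`.
#' @export
simulate_database <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, simulate_database_impl(params))
}

simulate_database_impl <- function(p) {
  # ---- node table, level by level --------------------------------------
  groups <- sprintf("G%02d", seq_len(p$n_groups))
  nodes <- data.frame(node_id = groups,
                      label = paste("Group", seq_len(p$n_groups)),
                      level_kind = "group", parents = "",
                      description = paste("Synthetic top-level group",
                                          seq_len(p$n_groups)),
                      stringsAsFactors = FALSE)
  current <- groups
  for (lvl in seq_len(p$depth)) {
    b <- p$families_per_group[lvl]
    parent <- rep(current, each = b)
    idx <- rep(seq_len(b), times = length(current))
    ids <- sprintf("%s.F%02d", parent, idx)
    nodes <- rbind(nodes, data.frame(
      node_id = ids, label = paste("Family", ids), level_kind = "family",
      parents = parent, description = "", stringsAsFactors = FALSE))
    current <- ids
  }
  bottoms <- current
  n_bottom <- length(bottoms)

  n_obj <- stats::rpois(n_bottom, p$objects_per_family)
  obj_parent <- rep(bottoms, times = n_obj)
  obj_idx <- sequence(n_obj)
  objects <- sprintf("%s.O%02d", obj_parent, obj_idx)
  obj_parents <- obj_parent
  # occasional second parent: another bottom family within the same group
  if (p$multi_parent_rate > 0 && length(objects)) {
    second <- stats::runif(length(objects)) < p$multi_parent_rate
    grp_of <- substr(obj_parent, 1L, 3L)
    for (k in which(second)) {
      candidates <- setdiff(bottoms[startsWith(bottoms, grp_of[k])],
                            obj_parent[k])
      if (length(candidates)) {
        obj_parents[k] <- paste(obj_parent[k], sample(candidates, 1L),
                                sep = ";")
      }
    }
  }
  if (length(objects)) {
    nodes <- rbind(nodes, data.frame(
      node_id = objects, label = paste("Object", objects),
      level_kind = "object", parents = obj_parents, description = "",
      stringsAsFactors = FALSE))
  }
  h <- hierarchy(nodes)

  # ---- planted author blocks -------------------------------------------
  pool <- sprintf("A%04d", seq_len(p$author_pool))
  sizes <- pmin(1L + stats::rnbinom(n_bottom, size = 0.9,
                                    mu = max(p$block_size - 1, 0.01)), 33L)
  cores <- lapply(sizes, function(s) sample(pool, s))
  names(cores) <- bottoms

  block_of <- c(stats::setNames(bottoms, bottoms),
                stats::setNames(obj_parent, objects))
  author_sets <- vector("list", n_bottom + length(objects))
  names(author_sets) <- c(bottoms, objects)
  for (id in names(author_sets)) {
    author_sets[[id]] <- perturb_set(cores[[block_of[[id]]]], pool, p$noise)
  }
  author_sets <- author_sets[lengths(author_sets) > 0L]
  contributors <- data.frame(
    author_id = unlist(author_sets, use.names = FALSE),
    node_id = rep(names(author_sets), lengths(author_sets)),
    stringsAsFactors = FALSE
  )

  # ---- outgoing references ---------------------------------------------
  all_ids <- nodes$node_id
  n_links <- stats::rpois(length(all_ids), p$refs_per_node)
  names(n_links) <- all_ids
  block_pool_size <- pmax(1L, stats::rpois(n_bottom, p$refs_per_node))
  block_pools <- lapply(seq_len(n_bottom), function(b) {
    sprintf("%s.R%03d", bottoms[b], seq_len(block_pool_size[b]))
  })
  names(block_pools) <- bottoms
  fresh_counter <- 0L
  link_node <- character(0)
  link_ref <- vector("list", length(all_ids))
  for (k in seq_along(all_ids)) {
    id <- all_ids[k]
    n_i <- n_links[[k]]
    if (n_i == 0L) next
    blk <- if (id %in% names(block_of)) block_of[[id]] else NA_character_
    shared <- if (!is.na(blk)) {
      pool_b <- block_pools[[blk]]
      k_sh <- min(stats::rbinom(1L, n_i, 0.15), length(pool_b))
      if (k_sh > 0L) sample(pool_b, k_sh) else character(0)
    } else character(0)
    n_fresh <- n_i - length(shared)
    fresh <- if (n_fresh > 0L) {
      out <- sprintf("R%06d", fresh_counter + seq_len(n_fresh))
      fresh_counter <- fresh_counter + n_fresh
      out
    } else character(0)
    link_ref[[k]] <- c(shared, fresh)
  }
  links <- data.frame(
    node_id = rep(all_ids, lengths(link_ref)),
    ref_id = unlist(link_ref, use.names = FALSE),
    stringsAsFactors = FALSE
  )

  ref_ids <- sort(unique(links$ref_id))
  n_refs <- length(ref_ids)
  surnames <- c("Almeida", "Baker", "Chen", "Diallo", "Evans", "Fischer",
                "Garcia", "Hansen", "Ito", "Johnson", "Kim", "Larsson",
                "Moreau", "Nkosi", "Okafor", "Patel", "Quinn", "Rossi",
                "Sato", "Tanaka", "Ueda", "Vargas", "Wang", "Xu", "Yilmaz",
                "Zhang")
  n_auth <- sample(1:6, n_refs, replace = TRUE)
  initials <- LETTERS[sample.int(26L, sum(n_auth), replace = TRUE)]
  name_draw <- paste0(sample(surnames, sum(n_auth), replace = TRUE), " ",
                      initials)
  ref_authors <- vapply(split(name_draw, rep(seq_len(n_refs), n_auth)),
                        paste, character(1), collapse = ";")
  venues <- c("J Synth Pharmacol", "Receptor Res", "Mol Targets",
              "Channels & Transporters", "Enzyme Biol", "Drug Discov Lett")
  years <- sample(1980:2024, n_refs, replace = TRUE)
  has_doi <- stats::runif(n_refs) < 0.6
  references <- data.frame(
    ref_id = ref_ids,
    title = paste("Characterisation of synthetic target", seq_len(n_refs)),
    authors = unname(ref_authors),
    venue = sample(venues, n_refs, replace = TRUE),
    year = years,
    external_id = ifelse(has_doi, sprintf("doi:10.9999/synth.%06d",
                                          seq_len(n_refs)), ""),
    stringsAsFactors = FALSE
  )

  h <- merge_contributors(h, contributors)
  h <- merge_references(h, references, links)
  structure(
    list(hierarchy = h, contributors = contributors,
         references = references, links = links,
         blocks = block_of, params = p),
    class = "synthetic_db"
  )
}

#' @export
print.synthetic_db <- function(x, ...) {
  cat("<synthetic_db> seed", x$params$seed, "noise", x$params$noise, "\n")
  print(x$hierarchy)
  invisible(x)
}

#' Write a synthetic database as the three interchange files
#'
#' @param db A [simulate_database()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.  Files written: `hierarchy.tsv`,
#'   `contributors.tsv`, `references.tsv`, `ref_links.tsv`.
#' @export
write_synthetic_db <- function(db, dir) {
  stopifnot(inherits(db, "synthetic_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hierarchy(db$hierarchy, file.path(dir, "hierarchy.tsv"))
  write_contributors(db$contributors, file.path(dir, "contributors.tsv"))
  write_references(db$references, file.path(dir, "references.tsv"))
  write_ref_links(db$links, file.path(dir, "ref_links.tsv"))
  invisible(dir)
}

# ---- worked-example fixtures ---------------------------------------------

#' Worked-example fixtures
#'
#' Small hand-checkable inputs used throughout the tests and documentation:
#' \describe{
#'   \item{`example_author_sets()`}{four three-element author sets over
#'     `{a, b, c, d}`, each omitting one author: every author contributes to
#'     exactly 3 of the 4 sets, so plain stress is 1 while the
#'     `"exponential"` alpha-stress is 0.5.}
#'   \item{`example_family_triple()`}{a parent family with author set
#'     `{a3, a4}` and two child families `{a1, a2, a3}` and `{a1, a2, a4}`
#'     under an authorless group.  All pairwise Jaccard distances are at
#'     least 0.5, yet the combined authorship is arguably coherent — the
#'     situation that motivates stress as a complement to pairwise
#'     clustering.}
#'   \item{`example_signed_graph()`}{a signed complete graph on five
#'     vertices whose unique optimal clustering is `{{1,2,3,4},{5}}` with
#'     one misplaced negative edge `(2,4)` and one misplaced positive edge
#'     `(1,5)`.}
#' }
#'
#' @return See each description.
#' @export
example_author_sets <- function() {
  list(c("b", "c", "d"), c("a", "c", "d"), c("a", "b", "d"), c("a", "b", "c"))
}

#' @rdname example_author_sets
#' @export
example_family_triple <- function() {
  nodes <- data.frame(
    node_id = c("grp", "fam", "fam.1", "fam.2"),
    label = c("Example group", "Parent family", "Child family 1",
              "Child family 2"),
    level_kind = c("group", "family", "family", "family"),
    parents = c("", "grp", "fam", "fam"),
    description = "",
    stringsAsFactors = FALSE
  )
  h <- hierarchy(nodes)
  contributors <- data.frame(
    author_id = c("a3", "a4", "a1", "a2", "a3", "a1", "a2", "a4"),
    node_id = c("fam", "fam", "fam.1", "fam.1", "fam.1", "fam.2", "fam.2",
                "fam.2"),
    stringsAsFactors = FALSE
  )
  merge_contributors(h, contributors)
}

#' @rdname example_author_sets
#' @export
example_signed_graph <- function() {
  signed_graph(
    as.character(1:5),
    positive = cbind(c("1", "1", "1", "2", "3", "1"),
                     c("2", "3", "4", "3", "4", "5")),
    negative = cbind(c("2", "2", "3", "4"),
                     c("4", "5", "5", "5"))
  )
}
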