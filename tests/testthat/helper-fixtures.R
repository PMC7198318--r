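# shared fixture builders; everything is generated in code at test time

# random multiset of author sets over a small pool
rand_family <- function(n_sets = NULL, pool = letters[1:8], p = 0.4) {
  if (is.null(n_sets)) n_sets <- sample(2:5, 1)
  repeat {
    fam <- lapply(seq_len(n_sets), function(i) pool[runif(length(pool)) < p])
    if (sum(lengths(fam)) > 0) return(fam)
  }
}

# random complete signed graph on n vertices, each edge +/- with prob p_pos
rand_signed_graph <- function(n, p_pos = 0.5) {
  v <- as.character(seq_len(n))
  pairs <- t(combn(v, 2))
  pos <- runif(nrow(pairs)) < p_pos
  signed_graph(v,
               positive = pairs[pos, , drop = FALSE],
               negative = pairs[!pos, , drop = FALSE])
}

# shorthand node-table builder: mk_nodes("id|kind|parents", ...)
mk_nodes <- function(...) {
  rows <- lapply(list(...), function(s) {
    f <- strsplit(s, "|", fixed = TRUE)[[1]]
    data.frame(node_id = f[1], label = paste("Node", f[1]),
               level_kind = f[2],
               parents = if (length(f) >= 3) f[3] else "",
               description = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# small-scale generator settings for fast property tests
small_params <- function(seed, noise = 0, multi_parent_rate = 0) {
  generator_params(n_groups = 2, families_per_group = c(2, 3),
                   objects_per_family = 2, author_pool = 60, block_size = 3,
                   noise = noise, refs_per_node = 4,
                   multi_parent_rate = multi_parent_rate, seed = seed)
}

# a hierarchy + contributor fixture with two planted author blocks under an
# authorless parent family
two_block_hierarchy <- function() {
  h <- hierarchy(mk_nodes(
    "g|group", "p|family|g", "p.a|family|p", "p.b|family|p"
  ))
  merge_contributors(h, data.frame(
    author_id = c("x1", "x2", "y1", "y2"),
    node_id = c("p.a", "p.a", "p.b", "p.b"),
    stringsAsFactors = FALSE
  ))
}
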