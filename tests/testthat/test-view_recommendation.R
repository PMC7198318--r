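test_that("stress report separates sub-stress from stress with own authors", {
  h <- example_family_triple()
  r <- stress_report(h)
  fam <- r[r$node_id == "fam", ]
  # descendants {a1,a2,a3} and {a1,a2,a4}: intersection 2 of union 4
  expect_equal(fam$sub_stress, 0.5)
  # adding the parent's own {a3,a4} empties the intersection
  expect_equal(fam$stress_value, 1)
  # leaves have no descendant sets
  expect_true(is.na(r$sub_stress[r$node_id == "fam.1"]))

  # a family whose objects all share one author set has sub-stress 0
  h2 <- hierarchy(mk_nodes("g|group", "f|family|g", "o1|object|f",
                           "o2|object|f"))
  h2 <- merge_contributors(h2, data.frame(
    author_id = c("a", "b", "a", "b"),
    node_id = c("o1", "o1", "o2", "o2")))
  r2 <- stress_report(h2)
  expect_equal(r2$sub_stress[r2$node_id == "f"], 0)
  # node with no authored descendants -> undefined
  expect_true(is.na(r2$sub_stress[r2$node_id == "o1"]))
})

test_that("sub-stress never exceeds stress where both are defined", {
  for (seed in 1:3) {
    db <- simulate_database(small_params(seed, noise = 0.3))
    for (a in c("indicator", "exponential")) {
      r <- stress_report(db$hierarchy, alpha = a)
      both <- !is.na(r$sub_stress) & !is.na(r$stress_value)
      expect_true(any(both))
      expect_true(all(r$sub_stress[both] <= r$stress_value[both] + 1e-12))
    }
  }
})

test_that("level table gives per-level means over defined values", {
  # zero-noise blocks: bottom-level sub-stress means are 0
  db <- simulate_database(small_params(2, noise = 0))
  lt <- level_table(stress_report(db$hierarchy))
  expect_equal(lt$level_kind, c("group", "family", "object"))
  fam_row <- lt[lt$level_kind == "family", ]
  expect_gt(fam_row$n_sub_defined, 0)
  # families at the bottom have identical member sets; intermediate families
  # mix blocks, so only check the bottom families directly
  r <- stress_report(db$hierarchy)
  bottoms <- citesum:::bottom_families(db$hierarchy)
  bsub <- r$sub_stress[match(bottoms, r$node_id)]
  expect_equal(mean(bsub, na.rm = TRUE), 0)

  # a level with no defined stress reports n = 0 and an empty mean
  h <- hierarchy(mk_nodes("g|group", "f|family|g"))
  lt0 <- level_table(stress_report(h))
  expect_equal(lt0$n_stress_defined[lt0$level_kind == "group"], 0)
  expect_true(is.na(lt0$mean_stress[lt0$level_kind == "group"]))

  # GtoPdb-scale preset: three level rows
  expect_equal(nrow(lt), 3L)
})

test_that("the bottom-up procedure assigns the documented cases", {
  # authored family whose objects share its authors: one auto root, case 2a
  h <- hierarchy(mk_nodes("g|group", "f|family|g", "o1|object|f",
                          "o2|object|f"))
  h <- merge_contributors(h, data.frame(
    author_id = c("a", "b", "a", "b", "a", "b"),
    node_id = c("f", "f", "o1", "o1", "o2", "o2")))
  plan <- recommend_views(h)
  expect_equal(plan$roots$node_id, "f")
  expect_equal(plan$roots$case, "2a")
  expect_equal(plan$roots$flag, "auto")

  # authorless parent over two disjoint author blocks: each child has zero
  # stress but jointly they exceed the threshold -> case 1b, roots at children
  h2 <- two_block_hierarchy()
  plan2 <- recommend_views(h2)
  expect_setequal(plan2$roots$node_id, c("p.a", "p.b"))
  expect_equal(plan2$rationale[["p"]], "1b")

  # authorless parent with jointly coherent children -> case 1a at the
  # parent, flagged for review
  h3 <- hierarchy(mk_nodes("g|group", "p|family|g", "p.a|family|p",
                           "p.b|family|p"))
  h3 <- merge_contributors(h3, data.frame(
    author_id = c("x1", "x2", "x1", "x2"),
    node_id = c("p.a", "p.a", "p.b", "p.b")))
  plan3 <- recommend_views(h3)
  expect_equal(plan3$roots$node_id, "p")
  expect_equal(plan3$roots$case, "1a")
  expect_equal(plan3$roots$flag, "needs_review")

  # authored parent incompatible with its children -> children keep their
  # roots and the parent is flagged (case 2b)
  h4 <- merge_contributors(
    hierarchy(mk_nodes("g|group", "p|family|g", "p.a|family|p",
                       "p.b|family|p")),
    data.frame(
    author_id = c("z1", "z2", "x1", "x2", "y1", "y2"),
    node_id = c("p", "p", "p.a", "p.a", "p.b", "p.b")))
  plan4 <- recommend_views(h4)
  expect_setequal(plan4$roots$node_id, c("p.a", "p.b"))
  expect_equal(plan4$rationale[["p"]], "2b")
  expect_equal(plan4$flags[["p"]], "needs_review")
})

test_that("plans cover every authored bottom family once and form an antichain", {
  for (seed in 1:4) {
    db <- simulate_database(small_params(seed, noise = 0.25))
    h <- db$hierarchy
    plan <- recommend_views(h)
    roots <- plan$roots$node_id
    # antichain: no root is a strict descendant of another
    for (r in roots) {
      expect_length(intersect(setdiff(descendants(h, r), r), roots), 0)
    }
    # coverage: each authored bottom-level family under exactly one root
    bottoms <- citesum:::bottom_families(h)
    authored <- bottoms[vapply(bottoms, function(b) {
      any(lengths(h$authors[descendants(h, b)]) > 0)
    }, logical(1))]
    cover <- vapply(authored, function(b) {
      sum(vapply(roots, function(r) b %in% descendants(h, r), logical(1)))
    }, integer(1))
    expect_true(all(cover == 1L))
  }
})

test_that("lowering the threshold never reduces the number of view roots", {
  for (seed in 1:3) {
    db <- simulate_database(small_params(seed, noise = 0.4))
    r <- stress_report(db$hierarchy)
    n_roots <- vapply(c(0.1, 0.3, 0.5, 0.8), function(low) {
      nrow(recommend_views(db$hierarchy, r, low = low)$roots)
    }, integer(1))
    expect_true(all(diff(n_roots) <= 0))
  }
})

test_that("at zero noise the plan recovers the planted blocks exactly", {
  db <- simulate_database(small_params(11, noise = 0))
  plan <- recommend_views(db$hierarchy, low = 0.3)
  expect_setequal(plan$roots$node_id, unique(unname(db$blocks)))
})
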