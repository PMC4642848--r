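test_that("variable ordering starts at a hub and keeps parents placed first", {
  ord <- compute_ordering(mk(c("a", "b"), c("b", "c")))
  expect_equal(ord$node[1], "b")
  expect_true(is.na(ord$parent[1]))
  expect_equal(ord$parent[2:3], c("b", "b"))

  single <- compute_ordering(labeled_graph(nodes = "only"))
  expect_equal(single$node, "only")
  expect_true(is.na(single$parent))

  # feed-forward loop: all degrees equal, tie broken deterministically on id
  ord_ffl <- compute_ordering(ffl_query())
  expect_equal(ord_ffl$node[1], "a")
  expect_false(any(is.na(ord_ffl$parent[2:3])))
})

test_that("orderings are valid permutations with earlier adjacent parents", {
  for (seed in 1:25) {
    q <- withr::with_seed(seed, {
      rand_labeled(sample(1:6, 1), sample(0:8, 1), sample(c(TRUE, FALSE), 1),
                   character())
    })
    ord <- compute_ordering(q)
    expect_setequal(ord$node, igraph::V(q)$name)
    for (i in seq_len(nrow(ord))) {
      p <- ord$parent[i]
      if (!is.na(p)) {
        expect_lt(match(p, ord$node), i)
        expect_gt(igraph::get_edge_ids(
          igraph::as_undirected(q, mode = "collapse"),
          c(p, ord$node[i])), 0)
      }
    }
  }
})

test_that("worked occurrence counts match brute force", {
  ffl <- ffl_query()
  expect_equal(nrow(brute_force_match(ffl, k_digraph(3))), 6)
  expect_equal(count_occurrences(ffl, k_digraph(3)), 6)

  c3 <- mk(c("x", "y"), c("y", "z"), c("z", "x"), directed = TRUE)
  expect_equal(nrow(brute_force_match(ffl, c3)), 0)
  expect_equal(count_occurrences(ffl, c3), 0)

  # a single wildcard node matches every target node
  wild <- labeled_graph(nodes = "w", directed = TRUE)
  tgt <- k_digraph(5)
  expect_equal(count_occurrences(wild, tgt), 5)

  # triangle cannot embed in the 4-cycle
  tri <- mk(c("a", "b"), c("b", "c"), c("c", "a"))
  c4 <- mk(c("p", "q"), c("q", "r"), c("r", "s"), c("s", "p"))
  expect_equal(count_occurrences(tri, c4), 0)
  expect_equal(nrow(brute_force_match(tri, c4)), 0)
})

test_that("single-edge queries count direction and symmetry correctly", {
  e_dir <- mk(c("a", "b"), directed = TRUE)
  t_dir <- mk(c("x", "y"), directed = TRUE)
  expect_equal(nrow(brute_force_match(e_dir, t_dir)), 1)
  expect_equal(count_occurrences(e_dir, t_dir), 1)

  e_und <- mk(c("a", "b"))
  t_und <- mk(c("x", "y"))
  expect_equal(nrow(brute_force_match(e_und, t_und)), 2)
  expect_equal(count_occurrences(e_und, t_und), 2)

  big <- mk(c("a", "b"), c("b", "c"), c("c", "a"))
  expect_equal(nrow(brute_force_match(big, e_und)), 0)
})

test_that("matcher agrees with the brute-force oracle on random instances", {
  for (seed in 1:80) {
    case <- rand_case(seed, allow_constraints = FALSE)
    got <- match_exact(case$query, case$target)
    want <- brute_force_match(case$query, case$target)
    expect_same_matches(got, want)
    expect_equal(count_occurrences(case$query, case$target), nrow(want))
  }
})

test_that("every returned match satisfies the mapping invariants", {
  for (seed in c(3, 17, 42)) {
    case <- rand_case(seed, allow_constraints = FALSE)
    q <- case$query; tg <- case$target
    m <- match_exact(q, tg)
    qel <- igraph::as_edgelist(q, names = TRUE)
    qlab <- igraph::vertex_attr(q, "label")
    names(qlab) <- igraph::V(q)$name
    tlab <- igraph::vertex_attr(tg, "label")
    names(tlab) <- igraph::V(tg)$name
    for (i in seq_len(nrow(m))) {
      row <- unlist(m[i, ])
      expect_equal(anyDuplicated(row), 0)  # injective
      for (e in seq_len(nrow(qel))) {
        expect_gt(igraph::get_edge_ids(
          tg, c(row[[qel[e, 1]]], row[[qel[e, 2]]]), error = FALSE), 0)
      }
      for (v in names(row)) {
        expect_true(labels_compatible(qlab[[v]], tlab[[row[[v]]]]))
      }
    }
  }
})

test_that("adding a query edge never increases the match count", {
  for (seed in 1:20) {
    case <- rand_case(seed, allow_constraints = FALSE)
    q <- case$query
    nq <- igraph::vcount(q)
    if (nq < 2) next
    nm <- igraph::V(q)$name
    pairs <- t(utils::combn(nm, 2))
    present <- apply(pairs, 1, function(p) {
      igraph::get_edge_ids(q, p, error = FALSE) > 0 ||
        igraph::get_edge_ids(q, rev(p), error = FALSE) > 0
    })
    if (all(present)) next
    add <- pairs[which(!present)[1], ]
    q2 <- igraph::add_edges(q, add, label = NA_character_)
    expect_lte(count_occurrences(q2, case$target),
               count_occurrences(q, case$target))
  }
})

test_that("match lists are deterministic and unlabeled counts match igraph", {
  case <- rand_case(7, allow_constraints = FALSE)
  expect_identical(match_exact(case$query, case$target),
                   match_exact(case$query, case$target))

  # independent library cross-check on unlabeled graphs
  for (seed in 1:5) {
    tg <- synth_network(7, 12, directed = TRUE, seed = seed)
    q <- ffl_query()
    ref <- length(igraph::subgraph_isomorphisms(q, tg, method = "lad",
                                                induced = FALSE))
    expect_equal(count_occurrences(q, tg), ref)
  }
})

test_that("distinct_node_sets collapses automorphic images", {
  sim <- motif_graph("single_input_module")
  tgt <- mk(c("h", "x"), c("h", "y"), c("h", "z"), directed = TRUE)
  expect_equal(nrow(match_exact(sim, tgt)), 6)  # 3! leaf permutations
  expect_equal(nrow(match_exact(sim, tgt, distinct_node_sets = TRUE)), 1)
})

test_that("directedness mismatch is an error", {
  expect_error(match_exact(mk(c("a", "b"), directed = TRUE), mk(c("x", "y"))),
               "directedness")
})
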