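test_that("path expressions parse and normalize", {
  pc <- parse_path_expression("?<=2")
  expect_equal(pc$op, "<=")
  expect_equal(pc$bound, 2L)

  pc2 <- parse_path_expression("?>3")
  expect_equal(pc2$op, ">")
  expect_equal(pc2$bound, 3L)

  # "?=1" is just an ordinary wildcard edge
  pc3 <- parse_path_expression("?=1")
  expect_equal(pc3$op, "=")
  expect_equal(pc3$bound, 1L)

  # integer on the left: the relation is read from the other side
  pc4 <- parse_path_expression("2<=?")
  expect_equal(pc4$op, ">=")
  expect_equal(pc4$bound, 2L)
  expect_equal(parse_path_expression("? >= 4")$bound, 4L)

  expect_error(parse_path_expression("?<=0"), "positive")
  expect_error(parse_path_expression("?<=x"), "parse")
  expect_error(parse_path_expression("?~2"), "parse")
  expect_error(parse_path_expression("1<=2"), "exactly one side")
  expect_error(parse_path_expression("?<=?"), "exactly one side")
})

test_that("decompose splits constraints from the exact part", {
  q <- mk(c("a", "b"), c("b", "c"), c("a", "c"), directed = TRUE,
          node_labels = c(a = "TF", b = "kinase"))
  q <- set_path_constraint(q, "a", "c", "?<=2")
  parts <- decompose_query(q)
  expect_equal(igraph::vcount(parts$exact), 3)
  expect_equal(igraph::ecount(parts$exact), 2)
  expect_equal(nrow(parts$constraints), 1)
  expect_equal(parts$constraints$from, "a")
  expect_equal(parts$constraints$bound, 2L)

  plain <- mk(c("a", "b"))
  parts2 <- decompose_query(plain)
  expect_true(graph_equal(parts2$exact, plain))
  expect_equal(nrow(parts2$constraints), 0)

  all_path <- set_path_constraint(mk(c("a", "b"), directed = TRUE),
                                  "a", "b", "?>1")
  parts3 <- decompose_query(all_path)
  expect_equal(igraph::ecount(parts3$exact), 0)
  expect_equal(igraph::vcount(parts3$exact), 2)
})

test_that("path lengths and constraint satisfaction use BFS distance", {
  chain <- mk(c("a", "b"), c("b", "c"), c("c", "d"), directed = TRUE)
  expect_equal(path_length(chain, "a", "a"), 0)
  expect_equal(path_length(chain, "a", "b"), 1)
  expect_equal(path_length(chain, "a", "d"), 3)
  expect_equal(path_length(chain, "d", "a"), Inf)  # direction respected

  expect_true(satisfies("?<=2", chain, "a", "c"))
  expect_false(satisfies("?<=2", chain, "a", "d"))
  expect_false(satisfies("?<=2", chain, "d", "a"))  # unreachable

  six <- mk(c("p1", "p2"), c("p2", "p3"), c("p3", "p4"), c("p4", "p5"),
            c("p5", "p6"), directed = TRUE)
  expect_true(satisfies("?>3", six, "p1", "p5"))   # distance 4
  expect_false(satisfies("?>3", six, "p1", "p3"))  # distance 2
  expect_false(satisfies("?>3", six, "p6", "p1"))  # unreachable
})

test_that("approximate matching joins exact parts with path checks", {
  tgt <- mk(c("x", "y"), c("y", "z"), directed = TRUE)
  q <- set_path_constraint(mk(c("a", "b"), directed = TRUE), "a", "b", "?<=2")
  m <- match_approximate(q, tgt)
  expect_equal(nrow(m), 3)
  expect_setequal(paste(m$a, m$b), c("x y", "y z", "x z"))

  q2 <- set_path_constraint(mk(c("a", "b"), directed = TRUE), "a", "b", "?>1")
  m2 <- match_approximate(q2, tgt)
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$a, m2$b), c("x", "z"))
})

test_that("a constraint-free query reduces exactly to exact matching", {
  for (seed in 1:10) {
    case <- rand_case(seed, allow_constraints = FALSE)
    expect_identical(match_approximate(case$query, case$target),
                     match_exact(case$query, case$target))
  }
})

test_that("?=1 is equivalent to an ordinary wildcard edge", {
  for (seed in 1:10) {
    case <- rand_case(seed, allow_constraints = FALSE)
    q <- case$query
    if (igraph::ecount(q) == 0) next
    el <- igraph::as_edgelist(q, names = TRUE)
    lab <- igraph::edge_attr(q, "label")
    plain <- q
    if (!is.null(lab)) {
      lab[1] <- NA_character_
      plain <- igraph::set_edge_attr(q, "label", value = lab)
    }
    constrained <- set_path_constraint(plain, el[1, 1], el[1, 2], "?=1")
    expect_same_matches(match_approximate(constrained, case$target),
                        match_exact(plain, case$target))
  }
})

test_that("raising a <= bound never loses matches", {
  for (seed in 1:10) {
    case <- rand_case(seed, allow_constraints = FALSE)
    q <- case$query
    if (igraph::ecount(q) == 0) next
    el <- igraph::as_edgelist(q, names = TRUE)
    counts <- vapply(1:3, function(b) {
      nrow(match_approximate(
        set_path_constraint(q, el[1, 1], el[1, 2], sprintf("?<=%d", b)),
        case$target))
    }, 0)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("approximate matcher agrees with brute force on constrained queries", {
  for (seed in 101:140) {
    case <- rand_case(seed, allow_constraints = TRUE)
    expect_same_matches(match_approximate(case$query, case$target),
                        brute_force_match(case$query, case$target))
  }
})
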