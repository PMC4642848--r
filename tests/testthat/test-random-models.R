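deg_sig <- function(g) {
  if (igraph::is_directed(g)) {
    list(out = sort(igraph::degree(g, mode = "out")),
         inn = sort(igraph::degree(g, mode = "in")))
  } else {
    list(all = sort(igraph::degree(g)))
  }
}

test_that("shuffling preserves the degree sequence exactly", {
  for (seed in 1:15) {
    tg <- synth_network(20, 35, n_labels = 3,
                        directed = seed %% 2 == 0, seed = seed)
    sh <- generate_shuffled(tg, sw_per_edge = 5, seed = seed + 100)
    expect_equal(deg_sig(sh), deg_sig(tg))
    expect_equal(igraph::vcount(sh), 20)
    expect_equal(igraph::ecount(sh), 35)
    # node-label multiset is conserved
    expect_equal(sort(igraph::V(sh)$label), sort(igraph::V(tg)$label))
  }
})

test_that("zero swaps is the identity and tiny graphs warn", {
  tg <- synth_network(10, 15, directed = TRUE, seed = 1)
  expect_true(graph_equal(generate_shuffled(tg, sw_per_edge = 0), tg))
  one <- mk(c("a", "b"), directed = TRUE)
  expect_warning(copy <- generate_shuffled(one, sw_per_edge = 10, seed = 1),
                 "no swap")
  expect_true(graph_equal(copy, one))
})

test_that("a shuffled 4-cycle stays 2-regular on 4 nodes", {
  c4 <- mk(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a"))
  for (seed in 1:10) {
    sh <- generate_shuffled(c4, sw_per_edge = 20, seed = seed)
    expect_equal(igraph::vcount(sh), 4)
    expect_equal(igraph::ecount(sh), 4)
    expect_true(all(igraph::degree(sh) == 2))
  }
})

test_that("Erdos-Renyi hits its closed forms and binomial mean", {
  expect_equal(igraph::ecount(generate_er(4, 1, seed = 1)), 6)
  expect_equal(igraph::ecount(generate_er(10, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(generate_er(4, 1, directed = TRUE, seed = 1)), 12)

  counts <- vapply(1:300, function(s) {
    igraph::ecount(generate_er(30, 0.1, seed = s))
  }, 0)
  npairs <- choose(30, 2)
  expect_lt(abs(mean(counts) - npairs * 0.1),
            3 * sqrt(npairs * 0.1 * 0.9 / 300))
})

test_that("Watts-Strogatz is a 2d-regular lattice at beta = 0", {
  g <- generate_ws(8, 2, 0, seed = 1)
  expect_true(all(igraph::degree(g) == 4))
  expect_equal(igraph::ecount(g), 16)
  expect_error(generate_ws(4, 2, 0), "n > 2")

  # beta = 1 scatters the degrees; edge count is conserved regardless
  degvar <- vapply(1:30, function(s) {
    g1 <- generate_ws(100, 2, 1, seed = s)
    expect_equal(igraph::ecount(g1), 200)
    stats::var(igraph::degree(g1))
  }, 0)
  expect_true(all(degvar > 0))
})

test_that("Barabasi-Albert obeys the edge-count identity and grows hubs", {
  expect_equal(igraph::ecount(generate_ba(3, 3, 1, seed = 1)), 3)  # n = k
  for (s in 1:5) {
    g <- generate_ba(50, 4, 2, seed = s)
    expect_equal(igraph::ecount(g), choose(4, 2) + (50 - 4) * 2)
    expect_equal(igraph::vcount(g), 50)
  }
  # preferential attachment makes bigger hubs than a density-matched ER graph
  wins <- sum(vapply(1:40, function(s) {
    ba <- generate_ba(200, 3, 1, seed = s)
    er <- generate_er(200, igraph::ecount(ba) / choose(200, 2), seed = s + 1e4)
    max(igraph::degree(ba)) > max(igraph::degree(er))
  }, TRUE))
  expect_gte(wins, 34)
})

test_that("geometric extremes give empty and complete graphs", {
  expect_equal(igraph::ecount(generate_geometric(20, 2, 0, seed = 1)), 0)
  expect_equal(igraph::ecount(generate_geometric(10, 2, sqrt(2), seed = 1)),
               choose(10, 2))
  # Monte-Carlo mean against a numerically integrated edge probability
  p_edge <- withr::with_seed(999, {
    a <- matrix(runif(2e5), ncol = 2); b <- matrix(runif(2e5), ncol = 2)
    mean(sqrt(rowSums((a - b)^2)) <= 0.2)
  })
  counts <- vapply(1:100, function(s) {
    igraph::ecount(generate_geometric(40, 2, 0.2, seed = s))
  }, 0)
  expected <- choose(40, 2) * p_edge
  expect_lt(abs(mean(counts) - expected), 4 * stats::sd(counts) / sqrt(100))
})

test_that("forest fire without spread is an out-tree", {
  g <- generate_ff(30, 0, 0, ambassadors = 1, seed = 1)
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::ecount(g), 29)
  expect_true(all(igraph::degree(g, mode = "out")[-1] >= 1))
  expect_equal(igraph::ecount(generate_ff(1, 0.5, 0.2, 1, seed = 1)), 0)
})

test_that("forest fire densifies as the burn probabilities rise", {
  m_low <- mean(vapply(1:10, function(s) {
    igraph::ecount(generate_ff(80, 0.1, 0.05, 1, seed = s))
  }, 0))
  m_high <- mean(vapply(1:10, function(s) {
    igraph::ecount(generate_ff(80, 0.35, 0.2, 1, seed = s))
  }, 0))
  expect_gt(m_high, m_low)
})

test_that("duplication copies neighborhoods and matches its recurrence", {
  g1 <- generate_duplication(20, 5, 0, seed = 1)
  expect_equal(igraph::ecount(g1), 5)  # only the seed ring
  g2 <- generate_duplication(20, 5, 1, seed = 1)
  expect_true(all(igraph::degree(g2)[6:20] >= 1))

  counts <- vapply(1:100, function(s) {
    igraph::ecount(generate_duplication(60, 5, 0.5, seed = s))
  }, 0)
  expected <- netmotif:::duplication_expected_edges(60, 5, 0.5)
  expect_lt(abs(mean(counts) - expected), 4 * stats::sd(counts) / sqrt(100))
})

test_that("all generators are deterministic under a fixed seed", {
  tg <- synth_network(40, 90, n_labels = 4, directed = TRUE, seed = 11)
  for (model in c("shuffling", "erdos_renyi", "watts_strogatz",
                  "barabasi_albert", "geometric", "forest_fire",
                  "duplication")) {
    config <- estimate_params(model, tg)
    g1 <- generate_null(tg, config, seed = 42)
    g2 <- generate_null(tg, config, seed = 42)
    expect_true(graph_equal(g1, g2))
    expect_equal(igraph::vcount(g1), 40)
    expect_true(igraph::is_directed(g1))
    expect_false(igraph::any_loop(g1))
    expect_false(igraph::any_multiple(g1))
    # replicas carry the target's node-label multiset
    expect_equal(sort(igraph::V(g1)$label), sort(igraph::V(tg)$label))
  }
})

test_that("estimated parameters reproduce the target edge count", {
  und <- synth_network(100, 200, seed = 3)
  expect_equal(estimate_params("watts_strogatz", und)$params$d, 2)
  full <- synth_network(10, 45, seed = 4)
  expect_equal(estimate_params("erdos_renyi", full)$params$p, 1)

  for (model in c("erdos_renyi", "geometric", "duplication")) {
    config <- estimate_params(model, und)
    ms <- vapply(1:40, function(s) {
      igraph::ecount(generate_null(und, config, seed = s))
    }, 0)
    # calibrated to within 5% of |E|, plus Monte-Carlo noise
    expect_lt(abs(mean(ms) - 200),
              0.05 * 200 + 3 * stats::sd(ms) / sqrt(40))
  }
})

test_that("label assignment permutes the target's label multiset", {
  tg <- synth_network(30, 60, n_labels = 3, seed = 5)
  g <- generate_er(30, 0.2, seed = 9)
  lg <- assign_labels(g, tg, seed = 10)
  expect_equal(sort(igraph::V(lg)$label), sort(igraph::V(tg)$label))
  unlab <- assign_labels(generate_er(30, 0.2, seed = 1),
                         synth_network(30, 40, seed = 6))
  expect_true(all(is.na(netmotif:::node_labels_of(unlab))))
})
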