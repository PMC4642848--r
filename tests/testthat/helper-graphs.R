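# Shared builders for the test suite. Everything is generated in code; no
# fixture files are required beyond the package's own motif library.

mk <- function(..., directed = FALSE, node_labels = NULL, edge_labels = NULL,
               nodes = NULL) {
  pairs <- list(...)
  edges <- if (length(pairs) == 0) NULL else do.call(rbind, pairs)
  suppressWarnings(
    labeled_graph(edges, nodes = nodes, directed = directed,
                  node_labels = node_labels, edge_labels = edge_labels))
}

# complete digraph on letters[1:n]
k_digraph <- function(n) {
  v <- letters[seq_len(n)]
  el <- expand.grid(from = v, to = v, stringsAsFactors = FALSE)
  el <- el[el$from != el$to, ]
  labeled_graph(as.matrix(el), directed = TRUE)
}

ffl_query <- function() {
  mk(c("a", "b"), c("a", "c"), c("b", "c"), directed = TRUE)
}

# canonical form for comparing match sets regardless of discovery order
norm_matches <- function(m) {
  df <- as.data.frame(m)
  if (nrow(df) > 0) df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# a random labeled graph with n nodes, m edges, labels drawn from a pool
# (with some chance of staying unlabeled); used for oracle instances
rand_labeled <- function(n, m, directed, lab_pool, prefix = "t",
                         p_node_lab = 0.6, p_edge_lab = 0.3) {
  nm <- paste0(prefix, seq_len(n))
  npairs <- if (directed) n * (n - 1) else n * (n - 1) / 2
  m <- min(m, npairs)
  pairs <- if (n < 2) matrix(integer(), ncol = 2) else t(utils::combn(n, 2))
  if (directed) pairs <- rbind(pairs, pairs[, 2:1, drop = FALSE])
  el <- pairs[sample.int(nrow(pairs), m), , drop = FALSE]
  pick_lab <- function(k, p) {
    ifelse(length(lab_pool) > 0 & runif(k) < p,
           sample(c(lab_pool, lab_pool), k, replace = TRUE), NA_character_)
  }
  node_labels <- stats::setNames(pick_lab(n, p_node_lab), nm)
  edge_labels <- pick_lab(m, p_edge_lab)
  labeled_graph(cbind(nm[el[, 1]], nm[el[, 2]]), nodes = nm,
                directed = directed, node_labels = node_labels,
                edge_labels = edge_labels)
}

# one randomized (query, target) oracle instance; small enough for brute force
rand_case <- function(seed, allow_constraints = TRUE) {
  withr::with_seed(seed, {
    directed <- sample(c(TRUE, FALSE), 1)
    nlab <- sample(0:8, 1)
    pool <- if (nlab > 0) paste0("L", seq_len(nlab)) else character()
    nt <- sample(3:8, 1)
    mt <- sample(0:(nt * (nt - 1) / 2), 1)
    target <- rand_labeled(nt, mt, directed, pool, prefix = "t")
    nq <- sample(1:4, 1)
    mq <- sample(0:(nq * (nq - 1) / 2), 1)
    query <- rand_labeled(nq, mq, directed, pool, prefix = "q",
                          p_node_lab = 0.4, p_edge_lab = 0.2)
    if (allow_constraints && igraph::ecount(query) > 0 && runif(1) < 0.4) {
      el <- igraph::as_edgelist(query, names = TRUE)
      e <- sample.int(nrow(el), 1)
      expr <- sprintf("?%s%d", sample(c("<", "<=", ">=", ">", "="), 1),
                      sample(1:3, 1))
      query <- set_path_constraint(query, el[e, 1], el[e, 2], expr)
    }
    list(query = query, target = target, directed = directed)
  })
}

expect_same_matches <- function(a, b) {
  expect_equal(norm_matches(a), norm_matches(b))
}
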