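#' @title Random-graph null models
#' @description
#' Seven generators used as null models for motif significance. Each replica
#' has exactly `|V|` nodes carrying the target network's labels. The
#' shuffling and forest-fire models handle edge direction natively; the
#' Erdos-Renyi model samples ordered pairs directly in directed mode; the
#' remaining generators build undirected structure and, for directed
#' targets, orient each edge with an independent fair coin.
#' @name null-models
NULL

MODEL_NAMES <- c("shuffling", "erdos_renyi", "watts_strogatz",
                 "barabasi_albert", "geometric", "forest_fire", "duplication")

with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

vertex_names <- function(n) paste0("v", seq_len(n))

graph_from_int_edges <- function(edges, n, directed) {
  nm <- vertex_names(n)
  if (length(edges) == 0) edges <- matrix(integer(), ncol = 2)
  labeled_graph(cbind(nm[edges[, 1]], nm[edges[, 2]]), nodes = nm,
                directed = directed)
}

# fair-coin orientation of an undirected structure, for directed targets
orient_edges <- function(edges) {
  if (nrow(edges) == 0) return(edges)
  flip <- runif(nrow(edges)) < 0.5
  edges[flip, ] <- edges[flip, 2:1, drop = FALSE]
  edges
}

all_pairs <- function(n, directed) {
  if (n < 2) return(matrix(integer(), ncol = 2))
  und <- t(utils::combn(n, 2L))
  if (!directed) und else rbind(und, und[, 2:1, drop = FALSE])
}

#' Null-model configuration
#'
#' @param model one of `"shuffling"`, `"erdos_renyi"`, `"watts_strogatz"`,
#'   `"barabasi_albert"`, `"geometric"`, `"forest_fire"`, `"duplication"`.
#' @param params named list of model parameters (see the individual
#'   `generate_*` functions); probabilities must lie in `[0, 1]` and counts
#'   be at least 1.
#' @param seed integer seed or `NULL`.
#' @return an object of class `model_config`.
#' @export
model_config <- function(model = MODEL_NAMES, params = list(), seed = NULL) {
  model <- match.arg(model)
  allowed <- switch(model,
    shuffling = c("sw_per_edge", "label_shuffle"),
    erdos_renyi = "p",
    watts_strogatz = c("d", "beta"),
    barabasi_albert = c("init_nodes", "d"),
    geometric = c("dim", "radius"),
    forest_fire = c("p_forward", "r_backward", "ambassadors"),
    duplication = c("init_nodes", "edge_prob"))
  extra <- setdiff(names(params), allowed)
  if (length(extra) > 0) {
    abort(sprintf("parameters %s do not belong to model '%s'",
                  paste(extra, collapse = ", "), model))
  }
  probs <- intersect(names(params),
                     c("p", "beta", "p_forward", "r_backward", "edge_prob"))
  for (nm in probs) {
    if (params[[nm]] < 0 || params[[nm]] > 1) {
      abort(sprintf("parameter '%s' must be a probability in [0, 1]", nm))
    }
  }
  counts <- intersect(names(params),
                      c("d", "init_nodes", "dim", "ambassadors"))
  for (nm in counts) {
    if (params[[nm]] < 1) abort(sprintf("parameter '%s' must be >= 1", nm))
  }
  structure(list(model = model, params = params, seed = seed),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  ps <- if (length(x$params) == 0) "(none)" else
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  cat(sprintf("<model_config: %s | %s | seed=%s>\n", x$model, ps,
              x$seed %||% "NULL"))
  invisible(x)
}

#' Degree-preserving shuffling (switching) null model
#'
#' Randomizes a network by repeated double-edge swaps: two distinct edges
#' `(a,b)` and `(c,d)` are replaced by `(a,d)` and `(c,b)` when the result
#' creates no self-loop or duplicate. Exactly `ceiling(sw_per_edge * |E|)`
#' *successful* swaps are performed, so the degree sequence (in- and
#' out-degree separately for directed graphs) is conserved exactly. With
#' `label_shuffle`, node labels and edge labels are additionally each
#' permuted uniformly (and independently).
#'
#' @param target the network to randomize (labels travel with it).
#' @param sw_per_edge successful swaps per edge (default 10).
#' @param label_shuffle permute node and edge labels too?
#' @param seed integer seed or `NULL` to use the current RNG stream.
#' @return a labeled graph with the same nodes and degree sequence.
#' @export
generate_shuffled <- function(target, sw_per_edge = 10, label_shuffle = FALSE,
                              seed = NULL) {
  with_seed_opt(seed, {
    directed <- igraph::is_directed(target)
    n <- igraph::vcount(target)
    el <- igraph::as_edgelist(target, names = FALSE)
    m <- nrow(el)
    elab <- edge_labels_of(target)
    needed <- ceiling(sw_per_edge * m)
    if (m < 2 && needed > 0) {
      warn("fewer than 2 edges: no swap is possible, returning a copy")
      needed <- 0
    }
    adj <- matrix(FALSE, n, n)
    if (m > 0) {
      adj[el] <- TRUE
      if (!directed) adj[el[, 2:1, drop = FALSE]] <- TRUE
    }
    done <- 0L
    attempts <- 0L
    max_attempts <- 200L * max(needed, 1L) + 1000L
    while (done < needed && attempts < max_attempts) {
      attempts <- attempts + 1L
      ij <- sample.int(m, 2L)
      a <- el[ij[1], 1]; b <- el[ij[1], 2]
      c <- el[ij[2], 1]; d <- el[ij[2], 2]
      if (!directed) {
        if (runif(1) < 0.5) { tmp <- a; a <- b; b <- tmp }
        if (runif(1) < 0.5) { tmp <- c; c <- d; d <- tmp }
      }
      if (a == d || c == b) next
      if (adj[a, d] || adj[c, b]) next
      if (a == c && d == b) next  # the two new edges would be parallel
      adj[a, b] <- FALSE; adj[c, d] <- FALSE
      adj[a, d] <- TRUE; adj[c, b] <- TRUE
      if (!directed) {
        adj[b, a] <- FALSE; adj[d, c] <- FALSE
        adj[d, a] <- TRUE; adj[b, c] <- TRUE
      }
      el[ij[1], ] <- c(a, d)
      el[ij[2], ] <- c(c, b)
      done <- done + 1L
    }
    if (done < needed) {
      warn(sprintf("shuffling stalled after %d of %d swaps", done, needed))
    }
    nm <- igraph::V(target)$name
    nlab <- unname(node_labels_of(target))
    if (label_shuffle) {
      nlab <- nlab[sample.int(n)]
      if (m > 0) elab <- elab[sample.int(m)]
    }
    labeled_graph(cbind(nm[el[, 1]], nm[el[, 2]]), nodes = nm,
                  directed = directed,
                  node_labels = stats::setNames(nlab, nm),
                  edge_labels = elab)
  })
}

#' Erdos-Renyi G(n, p) null model
#'
#' Every admissible node pair (ordered for directed graphs, unordered
#' otherwise) carries an edge independently with probability `p`.
#'
#' @param n node count.
#' @param p edge probability.
#' @param directed logical.
#' @param seed integer seed or `NULL`.
#' @return a labeled (unlabeled) graph on `n` nodes.
#' @export
generate_er <- function(n, p, directed = FALSE, seed = NULL) {
  stopifnot(n >= 1, p >= 0, p <= 1)
  with_seed_opt(seed, {
    pairs <- all_pairs(n, directed)
    hit <- runif(nrow(pairs)) < p
    graph_from_int_edges(pairs[hit, , drop = FALSE], n, directed)
  })
}

#' Watts-Strogatz small-world null model
#'
#' A ring lattice on `n` nodes where each node links to its `d` nearest
#' neighbors on each side, after which every lattice edge is independently
#' rewired with probability `beta`: the first endpoint is kept and the other
#' is moved to a uniformly random node that creates no self-loop or
#' duplicate. Undirected.
#'
#' @param n node count; must exceed `2 * d`.
#' @param d lattice half-degree.
#' @param beta rewiring probability.
#' @param seed integer seed or `NULL`.
#' @return an undirected graph with exactly `n * d` edges.
#' @export
generate_ws <- function(n, d, beta, seed = NULL) {
  if (n <= 2 * d) abort("watts_strogatz requires n > 2 * d")
  stopifnot(d >= 1, beta >= 0, beta <= 1)
  with_seed_opt(seed, {
    from <- rep(seq_len(n), d)
    off <- rep(seq_len(d), each = n)
    to <- ((from + off - 1L) %% n) + 1L
    el <- cbind(from, to)
    adj <- matrix(FALSE, n, n)
    adj[el] <- TRUE; adj[el[, 2:1]] <- TRUE
    for (e in seq_len(nrow(el))) {
      if (runif(1) >= beta) next
      u <- el[e, 1]; v <- el[e, 2]
      free <- which(!adj[u, ] & seq_len(n) != u)
      if (length(free) == 0) next
      w <- free[sample.int(length(free), 1L)]
      adj[u, v] <- FALSE; adj[v, u] <- FALSE
      adj[u, w] <- TRUE; adj[w, u] <- TRUE
      el[e, 2] <- w
    }
    graph_from_int_edges(el, n, directed = FALSE)
  })
}

#' Barabasi-Albert preferential-attachment null model
#'
#' Starts from a complete seed graph on `init_nodes` nodes; each of the
#' remaining nodes attaches to `d` distinct existing nodes chosen with
#' probability proportional to their current degree. Undirected.
#'
#' @param n node count (`n >= init_nodes`).
#' @param init_nodes seed-graph size `k >= 2`.
#' @param d edges added per new node (`1 <= d <= init_nodes`).
#' @param seed integer seed or `NULL`.
#' @return an undirected graph with `k(k-1)/2 + (n-k) d` edges.
#' @export
generate_ba <- function(n, init_nodes, d, seed = NULL) {
  k <- init_nodes
  if (!(n >= k && k >= 2)) abort("barabasi_albert requires n >= init_nodes >= 2")
  if (d > k) abort("barabasi_albert requires d <= init_nodes")
  with_seed_opt(seed, {
    el <- all_pairs(k, directed = FALSE)
    deg <- integer(n)
    deg[seq_len(k)] <- k - 1L
    if (n > k) {
      el <- rbind(el, matrix(0L, (n - k) * d, 2))
      row <- nrow(all_pairs(k, FALSE))
      for (v in (k + 1L):n) {
        existing <- seq_len(v - 1L)
        tgt <- sample(existing, d, prob = deg[existing])
        for (w in tgt) {
          row <- row + 1L
          el[row, ] <- c(v, w)
          deg[w] <- deg[w] + 1L
        }
        deg[v] <- d
      }
    }
    graph_from_int_edges(el, n, directed = FALSE)
  })
}

#' Random geometric null model
#'
#' Nodes are placed i.i.d. uniformly in the unit `dim`-cube; two nodes are
#' linked whenever the Euclidean distance between their points is at most
#' `radius`. Undirected.
#'
#' @param n node count.
#' @param dim dimension of the embedding space.
#' @param radius connection threshold.
#' @param seed integer seed or `NULL`.
#' @return an undirected graph.
#' @export
generate_geometric <- function(n, dim, radius, seed = NULL) {
  stopifnot(n >= 1, dim >= 1, radius >= 0)
  with_seed_opt(seed, {
    pts <- matrix(runif(n * dim), n, dim)
    el <- all_pairs(n, directed = FALSE)
    if (nrow(el) > 0) {
      d2 <- rowSums((pts[el[, 1], , drop = FALSE] -
                     pts[el[, 2], , drop = FALSE])^2)
      el <- el[d2 <= radius^2, , drop = FALSE]
    }
    graph_from_int_edges(el, n, directed = FALSE)
  })
}

#' Forest-fire null model
#'
#' Nodes arrive one at a time. Each new node `v` picks `ambassadors`
#' uniformly random existing nodes, links to each, and then "burns" through
#' the network: from every burning node, each out-neighbor is discovered
#' independently with probability `p_forward` and each in-neighbor with
#' probability `r_backward`; `v` links to every discovered node and burning
#' recurses from them. A node burns at most once per arrival. Directed; all
#' links created by `v` are out-links of `v`.
#'
#' @param n node count.
#' @param p_forward forward (out-neighbor) spread probability.
#' @param r_backward backward (in-neighbor) spread probability.
#' @param ambassadors anchors per arriving node.
#' @param seed integer seed or `NULL`.
#' @return a directed graph; with `p_forward = r_backward = 0` and one
#'   ambassador, a tree with `n - 1` edges.
#' @export
generate_ff <- function(n, p_forward, r_backward, ambassadors = 1,
                        seed = NULL) {
  stopifnot(n >= 1, p_forward >= 0, p_forward <= 1,
            r_backward >= 0, r_backward <= 1, ambassadors >= 1)
  with_seed_opt(seed, {
    out_adj <- rep(list(integer()), n)
    in_adj <- rep(list(integer()), n)
    for (v in seq_len(n)[-1]) {
      nexist <- v - 1L
      amb <- if (nexist <= ambassadors) seq_len(nexist)
             else sample.int(nexist, ambassadors)
      burned <- logical(n)
      burned[amb] <- TRUE
      links <- amb
      frontier <- amb
      while (length(frontier) > 0) {
        found <- integer()
        for (x in frontier) {
          outs <- out_adj[[x]]
          outs <- outs[!burned[outs] & runif(length(outs)) < p_forward]
          burned[outs] <- TRUE
          ins <- in_adj[[x]]
          ins <- ins[!burned[ins] & runif(length(ins)) < r_backward]
          burned[ins] <- TRUE
          found <- c(found, outs, ins)
        }
        links <- c(links, found)
        frontier <- found
      }
      out_adj[[v]] <- links
      for (w in links) in_adj[[w]] <- c(in_adj[[w]], v)
    }
    el <- cbind(rep(seq_len(n), lengths(out_adj)), unlist(out_adj))
    graph_from_int_edges(el, n, directed = TRUE)
  })
}

#' Duplication null model
#'
#' Growth by copying: starting from a ring seed on `init_nodes` nodes, each
#' step picks a uniformly random existing node `u`, creates a new node `v`,
#' and links `v` to each neighbor of `u` independently with probability
#' `edge_prob` (never to `u` itself). Undirected.
#'
#' @param n node count (`n >= init_nodes`).
#' @param init_nodes seed-ring size.
#' @param edge_prob duplication probability `p`; `p = 1` copies `u`'s
#'   neighborhood exactly, lower values diverge from it.
#' @param seed integer seed or `NULL`.
#' @return an undirected graph.
#' @export
generate_duplication <- function(n, init_nodes, edge_prob, seed = NULL) {
  k <- init_nodes
  if (!(n >= k && k >= 1)) abort("duplication requires n >= init_nodes >= 1")
  stopifnot(edge_prob >= 0, edge_prob <= 1)
  with_seed_opt(seed, {
    adj <- rep(list(integer()), n)
    if (k == 2) {
      adj[[1]] <- 2L; adj[[2]] <- 1L
    } else if (k >= 3) {
      for (i in seq_len(k)) {
        j <- (i %% k) + 1L
        adj[[i]] <- c(adj[[i]], j)
        adj[[j]] <- c(adj[[j]], i)
      }
    }
    if (n > k) {
      for (v in (k + 1L):n) {
        u <- sample.int(v - 1L, 1L)
        nb <- adj[[u]]
        keep <- nb[runif(length(nb)) < edge_prob]
        adj[[v]] <- keep
        for (w in keep) adj[[w]] <- c(adj[[w]], v)
      }
    }
    el <- cbind(rep(seq_len(n), lengths(adj)), unlist(adj))
    el <- el[el[, 1] < el[, 2], , drop = FALSE]
    graph_from_int_edges(el, n, directed = FALSE)
  })
}

#' Permute a target network's labels onto a generated graph
#'
#' The target's node-label multiset is permuted uniformly onto the generated
#' nodes. Edge labels are permuted likewise when the edge counts coincide;
#' otherwise they are sampled uniformly with replacement from the target's
#' edge-label multiset. Unlabeled targets yield unlabeled replicas.
#'
#' @param graph the generated structure (`|V|` must equal the target's).
#' @param target the network whose labels are transplanted.
#' @param seed integer seed or `NULL` to use the current RNG stream.
#' @return `graph` with labels attached.
#' @export
assign_labels <- function(graph, target, seed = NULL) {
  if (igraph::vcount(graph) != igraph::vcount(target)) {
    abort("graph and target must have the same node count")
  }
  with_seed_opt(seed, {
    nlab <- unname(node_labels_of(target))
    if (any(!is.na(nlab))) {
      graph <- igraph::set_vertex_attr(
        graph, "label", value = nlab[sample.int(length(nlab))])
    }
    elab <- edge_labels_of(target)
    m <- igraph::ecount(graph)
    if (any(!is.na(elab)) && m > 0) {
      newlab <- if (m == length(elab)) {
        elab[sample.int(m)]
      } else {
        elab[sample.int(length(elab), m, replace = TRUE)]
      }
      graph <- igraph::set_edge_attr(graph, "label", value = newlab)
    }
    graph
  })
}

n_pairs <- function(n, directed) if (directed) n * (n - 1) else n * (n - 1) / 2

#' Estimate null-model parameters from a target network
#'
#' Fills every parameter the user did not supply so that the expected edge
#' count of a sample matches the target's `|E|`: the Erdos-Renyi `p` is the
#' target density; the Watts-Strogatz half-degree is `round(|E|/|V|)`; the
#' Barabasi-Albert per-node attachment is `round((|E| - k(k-1)/2)/(|V|-k))`;
#' the geometric radius, forest-fire forward probability and duplication
#' edge probability are calibrated numerically (the calibration uses a fixed
#' internal seed, so the result is a deterministic function of the target).
#'
#' @param model model name (see [model_config()]).
#' @param target the network being tested.
#' @param params named list of user-chosen parameters to keep.
#' @param seed seed to store in the returned config.
#' @return a [model_config()] with all parameters filled.
#' @export
estimate_params <- function(model = MODEL_NAMES, target, params = list(),
                            seed = NULL) {
  model <- match.arg(model)
  n <- igraph::vcount(target)
  m <- igraph::ecount(target)
  directed <- igraph::is_directed(target)
  if (n < 1) abort("target is empty")
  p <- params
  fill <- function(name, value) if (is.null(p[[name]])) p[[name]] <<- value
  if (model == "shuffling") {
    fill("sw_per_edge", 10)
    fill("label_shuffle", FALSE)
  } else if (model == "erdos_renyi") {
    if (n < 2) abort("erdos_renyi needs at least 2 nodes")
    fill("p", min(1, m / n_pairs(n, directed)))
  } else if (model == "watts_strogatz") {
    fill("d", max(1L, round(m / n)))
    if (n <= 2 * p$d) abort("target too small for watts_strogatz (n <= 2d)")
    fill("beta", 0.1)
  } else if (model == "barabasi_albert") {
    fill("init_nodes", min(n, 3L))
    k <- p$init_nodes
    if (n > k) {
      d <- round((m - k * (k - 1) / 2) / (n - k))
      fill("d", min(k, max(1L, d)))
    } else {
      fill("d", 1L)
    }
  } else if (model == "geometric") {
    fill("dim", 2L)
    fill("radius", calibrate_radius(n, p$dim, m))
  } else if (model == "forest_fire") {
    fill("ambassadors", 1L)
    fill("p_forward", calibrate_ff(n, m, p$ambassadors, directed))
    fill("r_backward", p$p_forward / 2)
  } else if (model == "duplication") {
    fill("init_nodes", min(n, 5L))
    fill("edge_prob", calibrate_duplication(n, p$init_nodes, m))
  }
  model_config(model, p, seed = seed)
}

CALIBRATION_SEED <- 104729L

# radius giving E[edges] ~ m: with P(edge) = P(dist <= r), the calibrated r
# is the m / C(n,2) quantile of the pairwise-distance distribution in the
# unit cube, estimated once from a fixed sample of point pairs.
calibrate_radius <- function(n, dim, m) {
  npairs <- n_pairs(n, FALSE)
  if (m >= npairs) return(sqrt(dim))
  if (m == 0) return(0)
  withr::with_seed(CALIBRATION_SEED, {
    a <- matrix(runif(20000 * dim), ncol = dim)
    b <- matrix(runif(20000 * dim), ncol = dim)
    d <- sqrt(rowSums((a - b)^2))
    unname(quantile(d, m / npairs))
  })
}

# bisection on the forward probability, judged by a small Monte-Carlo mean
calibrate_ff <- function(n, m, ambassadors, directed) {
  sample_m <- function(pf) {
    mean(vapply(1:6, function(i) {
      g <- generate_ff(n, pf, pf / 2, ambassadors)
      if (!directed) g <- igraph::as_undirected(g, mode = "collapse")
      igraph::ecount(g)
    }, 0))
  }
  withr::with_seed(CALIBRATION_SEED, {
    lo <- 0; hi <- 0.95
    if (sample_m(lo) >= m) return(0)
    if (sample_m(hi) <= m) return(hi)
    for (i in 1:12) {
      mid <- (lo + hi) / 2
      if (sample_m(mid) < m) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
}

# deterministic mean-field recurrence for the duplication model:
# E[m_{t+1}] = m_t + p * 2 m_t / t  (expected degree of a uniform node)
duplication_expected_edges <- function(n, init_nodes, p) {
  k <- init_nodes
  m <- if (k >= 3) k else if (k == 2) 1 else 0
  t <- k
  while (t < n) {
    m <- m + p * 2 * m / t
    t <- t + 1
  }
  m
}

calibrate_duplication <- function(n, init_nodes, m) {
  if (duplication_expected_edges(n, init_nodes, 1) <= m) return(1)
  lo <- 0; hi <- 1
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (duplication_expected_edges(n, init_nodes, mid) < m) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate one null-model replica of a target network
#'
#' Dispatches on the configuration's model, generates the structure, orients
#' it when the target is directed but the generator is undirected, and
#' transplants the target's labels (the shuffling model carries them
#' natively). All randomness (structure, orientation, labels) is drawn from
#' one stream seeded by `seed`.
#'
#' @param target the network being tested.
#' @param config a [model_config()], typically from [estimate_params()].
#' @param seed integer seed overriding `config$seed`, or `NULL`.
#' @return a labeled graph with `|V(target)|` nodes.
#' @export
generate_null <- function(target, config, seed = NULL) {
  seed <- seed %||% config$seed
  n <- igraph::vcount(target)
  directed <- igraph::is_directed(target)
  p <- config$params
  with_seed_opt(seed, {
    if (config$model == "shuffling") {
      return(generate_shuffled(target, sw_per_edge = p$sw_per_edge %||% 10,
                               label_shuffle = isTRUE(p$label_shuffle)))
    }
    g <- switch(config$model,
      erdos_renyi = generate_er(n, p$p, directed = directed),
      watts_strogatz = generate_ws(n, p$d, p$beta),
      barabasi_albert = generate_ba(n, p$init_nodes, p$d),
      geometric = generate_geometric(n, p$dim, p$radius),
      forest_fire = generate_ff(n, p$p_forward, p$r_backward,
                                p$ambassadors %||% 1),
      duplication = generate_duplication(n, p$init_nodes, p$edge_prob))
    if (config$model == "forest_fire" && !directed) {
      el <- igraph::as_edgelist(igraph::as_undirected(g, mode = "collapse"),
                                names = FALSE)
      g <- graph_from_int_edges(el, n, directed = FALSE)
    }
    if (directed && config$model %in%
        c("watts_strogatz", "barabasi_albert", "geometric", "duplication")) {
      el <- orient_edges(igraph::as_edgelist(g, names = FALSE))
      g <- graph_from_int_edges(el, n, directed = TRUE)
    }
    assign_labels(g, target)
  })
}
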