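#' Compute the variable ordering for a query graph
#'
#' Static, query-topology-only search order in the greatest-constraint-first
#' style: start from a node of maximum degree; at each step take the unplaced
#' node maximizing, lexicographically, (number of already-placed neighbors,
#' number of its unplaced neighbors adjacent to the placed set, degree).
#' Ties break on the node identifier (radix order) so the ordering is
#' deterministic. Each non-root node's parent is its earliest-placed
#' neighbor; a node with no placed neighbor (first node of a connected
#' component) is a root.
#'
#' @param query a labeled graph with at least one node.
#' @return a tibble with columns `node` and `parent` (`NA` for roots), one
#'   row per query node in search order.
#' @export
compute_ordering <- function(query) {
  n <- igraph::vcount(query)
  if (n == 0) abort("query graph has no nodes")
  nm <- igraph::V(query)$name
  adj <- lapply(igraph::as_adj_list(query, mode = "all"),
                function(v) unique(as.integer(v)))
  deg <- lengths(adj)
  rank <- order(order(nm, method = "radix"))  # radix rank, lower wins ties

  placed <- logical(n)
  seq_idx <- integer(n)
  parent <- rep(NA_integer_, n)
  n_placed_nb <- integer(n)  # per node: neighbors already placed
  for (step in seq_len(n)) {
    cand <- which(!placed)
    # second key: unplaced neighbors of the candidate that touch the placed set
    frontier <- map_int(cand, function(v) {
      nb <- adj[[v]]
      sum(!placed[nb] & n_placed_nb[nb] > 0L)
    })
    key <- order(-n_placed_nb[cand], -frontier, -deg[cand], rank[cand])[1]
    v <- cand[key]
    seq_idx[step] <- v
    placed[v] <- TRUE
    for (w in adj[[v]]) {
      n_placed_nb[w] <- n_placed_nb[w] + 1L
      if (is.na(parent[w]) && !placed[w]) parent[w] <- v
    }
  }
  tibble(node = nm[seq_idx],
         parent = ifelse(is.na(parent[seq_idx]), NA_character_,
                         nm[ifelse(is.na(parent[seq_idx]), 1L, parent[seq_idx])]))
}

# Precompute everything the backtracking search needs, in integer ids.
build_search_plan <- function(query, target) {
  if (igraph::is_directed(query) != igraph::is_directed(target)) {
    abort("query and target must have the same directedness")
  }
  directed <- igraph::is_directed(query)
  ord <- compute_ordering(query)
  qnm <- igraph::V(query)$name
  pos_of <- stats::setNames(seq_along(ord$node), ord$node)

  qlab <- unname(node_labels_of(query)[ord$node])
  qdeg <- unname(igraph::degree(query, v = ord$node, mode = "all"))
  parent_pos <- unname(pos_of[ord$parent])

  # back edges: for each position i, query edges joining ord$node[i] to an
  # earlier position j; dir +1 = earlier -> current, -1 = current -> earlier
  el <- igraph::as_edgelist(query, names = TRUE)
  elab <- edge_labels_of(query)
  back <- rep(list(NULL), nrow(ord))
  if (nrow(el) > 0) {
    for (e in seq_len(nrow(el))) {
      a <- pos_of[[el[e, 1]]]; b <- pos_of[[el[e, 2]]]
      i <- max(a, b); j <- min(a, b)
      dir <- if (!directed) 0L else if (a == j) 1L else -1L
      back[[i]] <- rbind(back[[i]], c(j, dir, e))
    }
  }

  tnm <- igraph::V(target)$name
  tord <- order(tnm, method = "radix")  # deterministic candidate order
  tdeg <- igraph::degree(target, mode = "all")
  tlab <- unname(node_labels_of(target))
  tadj_all <- lapply(igraph::as_adj_list(target, mode = "all"),
                     function(v) unique(as.integer(v)))
  tadj_all <- lapply(tadj_all, function(v) v[order(tnm[v], method = "radix")])

  # O(1) edge lookup: environment keyed on "u to v" (canonical if undirected)
  tel <- igraph::as_edgelist(target, names = FALSE)
  tkey <- edge_key(tel[, 1], tel[, 2], directed)
  elab_t <- edge_labels_of(target)
  emap <- new.env(parent = emptyenv(), size = max(1L, nrow(tel)))
  for (e in seq_len(nrow(tel))) assign(tkey[e], elab_t[e], envir = emap)

  list(directed = directed, ord = ord, qnodes = ord$node, qlab = qlab,
       qdeg = qdeg, parent_pos = parent_pos, back = back, elab = elab,
       tnm = tnm, tord = tord, tdeg = tdeg, tlab = tlab, tadj = tadj_all,
       emap = emap)
}

target_edge_label <- function(plan, from, to) {
  key <- edge_key(from, to, plan$directed)
  if (!exists(key, envir = plan$emap, inherits = FALSE)) return(FALSE)
  get(key, envir = plan$emap, inherits = FALSE)
}

candidate_ok <- function(plan, pos, t, assign_vec) {
  if (plan$tdeg[t] < plan$qdeg[pos]) return(FALSE)
  ql <- plan$qlab[pos]
  if (!is.na(ql) && (is.na(plan$tlab[t]) || plan$tlab[t] != ql)) return(FALSE)
  be <- plan$back[[pos]]
  if (!is.null(be)) {
    for (k in seq_len(nrow(be))) {
      other <- assign_vec[be[k, 1]]
      lab <- if (be[k, 2] >= 0L) target_edge_label(plan, other, t)
             else target_edge_label(plan, t, other)
      if (isFALSE(lab)) return(FALSE)
      ql_e <- plan$elab[be[k, 3]]
      if (!is.na(ql_e) && (is.na(lab) || lab != ql_e)) return(FALSE)
    }
  }
  TRUE
}

search_matches <- function(plan, on_match) {
  nq <- length(plan$qnodes)
  nt <- length(plan$tnm)
  if (nq > nt) return(invisible())
  assign_vec <- integer(nq)
  used <- logical(nt)
  recurse <- function(pos) {
    cands <- if (is.na(plan$parent_pos[pos])) plan$tord
             else plan$tadj[[assign_vec[plan$parent_pos[pos]]]]
    for (t in cands) {
      if (used[t]) next
      if (!candidate_ok(plan, pos, t, assign_vec)) next
      assign_vec[pos] <<- t
      if (pos == nq) {
        on_match(assign_vec)
      } else {
        used[t] <<- TRUE
        recurse(pos + 1L)
        used[t] <<- FALSE
      }
    }
  }
  recurse(1L)
  invisible()
}

matches_tibble <- function(rows, query_nodes) {
  if (length(rows) == 0) {
    m <- matrix(character(), ncol = length(query_nodes))
  } else {
    m <- do.call(rbind, rows)
  }
  colnames(m) <- query_nodes
  as_tibble(as.data.frame(m, stringsAsFactors = FALSE, check.names = FALSE))
}

#' Find all exact occurrences of a query in a target network
#'
#' Subgraph (not induced-subgraph) isomorphism: every injective mapping of
#' query nodes to target nodes such that every query edge maps onto a target
#' edge with compatible label (respecting direction in directed graphs) and
#' every query node label is compatible with its image's label. Wildcard
#' (`"?"`/absent) query labels match anything. Automorphic images are counted
#' as distinct matches.
#'
#' @param query a labeled graph; any path constraints must be removed first
#'   (use [match_approximate()] for constrained queries).
#' @param target a labeled graph of the same directedness.
#' @param distinct_node_sets if `TRUE`, collapse matches that use the same
#'   set of target nodes, keeping the first found.
#' @return a tibble with one row per match and one column per query node (in
#'   the query's own node order), holding the mapped target node ids. Rows
#'   appear in deterministic search order.
#' @export
match_exact <- function(query, target, distinct_node_sets = FALSE) {
  if (any(!is.na(path_constraints_of(query)))) {
    abort("query has path constraints; use match_approximate()")
  }
  plan <- build_search_plan(query, target)
  rows <- list()
  search_matches(plan, function(a) rows[[length(rows) + 1L]] <<- plan$tnm[a])
  out <- matches_tibble(rows, plan$qnodes)
  out <- out[, igraph::V(query)$name, drop = FALSE]
  if (distinct_node_sets && nrow(out) > 0) {
    key <- apply(out, 1, function(r) paste(sort(r), collapse = "\r"))
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out
}

#' Count occurrences of a query in a target network
#'
#' Streaming version of [match_exact()]: counts matches without retaining
#' them. Dispatches to the approximate matcher when the query carries path
#' constraints.
#'
#' @inheritParams match_exact
#' @return a non-negative integer.
#' @export
count_occurrences <- function(query, target) {
  if (any(!is.na(path_constraints_of(query)))) {
    return(nrow(match_approximate(query, target)))
  }
  plan <- build_search_plan(query, target)
  n <- 0L
  search_matches(plan, function(a) n <<- n + 1L)
  n
}

#' Brute-force subgraph matching (test oracle)
#'
#' Enumerates every injective map from query nodes to target nodes and keeps
#' those satisfying the match invariants directly (edge presence, label
#' compatibility and — when the query carries path constraints — shortest
#' path length checks). Exponential; intended as ground truth on small
#' instances.
#'
#' @inheritParams match_exact
#' @return a tibble shaped like [match_exact()]'s, rows sorted by mapped
#'   node ids.
#' @export
brute_force_match <- function(query, target) {
  if (igraph::is_directed(query) != igraph::is_directed(target)) {
    abort("query and target must have the same directedness")
  }
  directed <- igraph::is_directed(query)
  qnm <- igraph::V(query)$name
  tnm <- igraph::V(target)$name
  nq <- length(qnm); nt <- length(tnm)
  if (nq > 12 || nt > 14) abort("brute_force_match is for small instances")
  if (nq > nt) return(matches_tibble(list(), qnm))

  combos <- as.matrix(expand.grid(rep(list(seq_len(nt)), nq)))
  if (nq > 1) {
    inj <- !apply(combos, 1, anyDuplicated)
    combos <- combos[inj, , drop = FALSE]
  }
  ok <- rep(TRUE, nrow(combos))

  qlab <- unname(node_labels_of(query))
  tlab <- unname(node_labels_of(target))
  for (i in seq_len(nq)) {
    if (!is.na(qlab[i])) {
      tl <- tlab[combos[, i]]
      ok <- ok & !is.na(tl) & tl == qlab[i]
    }
  }

  A <- matrix(FALSE, nt, nt)
  L <- matrix(NA_character_, nt, nt)
  tel <- igraph::as_edgelist(target, names = FALSE)
  telab <- edge_labels_of(target)
  if (nrow(tel) > 0) {
    A[tel] <- TRUE
    L[tel] <- telab
    if (!directed) {
      A[tel[, 2:1, drop = FALSE]] <- TRUE
      L[tel[, 2:1, drop = FALSE]] <- telab
    }
  }

  cons <- path_constraints_of(query)
  qel <- igraph::as_edgelist(query, names = TRUE)
  qelab <- edge_labels_of(query)
  qpos <- stats::setNames(seq_len(nq), qnm)
  D <- NULL
  for (e in seq_along(qelab)) {
    a <- qpos[[qel[e, 1]]]; b <- qpos[[qel[e, 2]]]
    idx <- cbind(combos[, a], combos[, b])
    if (!is.na(cons[e])) {
      if (is.null(D)) {
        D <- igraph::distances(target, mode = if (directed) "out" else "all")
      }
      pc <- parse_path_expression(cons[e])
      d <- D[idx]
      ok <- ok & is.finite(d) & constraint_holds(pc, d)
    } else {
      ok <- ok & A[idx]
      if (!is.na(qelab[e])) {
        tl <- L[idx]
        ok <- ok & !is.na(tl) & tl == qelab[e]
      }
    }
  }

  combos <- combos[ok, , drop = FALSE]
  rows <- lapply(seq_len(nrow(combos)), function(r) tnm[combos[r, ]])
  out <- matches_tibble(rows, qnm)
  if (nrow(out) > 0) out <- arrange(out, across(everything()))
  out
}
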