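#' Parse a path-constraint expression
#'
#' A path constraint annotates a query edge with a bound on the length of the
#' path joining the mapped endpoints in the target. The grammar is `a op b`
#' where one of `a`, `b` is the wildcard `"?"` (the path length) and the
#' other a positive integer, with `op` one of `<`, `<=`, `>=`, `>`, `=`.
#' `"?<=2"` means "a path of length at most 2"; `"2<=?"` is normalized to the
#' same constraint read from the other side (length at least 2).
#'
#' @param text expression string; internal whitespace is ignored.
#' @return an object of class `path_constraint`: a list with `op` (normalized
#'   so the path length is on the left), `bound` and `raw`.
#' @export
parse_path_expression <- function(text) {
  raw <- text
  s <- gsub("\\s+", "", as.character(text))
  m <- regmatches(s, regexec("^(\\?|[0-9]+)(<=|>=|<|>|=)(\\?|[0-9]+)$", s))[[1]]
  if (length(m) != 4) abort(sprintf("cannot parse path expression: %s", raw))
  lhs <- m[2]; op <- m[3]; rhs <- m[4]
  if ((lhs == "?") == (rhs == "?")) {
    abort(sprintf("path expression must have '?' on exactly one side: %s", raw))
  }
  if (lhs != "?") {  # m op ?  ==  ? flipped-op m
    op <- c("<" = ">", "<=" = ">=", ">" = "<", ">=" = "<=", "=" = "=")[[op]]
    bound <- as.integer(lhs)
  } else {
    bound <- as.integer(rhs)
  }
  if (is.na(bound) || bound < 1) {
    abort(sprintf("path bound must be a positive integer: %s", raw))
  }
  structure(list(op = op, bound = bound, raw = as.character(raw)),
            class = "path_constraint")
}

#' @export
format.path_constraint <- function(x, ...) sprintf("?%s%d", x$op, x$bound)

#' @export
print.path_constraint <- function(x, ...) {
  cat("<path constraint: length", x$op, x$bound, ">\n")
  invisible(x)
}

is_path_expression <- function(x) {
  !is.na(x) & grepl("^\\s*(\\?|[0-9]+)\\s*(<=|>=|<|>|=)\\s*(\\?|[0-9]+)\\s*$", x)
}

path_constraints_of <- function(g) {
  cons <- igraph::edge_attr(g, "constraint")
  if (is.null(cons)) cons <- rep(NA_character_, igraph::ecount(g))
  as.character(cons)
}

constraint_holds <- function(pc, d) {
  switch(pc$op,
         "<"  = d < pc$bound,
         "<=" = d <= pc$bound,
         ">"  = d > pc$bound,
         ">=" = d >= pc$bound,
         "="  = d == pc$bound,
         abort(sprintf("unknown operator: %s", pc$op)))
}

#' Attach a path constraint to a query edge
#'
#' Marks the edge `(from, to)` as an approximate path rather than a direct
#' link. A constrained edge has no ordinary edge label.
#'
#' @param query a labeled graph.
#' @param from,to endpoint node names of an existing query edge.
#' @param expression constraint expression, e.g. `"?<=2"` (see
#'   [parse_path_expression()]; validated here).
#' @return the query graph with the constraint set.
#' @export
set_path_constraint <- function(query, from, to, expression) {
  parse_path_expression(expression)  # validate
  eid <- igraph::get_edge_ids(query, c(from, to))
  if (eid == 0) abort(sprintf("no query edge %s -> %s", from, to))
  cons <- path_constraints_of(query)
  cons[eid] <- gsub("\\s+", "", expression)
  lab <- edge_labels_of(query)
  lab[eid] <- NA_character_
  query <- igraph::set_edge_attr(query, "label", value = lab)
  igraph::set_edge_attr(query, "constraint", value = cons)
}

#' Read a query graph from SIF plus attribute sidecars
#'
#' Like [read_network()], but `.EA` values that parse as path-constraint
#' expressions (e.g. `?<=2`) become path constraints on the corresponding
#' edge instead of ordinary edge labels.
#'
#' @inheritParams read_network
#' @return a query graph (labeled graph with a `constraint` edge attribute).
#' @export
read_query <- function(sif, node_attrs = NULL, edge_attrs = NULL,
                       directed = FALSE) {
  g <- read_network(sif, node_attrs = node_attrs, edge_attrs = NULL,
                    directed = directed)
  if (!is.null(edge_attrs)) {
    ea <- read_attributes(edge_attrs, "edge")
    for (i in seq_len(nrow(ea))) {
      eid <- igraph::get_edge_ids(g, c(ea$source[i], ea$target[i]),
                                  error = FALSE)
      if (eid == 0) next
      if (is_path_expression(ea$value[i])) {
        el <- igraph::as_edgelist(g)
        g <- set_path_constraint(g, el[eid, 1], el[eid, 2], ea$value[i])
      } else {
        lab <- edge_labels_of(g)
        lab[eid] <- ea$value[i]
        g <- igraph::set_edge_attr(g, "label", value = normalize_label(lab))
      }
    }
  }
  g
}

#' Split a query into its exact part and its path constraints
#'
#' @param query a query graph.
#' @return a list with `exact` (the query minus constrained edges, nodes
#'   retained) and `constraints`, a tibble with one row per removed edge
#'   (`from`, `to`, `op`, `bound`, `raw`).
#' @export
decompose_query <- function(query) {
  cons <- path_constraints_of(query)
  idx <- which(!is.na(cons))
  parsed <- lapply(cons[idx], parse_path_expression)
  el <- igraph::as_edgelist(query, names = TRUE)
  spec <- tibble(
    from = el[idx, 1], to = el[idx, 2],
    op = map_chr(parsed, "op"),
    bound = map_int(parsed, "bound"),
    raw = cons[idx]
  )
  exact <- if (length(idx) > 0) {
    igraph::delete_edges(query, idx)
  } else {
    query
  }
  exact <- drop_constraint_attr(exact)
  list(exact = exact, constraints = spec)
}

# delete_edge_attr errors when the attribute is absent; tolerate that
drop_constraint_attr <- function(g) {
  if ("constraint" %in% igraph::edge_attr_names(g)) {
    g <- igraph::delete_edge_attr(g, "constraint")
  }
  g
}

#' Shortest path length between two target nodes
#'
#' Breadth-first shortest-path distance, following edge direction in directed
#' graphs; `Inf` when unreachable.
#'
#' @param target a labeled graph.
#' @param u,v node names.
#' @return a non-negative number or `Inf`.
#' @export
path_length <- function(target, u, v) {
  mode <- if (igraph::is_directed(target)) "out" else "all"
  as.vector(igraph::distances(target, v = u, to = v, mode = mode))
}

#' Does a pair of target nodes satisfy a path constraint?
#'
#' The shortest-path distance `d` from `u` to `v` must be finite (the
#' endpoints reachable) and satisfy `d op bound`. Requiring reachability also
#' for lower-bound operators is a deliberate semantic choice.
#'
#' @param constraint a `path_constraint` or expression string.
#' @param target a labeled graph.
#' @param u,v distinct node names.
#' @return logical.
#' @export
satisfies <- function(constraint, target, u, v) {
  if (!inherits(constraint, "path_constraint")) {
    constraint <- parse_path_expression(constraint)
  }
  d <- path_length(target, u, v)
  is.finite(d) && constraint_holds(constraint, d)
}

#' Find occurrences of an approximate query
#'
#' Matches the exactly-specified part of the query with [match_exact()]
#' semantics, then keeps the mappings whose constrained edges are realized by
#' target paths of admissible length (shortest-path semantics; path interiors
#' are not required to avoid other mapped nodes). On a query without path
#' constraints this reduces exactly to [match_exact()].
#'
#' @param query a query graph (may contain wildcard labels and path
#'   constraints).
#' @param target a labeled graph of the same directedness.
#' @return a tibble shaped like [match_exact()]'s.
#' @export
match_approximate <- function(query, target) {
  parts <- decompose_query(query)
  out <- match_exact(parts$exact, target)
  if (nrow(parts$constraints) == 0 || nrow(out) == 0) return(out)
  mode <- if (igraph::is_directed(target)) "out" else "all"
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(parts$constraints))) {
    pc <- parse_path_expression(parts$constraints$raw[i])
    us <- out[[parts$constraints$from[i]]]
    vs <- out[[parts$constraints$to[i]]]
    D <- igraph::distances(target, v = unique(us), to = unique(vs), mode = mode)
    d <- D[cbind(match(us, rownames(D)), match(vs, colnames(D)))]
    keep <- keep & is.finite(d) & constraint_holds(pc, d)
  }
  out[keep, , drop = FALSE]
}
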