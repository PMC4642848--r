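#' Construct a labeled graph
#'
#' Builds the simple labeled graph used throughout the package: an igraph
#' object whose vertices and edges may carry a `label` attribute. A label of
#' `NA` means "unlabeled"; in a query an unlabeled element is a wildcard and
#' matches anything, in a target it matches only wildcard query elements. The
#' single character `"?"` is the on-disk spelling of the wildcard and is
#' normalized to `NA` on construction.
#'
#' Self-loops and parallel edges are not representable: they are dropped with
#' a warning, matching the simple-graph model shared by all seven null models.
#'
#' @param edges two-column character matrix (or data frame) of endpoints; may
#'   have zero rows.
#' @param nodes character vector of node identifiers; defaults to the nodes
#'   appearing in `edges`. Identifiers are case-sensitive opaque strings.
#' @param directed logical.
#' @param node_labels named character vector (names = node ids) or `NULL`.
#' @param edge_labels character vector parallel to the rows of `edges`.
#' @return an igraph object with `name`/`label` vertex attributes and a
#'   `label` edge attribute.
#' @export
labeled_graph <- function(edges = NULL, nodes = NULL, directed = FALSE,
                          node_labels = NULL, edge_labels = NULL) {
  if (is.null(edges)) edges <- matrix(character(), ncol = 2)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2 && nrow(edges) > 0) {
    abort("`edges` must have two columns")
  }
  storage.mode(edges) <- "character"
  if (is.null(edge_labels)) edge_labels <- rep(NA_character_, nrow(edges))
  edge_labels <- normalize_label(as.character(edge_labels))
  nodes <- unique(c(as.character(nodes %||% character()), as.vector(t(edges))))

  keep <- rep(TRUE, nrow(edges))
  if (nrow(edges) > 0) {
    loops <- edges[, 1] == edges[, 2]
    if (any(loops)) {
      warn(sprintf("dropping %d self-loop(s)", sum(loops)))
      keep <- keep & !loops
    }
    key <- edge_key(edges[, 1], edges[, 2], directed)
    dup <- duplicated(key) & keep
    if (any(dup)) {
      warn(sprintf("dropping %d duplicate edge(s), keeping first occurrence",
                   sum(dup)))
      keep <- keep & !dup
    }
  }
  edges <- edges[keep, , drop = FALSE]
  edge_labels <- edge_labels[keep]

  vdf <- data.frame(name = nodes, stringsAsFactors = FALSE)
  vdf$label <- if (is.null(node_labels)) {
    rep(NA_character_, length(nodes))
  } else {
    normalize_label(unname(node_labels[nodes]))
  }
  edf <- data.frame(from = edges[, 1], to = edges[, 2],
                    label = edge_labels, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = directed, vertices = vdf)
}

# "?" and "" are spellings of "no label"
normalize_label <- function(x) {
  x[!is.na(x) & (x == "?" | x == "")] <- NA_character_
  x
}

# canonical string key of an edge, order-free for undirected graphs
edge_key <- function(from, to, directed) {
  if (directed) {
    paste(from, to, sep = "\r")
  } else {
    paste(pmin(from, to), pmax(from, to), sep = "\r")
  }
}

node_labels_of <- function(g) {
  lab <- igraph::vertex_attr(g, "label")
  if (is.null(lab)) lab <- rep(NA_character_, igraph::vcount(g))
  stats::setNames(as.character(lab), igraph::V(g)$name)
}

edge_labels_of <- function(g) {
  lab <- igraph::edge_attr(g, "label")
  if (is.null(lab)) lab <- rep(NA_character_, igraph::ecount(g))
  as.character(lab)
}

#' Are a query label and a target label compatible?
#'
#' A query label that is absent (`NA`) or the wildcard `"?"` matches any
#' target label, including an absent one. Otherwise the target label must be
#' present and string-equal (exact, case-sensitive).
#'
#' @param query_label,target_label character scalars (or vectors recycled
#'   together); `NA` means absent.
#' @return logical.
#' @export
labels_compatible <- function(query_label, target_label) {
  q <- normalize_label(as.character(query_label))
  t <- normalize_label(as.character(target_label))
  is.na(q) | (!is.na(t) & q == t)
}

#' Structural equality of labeled graphs
#'
#' Two labeled graphs are equal when they have the same directedness, node
#' set, node labels, and edge set with edge labels and path constraints —
#' regardless of node or edge storage order. This is the identity preserved
#' by a SIF/.NA/.EA round trip.
#'
#' @param g1,g2 labeled graphs.
#' @return logical.
#' @export
graph_equal <- function(g1, g2) {
  if (igraph::is_directed(g1) != igraph::is_directed(g2)) return(FALSE)
  n1 <- sort(igraph::V(g1)$name); n2 <- sort(igraph::V(g2)$name)
  if (!identical(n1, n2)) return(FALSE)
  l1 <- node_labels_of(g1)[n1]; l2 <- node_labels_of(g2)[n1]
  if (!identical(unname(l1), unname(l2))) return(FALSE)
  edge_table <- function(g) {
    el <- igraph::as_edgelist(g, names = TRUE)
    key <- edge_key(el[, 1], el[, 2], igraph::is_directed(g))
    o <- order(key, method = "radix")
    paste(key[o], edge_labels_of(g)[o], path_constraints_of(g)[o],
          sep = "\x01")
  }
  identical(edge_table(g1), edge_table(g2))
}

read_text_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  sub("\r$", "", lines)
}

#' Read a SIF (simple interaction format) file
#'
#' Each non-blank line is either `source relation target [target2 ...]`
#' (whitespace-delimited; one edge per source/target pair, labeled with the
#' relation) or a bare node name adding an isolated node. The relation `"?"`
#' yields an unlabeled edge.
#'
#' @param path file path.
#' @param directed logical; SIF itself carries no directedness flag.
#' @return a labeled graph.
#' @export
read_sif <- function(path, directed = FALSE) {
  lines <- read_text_lines(path)
  nodes <- character()
  from <- character(); to <- character(); rel <- character()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    tok <- strsplit(line, "\\s+")[[1]]
    if (length(tok) == 1) {
      nodes <- c(nodes, tok)
    } else if (length(tok) == 2) {
      abort(sprintf("%s:%d: malformed SIF line (2 tokens): %s", path, i, line))
    } else {
      tgt <- tok[3:length(tok)]
      from <- c(from, rep(tok[1], length(tgt)))
      to <- c(to, tgt)
      rel <- c(rel, rep(tok[2], length(tgt)))
      nodes <- c(nodes, tok[1], tgt)
    }
  }
  labeled_graph(cbind(from, to), nodes = unique(nodes), directed = directed,
                edge_labels = rel)
}

#' Write a graph to SIF
#'
#' Unlabeled edges are rendered with the relation `"?"`; isolated nodes are
#' written as bare-node lines. `read_sif(write_sif(g))` reconstructs `g` up
#' to node and edge order.
#'
#' @param graph a labeled graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(graph, path) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  rel <- edge_labels_of(graph)
  rel[is.na(rel)] <- "?"
  lines <- if (nrow(el) > 0) paste(el[, 1], rel, el[, 2]) else character()
  iso <- setdiff(igraph::V(graph)$name, as.vector(el))
  writeLines(c(lines, iso), path, useBytes = TRUE)
  invisible(path)
}

#' Read a Cytoscape node- or edge-attribute file
#'
#' Dialect: an optional header line (any line without `"="`, conventionally
#' the attribute name), then `identifier = value` lines. Edge identifiers use
#' the Cytoscape form `source (relation) target`. A duplicated identifier
#' keeps the last value, with a warning.
#'
#' @param path file path.
#' @param kind `"node"` or `"edge"`.
#' @return a tibble with columns `id` and `value`; for `kind = "edge"` also
#'   `source`, `relation`, `target` parsed from the identifier.
#' @export
read_attributes <- function(path, kind = c("node", "edge")) {
  kind <- match.arg(kind)
  lines <- read_text_lines(path)
  ids <- character(); vals <- character()
  first_content <- TRUE
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") next
    if (!grepl("=", line, fixed = TRUE)) {
      if (first_content) { first_content <- FALSE; next }  # header
      abort(sprintf("%s:%d: expected `identifier = value`: %s", path, i, line))
    }
    first_content <- FALSE
    eq <- regexpr("=", line, fixed = TRUE)
    ids <- c(ids, trimws(substr(line, 1, eq - 1)))
    vals <- c(vals, trimws(substr(line, eq + 1, nchar(line))))
  }
  if (anyDuplicated(ids)) {
    warn(sprintf("%s: duplicate identifiers, last value wins", path))
    keep <- !duplicated(ids, fromLast = TRUE)
    ids <- ids[keep]; vals <- vals[keep]
  }
  out <- tibble(id = ids, value = vals)
  if (kind == "edge" && nrow(out) > 0) {
    m <- regmatches(out$id, regexec("^(\\S+)\\s+\\((.*)\\)\\s+(\\S+)$", out$id))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad)) {
      abort(sprintf("%s: malformed edge identifier: %s", path,
                    out$id[which(bad)[1]]))
    }
    out$source <- map_chr(m, 2)
    out$relation <- map_chr(m, 3)
    out$target <- map_chr(m, 4)
  }
  attr(out, "kind") <- kind
  out
}

#' Write an attribute table
#'
#' @param table a tibble with `id` and `value` columns (as returned by
#'   [read_attributes()]).
#' @param path output file path.
#' @param header attribute-name header line.
#' @return `path`, invisibly.
#' @export
write_attributes <- function(table, path, header = "Label") {
  body <- if (nrow(table) > 0) paste(table$id, "=", table$value) else character()
  lines <- c(header, body)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

sif_edge_id <- function(graph) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  rel <- edge_labels_of(graph)
  rel[is.na(rel)] <- "?"
  sprintf("%s (%s) %s", el[, 1], rel, el[, 2])
}

#' Read a network from SIF plus optional attribute sidecars
#'
#' Node labels come from the `.NA` file; edge labels default to the SIF
#' relation and are overridden by the `.EA` file where present.
#'
#' @param sif path to the SIF file.
#' @param node_attrs,edge_attrs paths to `.NA` / `.EA` files, or `NULL`.
#' @param directed logical.
#' @return a labeled graph.
#' @export
read_network <- function(sif, node_attrs = NULL, edge_attrs = NULL,
                         directed = FALSE) {
  g <- read_sif(sif, directed = directed)
  if (!is.null(node_attrs)) {
    na <- read_attributes(node_attrs, "node")
    lab <- node_labels_of(g)
    hit <- na$id %in% names(lab)
    lab[na$id[hit]] <- na$value[hit]
    g <- igraph::set_vertex_attr(g, "label", value = normalize_label(unname(lab)))
  }
  if (!is.null(edge_attrs)) {
    ea <- read_attributes(edge_attrs, "edge")
    if (nrow(ea) > 0) {
      eid <- igraph::get_edge_ids(
        g, rbind(ea$source, ea$target), directed = directed, error = FALSE)
      ok <- eid > 0
      lab <- edge_labels_of(g)
      lab[eid[ok]] <- ea$value[ok]
      g <- igraph::set_edge_attr(g, "label", value = normalize_label(lab))
    }
  }
  g
}

#' Write a network to SIF plus optional attribute sidecars
#'
#' The `.NA` file lists labeled nodes; the `.EA` file lists labeled edges,
#' including path-constraint expressions on query graphs, so that a query
#' round-trips through `write_network()` / [read_query()].
#'
#' @param graph a labeled graph (or query graph).
#' @param sif output SIF path.
#' @param node_attrs,edge_attrs output attribute paths, or `NULL` to skip.
#' @return `sif`, invisibly.
#' @export
write_network <- function(graph, sif, node_attrs = NULL, edge_attrs = NULL) {
  cons <- path_constraints_of(graph)
  write_sif(graph, sif)
  if (!is.null(node_attrs)) {
    lab <- node_labels_of(graph)
    keep <- !is.na(lab)
    write_attributes(tibble(id = names(lab)[keep], value = unname(lab[keep])),
                     node_attrs)
  }
  if (!is.null(edge_attrs)) {
    lab <- edge_labels_of(graph)
    val <- ifelse(is.na(cons), lab, cons)
    keep <- !is.na(val)
    write_attributes(tibble(id = sif_edge_id(graph)[keep], value = val[keep]),
                     edge_attrs)
  }
  invisible(sif)
}
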