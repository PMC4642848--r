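#' Built-in motif library
#'
#' The canonical small regulatory topologies shipped with the package as SIF
#' resources: feed-forward loop, diamond, single-input module (3 outputs),
#' dense overlapping regulon (complete 2x3 bipartite block), bifan (complete
#' 2x2 bipartite block), cascade, 3-cycle and 4-cycle. All entries are
#' directed and wildcard-labeled; use [motif_graph()] with
#' `directed = FALSE` to query undirected targets. The library is
#' data-driven: dropping another `.sif` file into the package's
#' `extdata/motifs` directory adds an entry without code changes.
#'
#' @return a tibble with columns `name`, `n_nodes`, `n_edges`, `directed`
#'   and a `graph` list-column of query graphs.
#' @export
motif_library <- function() {
  dir <- system.file("extdata", "motifs", package = "netmotif")
  files <- sort(list.files(dir, pattern = "\\.sif$", full.names = TRUE))
  graphs <- map(files, read_sif, directed = TRUE)
  tibble(
    name = sub("\\.sif$", "", basename(files)),
    n_nodes = map_int(graphs, igraph::vcount),
    n_edges = map_int(graphs, igraph::ecount),
    directed = TRUE,
    graph = graphs
  )
}

#' Fetch one library motif
#'
#' @param name motif name (see [motif_library()]).
#' @param directed `TRUE` for the native directed form; `FALSE` collapses
#'   arc pairs to undirected edges so the motif can query undirected
#'   networks.
#' @return a query graph.
#' @export
motif_graph <- function(name, directed = TRUE) {
  lib <- motif_library()
  hit <- match(name, lib$name)
  if (is.na(hit)) {
    abort(sprintf("unknown motif '%s'; available: %s", name,
                  paste(lib$name, collapse = ", ")))
  }
  g <- lib$graph[[hit]]
  if (!directed) {
    el <- igraph::as_edgelist(igraph::as_undirected(g, mode = "collapse"),
                              names = TRUE)
    g <- labeled_graph(el, nodes = igraph::V(g)$name, directed = FALSE)
  }
  g
}

#' Synthetic labeled benchmark network
#'
#' A seeded uniform random graph with exactly `density` edges and node
#' labels drawn uniformly from `n_labels` synthetic label strings
#' (`"L1" ... "Lk"`); `n_labels = 0` leaves the network unlabeled. This is
#' the package's stand-in for randomly labeled benchmark networks.
#'
#' @param n node count.
#' @param density exact number of edges (0 up to the number of node pairs).
#' @param n_labels size of the synthetic label alphabet.
#' @param directed logical.
#' @param seed integer seed or `NULL`.
#' @return a labeled graph with nodes `"n1" ... "n<n>"`.
#' @export
synth_network <- function(n, density, n_labels = 0, directed = FALSE,
                          seed = NULL) {
  stopifnot(n >= 1, density >= 0)
  npairs <- n_pairs(n, directed)
  if (density > npairs) {
    abort(sprintf("density %d exceeds the %d possible edges", density, npairs))
  }
  with_seed_opt(seed, {
    pairs <- all_pairs(n, directed)
    el <- pairs[sample.int(nrow(pairs), density), , drop = FALSE]
    nm <- paste0("n", seq_len(n))
    labels <- if (n_labels > 0) {
      stats::setNames(paste0("L", sample.int(n_labels, n, replace = TRUE)), nm)
    } else {
      NULL
    }
    labeled_graph(cbind(nm[el[, 1]], nm[el[, 2]]), nodes = nm,
                  directed = directed, node_labels = labels)
  })
}

#' Plant motif copies into a host network
#'
#' Embeds `copies` node-disjoint copies of a motif into the host by choosing
#' random disjoint node sets and adding the motif's edges among them (edges
#' already present are reused). The returned placements are ground truth:
#' the matcher must find at least these embeddings.
#'
#' @param host a labeled graph with at least `copies * |V(motif)|` nodes.
#' @param motif a query graph of the same directedness as the host.
#' @param copies number of disjoint embeddings.
#' @param seed integer seed or `NULL`.
#' @return a list with `graph` (the host plus planted edges) and
#'   `placements`, a list of named character vectors mapping motif nodes to
#'   host nodes.
#' @export
plant_motif <- function(host, motif, copies = 1, seed = NULL) {
  if (igraph::is_directed(host) != igraph::is_directed(motif)) {
    abort("host and motif must have the same directedness")
  }
  k <- igraph::vcount(motif)
  need <- copies * k
  if (need > igraph::vcount(host)) {
    abort(sprintf("host has %d nodes; %d disjoint copies of a %d-node motif need %d",
                  igraph::vcount(host), copies, k, need))
  }
  if (copies == 0) return(list(graph = host, placements = list()))
  with_seed_opt(seed, {
    hosts <- sample(igraph::V(host)$name, need)
    mel <- igraph::as_edgelist(motif, names = TRUE)
    mnodes <- igraph::V(motif)$name
    placements <- vector("list", copies)
    g <- host
    for (cp in seq_len(copies)) {
      image <- stats::setNames(hosts[((cp - 1) * k + 1):(cp * k)], mnodes)
      placements[[cp]] <- image
      for (e in seq_len(nrow(mel))) {
        u <- image[[mel[e, 1]]]; v <- image[[mel[e, 2]]]
        if (igraph::get_edge_ids(g, c(u, v), error = FALSE) == 0) {
          g <- igraph::add_edges(g, c(u, v), label = NA_character_)
        }
      }
    }
    list(graph = g, placements = placements)
  })
}
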