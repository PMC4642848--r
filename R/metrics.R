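#' Average node degree
#'
#' Mean total degree: `2|E|/|V|` for undirected graphs. For directed graphs
#' the default mode `"total"` also gives `2|E|/|V|`; `mode = "out"` gives the
#' per-arc mean `|E|/|V|`.
#'
#' @param graph a labeled graph with at least one node.
#' @param mode degree mode passed to [igraph::degree()] for directed graphs.
#' @return a number.
#' @export
average_degree <- function(graph, mode = c("total", "out", "in", "all")) {
  mode <- match.arg(mode)
  if (igraph::vcount(graph) == 0) abort("graph has no nodes")
  mean(igraph::degree(graph, mode = if (mode == "total") "all" else mode))
}

#' Average local clustering coefficient
#'
#' Mean over nodes of the local clustering coefficient (triangles among a
#' node's neighbors over possible neighbor pairs), with nodes of degree
#' below 2 contributing 0. Directed graphs are evaluated on the underlying
#' undirected graph.
#'
#' @param graph a labeled graph with at least one node.
#' @return a number in `[0, 1]`.
#' @export
average_clustering <- function(graph) {
  if (igraph::vcount(graph) == 0) abort("graph has no nodes")
  g <- if (igraph::is_directed(graph)) {
    igraph::as_undirected(graph, mode = "collapse")
  } else {
    graph
  }
  mean(igraph::transitivity(g, type = "local", isolates = "zero"))
}

#' Degree assortativity
#'
#' Pearson correlation between the (total) degrees of edge endpoints.
#' Undirected edges are counted in both orientations, the standard
#' convention, so the correlation is symmetric. Undefined (`NA`) when either
#' endpoint-degree sequence is constant or the graph has no edges.
#'
#' @param graph a labeled graph.
#' @return a number in `[-1, 1]`, or `NA` when undefined.
#' @export
degree_assortativity <- function(graph) {
  el <- igraph::as_edgelist(graph, names = FALSE)
  if (nrow(el) == 0) return(NA_real_)
  deg <- igraph::degree(graph, mode = "all")
  x <- deg[el[, 1]]; y <- deg[el[, 2]]
  if (!igraph::is_directed(graph)) {
    tmp <- x
    x <- c(x, y); y <- c(y, tmp)
  }
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y)
}

#' Summary metrics of a network
#'
#' The three metrics used to judge which null model resembles a target:
#' average degree, average clustering coefficient and degree assortativity.
#'
#' @param graph a labeled graph.
#' @param graph_id identifier put in the `graph_id` column.
#' @return a one-row tibble: `graph_id`, `n_nodes`, `n_edges`, `avg_degree`,
#'   `avg_clustering`, `assortativity`.
#' @export
network_metrics <- function(graph, graph_id = "graph") {
  tibble(graph_id = graph_id,
         n_nodes = igraph::vcount(graph),
         n_edges = igraph::ecount(graph),
         avg_degree = average_degree(graph),
         avg_clustering = average_clustering(graph),
         assortativity = degree_assortativity(graph))
}

#' Compare a target's metrics with one sample from each null model
#'
#' Draws one replica per model (parameters estimated from the target via
#' [estimate_params()]), computes the summary metrics for the target and
#' each replica, and ranks the models by Euclidean distance to the target's
#' metric vector. Each metric is normalized by the target's absolute value
#' where nonzero; an undefined assortativity is excluded from the distance.
#' Values close to the target's suggest a null model that preserves the
#' network's character.
#'
#' @param target a labeled graph.
#' @param models character vector of model names to sample.
#' @param seed integer base seed; model `i` uses `seed + i`.
#' @return a tibble with the target row first (rank `NA`), then one row per
#'   model sorted by `distance`.
#' @export
model_sample_report <- function(target, models = MODEL_NAMES, seed = 1) {
  rows <- list(network_metrics(target, "target"))
  for (i in seq_along(models)) {
    config <- estimate_params(models[i], target)
    replica <- generate_null(target, config, seed = as.integer(seed) + i)
    rows[[i + 1]] <- network_metrics(replica, models[i])
  }
  out <- bind_rows(rows)
  ref <- unlist(out[1, c("avg_degree", "avg_clustering", "assortativity")])
  scale <- ifelse(is.na(ref) | abs(ref) == 0, 1, abs(ref))
  dist_to_target <- function(row) {
    d <- (unlist(row) - ref) / scale
    d <- d[!is.na(d)]
    if (length(d) == 0) return(NA_real_)
    sqrt(sum(d^2))
  }
  out$distance <- vapply(seq_len(nrow(out)), function(i) {
    dist_to_target(out[i, c("avg_degree", "avg_clustering", "assortativity")])
  }, 0)
  out$distance[1] <- NA_real_
  models_part <- out[-1, ]
  models_part <- models_part[order(models_part$distance), ]
  models_part$rank <- seq_len(nrow(models_part))
  out <- bind_rows(mutate(out[1, ], rank = NA_integer_), models_part)
  out
}

#' Plot a model-sample metrics report
#'
#' Dot plot of each model's metrics against the target's (dashed lines).
#'
#' @param report output of [model_sample_report()].
#' @return a ggplot object.
#' @export
plot_model_report <- function(report) {
  long <- tidyr_pivot_metrics(report)
  refs <- long[long$graph_id == "target", ]
  ggplot2::ggplot(long[long$graph_id != "target", ],
                  ggplot2::aes(x = .data$graph_id, y = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(data = refs,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed", color = "red") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Null-model samples vs. target (dashed)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

# minimal long-format reshape (avoids a tidyr dependency for one call)
tidyr_pivot_metrics <- function(report) {
  metrics <- c("avg_degree", "avg_clustering", "assortativity")
  bind_rows(lapply(metrics, function(m) {
    tibble(graph_id = report$graph_id, metric = m, value = report[[m]])
  }))
}
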