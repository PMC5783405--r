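# Graph characteristics of a consensus network: density, degree, normalized
# centralities, Markov blankets, and modularity communities. Centralities
# and communities are computed on the undirected projection of the DAG;
# density uses the directed formula.

dag_to_igraph <- function(dag, directed = FALSE) {
  g <- igraph::make_empty_graph(n = length(dag$nodes), directed = directed)
  g <- igraph::set_vertex_attr(g, "name", value = dag$nodes)
  if (nrow(dag$arcs)) {
    edges <- rbind(dag$arcs$from, dag$arcs$to)
    g <- igraph::add_edges(g, as.vector(edges))
    if (!directed) g <- igraph::simplify(g)
  }
  g
}

#' Directed density of a DAG
#'
#' The proportion of the `n (n - 1)` possible directed arcs present.
#'
#' @param dag A `bn_dag` with at least two nodes.
#' @return A number in `[0, 1]`.
#' @export
graph_density <- function(dag) {
  n <- length(dag$nodes)
  if (n < 2) abort("density needs at least two nodes")
  nrow(dag$arcs) / (n * (n - 1))
}

#' Node degree (incoming plus outgoing edges)
#' @param dag A `bn_dag`.
#' @param node Node name.
#' @return Integer degree.
#' @export
node_degree <- function(dag, node) {
  if (!node %in% dag$nodes) abort(sprintf("unknown node '%s'", node))
  sum(dag$arcs$from == node) + sum(dag$arcs$to == node)
}

#' Normalized closeness centrality
#'
#' Freeman closeness on the undirected projection with the
#' reachable-fraction correction for disconnected graphs:
#' `(reachable / (n - 1)) * (reachable / sum of shortest-path distances)`,
#' where `reachable` counts the other nodes the node can reach. Isolated
#' nodes score 0.
#'
#' @param dag A `bn_dag`.
#' @param node Node name (default: all nodes).
#' @return Named numeric vector in `[0, 1]`.
#' @export
closeness_centrality <- function(dag, node = dag$nodes) {
  stopifnot(all(node %in% dag$nodes))
  g <- dag_to_igraph(dag)
  n <- length(dag$nodes)
  d <- igraph::distances(g, v = node, to = igraph::V(g))
  vapply(seq_along(node), function(i) {
    di <- d[i, setdiff(colnames(d), node[i])]
    reach <- sum(is.finite(di))
    if (reach == 0) return(0)
    (reach / (n - 1)) * (reach / sum(di[is.finite(di)]))
  }, numeric(1), USE.NAMES = FALSE) -> out
  setNames(out, node)
}

#' Normalized betweenness centrality
#'
#' Shortest-path betweenness on the undirected projection, normalized by
#' `(n - 1)(n - 2) / 2`.
#'
#' @param dag A `bn_dag`.
#' @param node Node name (default: all nodes).
#' @return Named numeric vector in `[0, 1]`.
#' @export
betweenness_centrality <- function(dag, node = dag$nodes) {
  stopifnot(all(node %in% dag$nodes))
  g <- dag_to_igraph(dag)
  n <- length(dag$nodes)
  if (n < 3) return(setNames(rep(0, length(node)), node))
  b <- igraph::betweenness(g, v = node, directed = FALSE)
  setNames(as.numeric(b) / ((n - 1) * (n - 2) / 2), node)
}

#' Louvain community detection on the undirected projection
#'
#' Greedy modularity optimization without edge weights at a configurable
#' resolution. The seed fixes tie-breaking; community labels are
#' canonicalized so that communities are numbered by their smallest member
#' node name.
#'
#' @param dag A `bn_dag` (non-empty).
#' @param resolution Modularity resolution. Default 1.0.
#' @param seed Integer seed.
#' @return An object of class `bn_communities`: tibble with `node`,
#'   `community`; attribute `modularity` holds Q.
#' @export
detect_communities <- function(dag, resolution = 1.0, seed = 1) {
  if (length(dag$nodes) == 0) abort("empty graph")
  g <- dag_to_igraph(dag)
  cl <- with_seed(seed, igraph::cluster_louvain(g, resolution = resolution))
  membership <- igraph::membership(cl)
  q <- igraph::modularity(g, membership)
  # canonical labels: communities numbered by smallest member node name
  reps <- tapply(names(membership), membership, min)
  canon <- setNames(seq_along(reps), names(reps)[order(unname(reps))])
  out <- tibble::tibble(
    node = names(membership),
    community = as.integer(canon[as.character(membership)])
  )
  structure(out, class = c("bn_communities", class(out)), modularity = q)
}

#' @export
print.bn_communities <- function(x, ...) {
  cat(sprintf(
    "<bn_communities> %d communities, Q = %.4f\n",
    length(unique(x$community)), attr(x, "modularity")
  ))
  NextMethod()
}

#' Per-node and whole-graph metrics report
#'
#' @param dag A `bn_dag`.
#' @param categories Optional named character vector of node categories.
#' @param resolution,seed Passed to [detect_communities()].
#' @return An object of class `bn_metrics`: per-node tibble with `node`,
#'   `category`, `degree`, `closeness`, `betweenness`,
#'   `markov_blanket_size`, `community`; the graph summary (node count,
#'   edge count, density, mean Markov-blanket size, modularity) is attached
#'   and available via [glance()].
#' @export
metrics_report <- function(dag, categories = NULL, resolution = 1.0, seed = 1) {
  comm <- detect_communities(dag, resolution = resolution, seed = seed)
  per_node <- tibble::tibble(
    node = dag$nodes,
    category = if (is.null(categories)) NA_character_ else unname(categories[dag$nodes]),
    degree = vapply(dag$nodes, function(v) node_degree(dag, v), numeric(1)),
    closeness = unname(closeness_centrality(dag)),
    betweenness = unname(betweenness_centrality(dag)),
    markov_blanket_size = vapply(dag$nodes, function(v) length(markov_blanket(dag, v)), numeric(1))
  )
  per_node <- dplyr::left_join(per_node, comm, by = "node")
  summary <- tibble::tibble(
    n_nodes = length(dag$nodes),
    n_edges = nrow(dag$arcs),
    density = graph_density(dag),
    mean_markov_blanket = mean(per_node$markov_blanket_size),
    modularity = attr(comm, "modularity")
  )
  structure(per_node, class = c("bn_metrics", class(per_node)), summary = summary)
}

#' @export
print.bn_metrics <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "<bn_metrics> %d nodes, %d edges, density %.3f, mean Markov blanket %.1f\n",
    s$n_nodes, s$n_edges, s$density, s$mean_markov_blanket
  ))
  NextMethod()
}

#' @export
glance.bn_metrics <- function(x, ...) attr(x, "summary")

#' @export
tidy.bn_metrics <- function(x, ...) tibble::as_tibble(unclass(x))
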