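#' Directed acyclic graph over named variables
#'
#' @param nodes Character vector of node names.
#' @param arcs Data frame with columns `from`, `to` (may be empty).
#' @return An object of class `bn_dag`: list with `nodes` and an `arcs`
#'   tibble.
#' @export
bn_dag <- function(nodes, arcs = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node names")
  if (is.null(arcs) || nrow(arcs) == 0L) {
    arcs <- tibble::tibble(from = character(), to = character())
  } else {
    arcs <- tibble::tibble(from = as.character(arcs$from), to = as.character(arcs$to))
  }
  if (any(arcs$from == arcs$to)) abort("self-loops are not allowed")
  if (anyDuplicated(paste(arcs$from, arcs$to))) abort("duplicate arcs")
  unknown <- setdiff(c(arcs$from, arcs$to), nodes)
  if (length(unknown)) abort(sprintf("arc references unknown node '%s'", unknown[1]))
  dag <- structure(list(nodes = nodes, arcs = arcs), class = "bn_dag")
  if (dag_has_cycle(dag)) abort("arcs form a cycle")
  dag
}

#' @export
print.bn_dag <- function(x, ...) {
  cat(sprintf("<bn_dag> %d nodes, %d arcs\n", length(x$nodes), nrow(x$arcs)))
  invisible(x)
}

#' @export
variables.bn_dag <- function(x) x$nodes

# Adjacency matrix (logical, from x to) of a bn_dag.
dag_adjacency <- function(dag) {
  n <- length(dag$nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(dag$nodes, dag$nodes))
  if (nrow(dag$arcs)) adj[cbind(dag$arcs$from, dag$arcs$to)] <- TRUE
  adj
}

dag_has_cycle <- function(dag) {
  adj <- dag_adjacency(dag)
  adjacency_has_cycle(adj)
}

# Kahn's algorithm on a logical adjacency matrix.
adjacency_has_cycle <- function(adj) {
  n <- nrow(adj)
  indeg <- colSums(adj)
  queue <- which(indeg == 0)
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    seen <- seen + 1L
    out <- which(adj[v, ])
    for (w in out) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  seen < n
}

# TRUE if a directed path v -> ... -> w exists in adj.
has_path <- function(adj, v, w) {
  if (v == w) return(TRUE)
  n <- nrow(adj)
  visited <- logical(n)
  stack <- v
  while (length(stack)) {
    u <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (u == w) return(TRUE)
    if (visited[u]) next
    visited[u] <- TRUE
    stack <- c(stack, which(adj[u, ] & !visited))
  }
  FALSE
}

#' Topological order of a DAG
#' @param dag A `bn_dag`.
#' @return Character vector of node names, parents before children.
#' @export
topological_order <- function(dag) {
  adj <- dag_adjacency(dag)
  n <- nrow(adj)
  indeg <- colSums(adj)
  order <- integer(0)
  avail <- which(indeg == 0)
  indeg[avail] <- NA
  while (length(avail)) {
    v <- min(avail)
    avail <- setdiff(avail, v)
    order <- c(order, v)
    for (w in which(adj[v, ])) {
      indeg[w] <- indeg[w] - 1L
      if (!is.na(indeg[w]) && indeg[w] == 0L) {
        avail <- c(avail, w)
        indeg[w] <- NA
      }
    }
  }
  if (length(order) < n) abort("graph has a cycle")
  dag$nodes[order]
}

#' Parents and children of a node
#' @param dag A `bn_dag`.
#' @param node Node name.
#' @return Character vector of node names.
#' @export
parents <- function(dag, node) {
  stopifnot(node %in% dag$nodes)
  dag$arcs$from[dag$arcs$to == node]
}

#' @rdname parents
#' @export
children <- function(dag, node) {
  stopifnot(node %in% dag$nodes)
  dag$arcs$to[dag$arcs$from == node]
}

#' Structural constraints for the search
#'
#' Roots have all incoming arcs forbidden; leaves have all outgoing arcs
#' forbidden. Additional explicit forbidden/required ordered pairs can be
#' supplied.
#'
#' @param nodes All node names.
#' @param roots,leaves Node names constrained as roots / leaves.
#' @param forbidden,required Optional data frames of ordered pairs
#'   (`from`, `to`).
#' @return An object of class `bn_constraints` holding logical forbidden and
#'   required adjacency matrices.
#' @export
structural_constraints <- function(nodes, roots = character(), leaves = character(),
                                   forbidden = NULL, required = NULL) {
  nodes <- as.character(nodes)
  stopifnot(all(roots %in% nodes), all(leaves %in% nodes))
  n <- length(nodes)
  forb <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  req <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  forb[, roots] <- TRUE
  forb[leaves, ] <- TRUE
  diag(forb) <- TRUE
  if (!is.null(forbidden) && nrow(forbidden)) {
    forb[cbind(as.character(forbidden$from), as.character(forbidden$to))] <- TRUE
  }
  if (!is.null(required) && nrow(required)) {
    req[cbind(as.character(required$from), as.character(required$to))] <- TRUE
  }
  if (any(req & forb)) abort("required arcs overlap forbidden arcs")
  if (adjacency_has_cycle(req)) abort("required arcs form a cycle")
  structure(
    list(nodes = nodes, forbidden = forb, required = req,
         roots = roots, leaves = leaves),
    class = "bn_constraints"
  )
}

#' @export
print.bn_constraints <- function(x, ...) {
  cat(sprintf(
    "<bn_constraints> %d nodes; roots: %s; leaves: %s; %d forbidden, %d required pairs\n",
    length(x$nodes),
    paste(x$roots, collapse = ","), paste(x$leaves, collapse = ","),
    sum(x$forbidden) - length(x$nodes), sum(x$required)
  ))
  invisible(x)
}

#' Constraints implied by a dataset's declared roles
#' @param dataset A [bn_dataset()].
#' @return A `bn_constraints` object.
#' @export
constraints_from_roles <- function(dataset) {
  roles <- variable_roles(dataset)
  structural_constraints(
    nodes = names(roles),
    roots = names(roles)[roles == "root"],
    leaves = names(roles)[roles == "leaf"]
  )
}

#' Arc list of a DAG as a tibble
#' @param x A `bn_dag`.
#' @param ... Unused.
#' @return Tibble with columns `from`, `to`.
#' @export
tidy.bn_dag <- function(x, ...) x$arcs

#' One-row graph summary of a DAG
#' @param x A `bn_dag`.
#' @param ... Unused.
#' @return Tibble with node count, arc count, directed density, and mean
#'   Markov-blanket size.
#' @export
glance.bn_dag <- function(x, ...) {
  tibble::tibble(
    n_nodes = length(x$nodes),
    n_arcs = nrow(x$arcs),
    density = if (length(x$nodes) >= 2) graph_density(x) else NA_real_,
    mean_markov_blanket = mean(vapply(
      x$nodes, function(v) length(markov_blanket(x, v)), numeric(1)
    ))
  )
}

#' Read / write a DAG as an arc-list CSV
#' @param dag A `bn_dag`.
#' @param file Path to a CSV with columns `from,to`.
#' @param nodes For reading: the full node set (isolated nodes are not
#'   recoverable from the arc list alone).
#' @return `write_arcs()` returns `file` invisibly; `read_arcs()` a
#'   `bn_dag`.
#' @export
write_arcs <- function(dag, file) {
  utils::write.csv(dag$arcs, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_arcs
#' @export
read_arcs <- function(file, nodes = NULL) {
  arcs <- utils::read.csv(file, colClasses = "character")
  bn_dag(nodes %||% unique(c(arcs$from, arcs$to)), arcs)
}
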