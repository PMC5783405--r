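# Bootstrap arc-strength ensembles and thresholded consensus DAGs.

new_arc_strength <- function(tbl, n_networks) {
  tbl <- tibble::as_tibble(tbl)
  structure(tbl, class = c("bn_arc_strength", class(tbl)), n_networks = n_networks)
}

#' Build a bootstrap ensemble of learned networks and pool arc frequencies
#'
#' For each of `n_seeds` search seeds, `n_boot` bootstrap resamples of the
#' subjects are drawn and a network is learned by [hill_climb()] on each.
#' Arc frequencies are pooled over the whole ensemble: for every unordered
#' node pair, `support` is the fraction of networks containing an arc
#' between the pair in either direction, and `direction` is the fraction of
#' those supporting networks that orient it that way.
#'
#' The master seed derives one sub-stream per search seed and one resampling
#' seed per replicate through a counter scheme, so results are reproducible
#' and independent of any parallel execution plan.
#'
#' @param data A [bn_dataset()] or data frame of factors.
#' @param constraints Optional [structural_constraints()]; defaults to the
#'   dataset's declared roles.
#' @param alpha Imaginary sample size for BDeu scoring.
#' @param n_seeds Number of hill-climbing restart seeds (study default 1000).
#' @param n_boot Bootstrap replicates per seed (study default 1000).
#' @param master_seed Integer master seed.
#' @return A `bn_arc_strength` tibble with columns `from`, `to`, `support`,
#'   `direction`, one row per ordered pair of distinct nodes (direction is
#'   `NA` for unsupported pairs); attribute `n_networks` carries the
#'   ensemble size.
#' @export
bootstrap_ensemble <- function(data, constraints = NULL, alpha = 1,
                               n_seeds = 1000, n_boot = 1000, master_seed = 1) {
  stopifnot(n_seeds >= 1, n_boot >= 1)
  codes <- scoring_codes(data)
  nodes <- colnames(codes$mat)
  constraints <- constraints %||% default_constraints(data, nodes)
  if (!setequal(constraints$nodes, nodes)) abort("constraints cover different nodes")
  forb <- constraints$forbidden[nodes, nodes]
  req <- constraints$required[nodes, nodes]
  n <- nrow(codes$mat)
  p <- length(nodes)

  search_seeds <- derive_seeds(master_seed, n_seeds)
  arc_counts <- matrix(0, p, p, dimnames = list(nodes, nodes))
  for (s in seq_len(n_seeds)) {
    boot_seeds <- derive_seeds(search_seeds[s], n_boot)
    for (b in seq_len(n_boot)) {
      rows <- with_seed(boot_seeds[b], sample.int(n, n, replace = TRUE))
      fit <- hill_climb_codes(
        codes$mat[rows, , drop = FALSE], codes$nlev, nodes,
        forb, req, alpha, seed = search_seeds[s]
      )
      arc_counts <- arc_counts + fit$adj
    }
  }
  pool_arc_counts(arc_counts, n_seeds * n_boot)
}

# Turn an arc-count matrix into the strength/direction table.
pool_arc_counts <- function(arc_counts, n_networks) {
  nodes <- rownames(arc_counts)
  pairs <- expand.grid(
    from = nodes, to = nodes,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  fwd <- arc_counts[cbind(pairs$from, pairs$to)]
  rev <- arc_counts[cbind(pairs$to, pairs$from)]
  both <- fwd + rev
  tbl <- tibble::tibble(
    from = pairs$from,
    to = pairs$to,
    support = both / n_networks,
    direction = ifelse(both > 0, fwd / both, NA_real_)
  )
  new_arc_strength(dplyr::arrange(tbl, .data$from, .data$to), n_networks)
}

#' Arc-strength table of an explicit list of DAGs
#'
#' Pools an already-built ensemble (used for hand-checkable examples and for
#' associativity checks against [bootstrap_ensemble()]).
#'
#' @param dags List of `bn_dag` objects over the same node set.
#' @return A `bn_arc_strength` tibble.
#' @export
arc_strength_from_dags <- function(dags) {
  stopifnot(length(dags) >= 1)
  nodes <- dags[[1]]$nodes
  counts <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  for (d in dags) {
    stopifnot(setequal(d$nodes, nodes))
    if (nrow(d$arcs)) {
      counts[cbind(d$arcs$from, d$arcs$to)] <- counts[cbind(d$arcs$from, d$arcs$to)] + 1
    }
  }
  pool_arc_counts(counts, length(dags))
}

#' Threshold an arc-strength table into a consensus DAG
#'
#' Includes every unordered pair whose `support` meets the threshold,
#' oriented by majority `direction` (ties broken towards the
#' lexicographically smaller parent). If the thresholded graph is cyclic,
#' included arcs are deleted greedily by ascending `support * direction`
#' until it is acyclic; deletions are recorded on the result.
#'
#' @param strengths A `bn_arc_strength` table.
#' @param threshold Support threshold in (0, 1]. The study used 0.30 and a
#'   0.50 majority rule.
#' @return A `bn_dag`; attribute `"removed_for_acyclicity"` lists arcs (if
#'   any) dropped during cycle repair, and the included arcs' strengths are
#'   attached as attribute `"strengths"`.
#' @export
averaged_network <- function(strengths, threshold = 0.30) {
  stopifnot(threshold > 0, threshold <= 1)
  nodes <- sort(unique(c(strengths$from, strengths$to)))
  tbl <- tibble::as_tibble(strengths)
  tbl <- tbl[!is.na(tbl$direction) & tbl$support >= threshold, , drop = FALSE]
  # keep one orientation per unordered pair: majority direction, ties to the
  # lexicographically smaller `from`
  key <- ifelse(tbl$from < tbl$to, paste(tbl$from, tbl$to), paste(tbl$to, tbl$from))
  keep <- logical(nrow(tbl))
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) == 1L) {
      keep[idx] <- tbl$direction[idx] >= 0.5
    } else {
      d <- tbl$direction[idx]
      pick <- if (abs(d[1] - d[2]) < 1e-12) idx[order(tbl$from[idx])[1]] else idx[which.max(d)]
      keep[pick] <- TRUE
    }
  }
  arcs <- tbl[keep, , drop = FALSE]
  removed <- arcs[0, , drop = FALSE]
  adj <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  if (nrow(arcs)) adj[cbind(arcs$from, arcs$to)] <- TRUE
  while (adjacency_has_cycle(adj)) {
    on_cycle <- vapply(seq_len(nrow(arcs)), function(k) {
      # arc is on a cycle iff a path to -> from exists
      has_path(adj, match(arcs$to[k], nodes), match(arcs$from[k], nodes))
    }, logical(1))
    weight <- arcs$support * arcs$direction
    weight[!on_cycle] <- Inf
    drop_k <- which.min(weight)
    adj[arcs$from[drop_k], arcs$to[drop_k]] <- FALSE
    removed <- dplyr::bind_rows(removed, arcs[drop_k, , drop = FALSE])
    arcs <- arcs[-drop_k, , drop = FALSE]
  }
  dag <- bn_dag(nodes, arcs[, c("from", "to")])
  attr(dag, "strengths") <- arcs
  attr(dag, "removed_for_acyclicity") <- removed
  dag
}

#' Partition consensus edges into bridging vs within-category edges
#'
#' A bridging edge connects nodes of different a-priori categories; an
#' intra edge connects nodes of the same category. Optionally re-filters the
#' edges at a higher support threshold using the strengths attached by
#' [averaged_network()] (or supplied explicitly).
#'
#' @param dag A consensus `bn_dag`.
#' @param categories Named character vector: node -> category.
#' @param strengths Optional `bn_arc_strength` table for support filtering.
#' @param min_support Optional higher support threshold applied on top.
#' @return Tibble of edges with `from`, `to`, `from_category`,
#'   `to_category`, `support` (if available) and logical `bridging`.
#' @export
bridging_edges <- function(dag, categories, strengths = NULL, min_support = NULL) {
  uncat <- setdiff(dag$nodes, names(categories)[!is.na(categories)])
  if (length(uncat)) abort(sprintf("uncategorized node '%s'", uncat[1]))
  edges <- dag$arcs
  edges$from_category <- unname(categories[edges$from])
  edges$to_category <- unname(categories[edges$to])
  edges$bridging <- edges$from_category != edges$to_category
  strengths <- strengths %||% attr(dag, "strengths")
  if (!is.null(strengths)) {
    s <- tibble::as_tibble(strengths)[, c("from", "to", "support")]
    edges <- dplyr::left_join(edges, s, by = c("from", "to"))
  }
  if (!is.null(min_support)) {
    if (is.null(edges$support)) abort("min_support given but no strengths available")
    edges <- edges[!is.na(edges$support) & edges$support >= min_support, , drop = FALSE]
  }
  tibble::as_tibble(edges)
}

#' @export
print.bn_arc_strength <- function(x, ...) {
  cat(sprintf(
    "<bn_arc_strength> pooled over %s networks\n",
    format(attr(x, "n_networks"), big.mark = ",")
  ))
  NextMethod()
}

#' Read / write an arc-strength table as CSV
#' @param strengths A `bn_arc_strength` table.
#' @param file CSV path (`from,to,support,direction`).
#' @param n_networks Ensemble size recorded on reading.
#' @return `read_arc_strength()` returns a `bn_arc_strength` tibble.
#' @export
write_arc_strength <- function(strengths, file) {
  utils::write.csv(tibble::as_tibble(strengths), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_arc_strength
#' @export
read_arc_strength <- function(file, n_networks = NA_integer_) {
  tbl <- utils::read.csv(file, colClasses = c(
    from = "character", to = "character", support = "numeric", direction = "numeric"
  ))
  new_arc_strength(tbl, n_networks)
}
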