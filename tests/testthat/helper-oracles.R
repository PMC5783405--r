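# Independent oracles and small fixture builders used across the suite.

# Sequential Dirichlet posterior-predictive log marginal likelihood of a
# child given parents under the BDeu prior: walks the rows one at a time,
# multiplying P(x_i | x_1..x_{i-1}) = (a_cell + N_cell) / (a_cfg + N_cfg).
# Independent of the lgamma closed form used by the package.
oracle_local_marginal <- function(df, child, parent_set, alpha) {
  r <- nlevels(df[[child]])
  q <- if (length(parent_set)) prod(vapply(df[parent_set], nlevels, integer(1))) else 1
  a_cell <- alpha / (r * q)
  a_cfg <- alpha / q
  cell_counts <- new.env(parent = emptyenv())
  cfg_counts <- new.env(parent = emptyenv())
  ll <- 0
  for (i in seq_len(nrow(df))) {
    cfg <- if (length(parent_set)) {
      paste(vapply(parent_set, function(p) as.character(df[[p]][i]), character(1)), collapse = "\r")
    } else {
      "."
    }
    cell <- paste(cfg, as.character(df[[child]][i]), sep = "\r\r")
    n_cell <- cell_counts[[cell]] %||% 0
    n_cfg <- cfg_counts[[cfg]] %||% 0
    ll <- ll + log((a_cell + n_cell) / (a_cfg + n_cfg))
    cell_counts[[cell]] <- n_cell + 1
    cfg_counts[[cfg]] <- n_cfg + 1
  }
  ll
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Full joint enumeration oracle for P(target | evidence) on a bn_fit.
oracle_enumeration_query <- function(fit, target, evidence = list()) {
  nodes <- fit$dag$nodes
  grid <- expand.grid(fit$levels[nodes], stringsAsFactors = FALSE)
  names(grid) <- nodes
  jp <- vapply(seq_len(nrow(grid)), function(k) {
    p <- 1
    for (v in nodes) {
      pa <- bnconsensus::parents(fit$dag, v)
      cpt <- fit$cpts[[v]]
      idx <- c(list(grid[[v]][k]), lapply(pa, function(w) grid[[w]][k]))
      p <- p * do.call(`[`, c(list(cpt), idx))
    }
    p
  }, numeric(1))
  keep <- rep(TRUE, nrow(grid))
  for (v in names(evidence)) keep <- keep & grid[[v]] == evidence[[v]]
  num <- tapply(jp[keep], factor(grid[[target]][keep], levels = fit$levels[[target]]), sum)
  num[is.na(num)] <- 0
  as.numeric(num) / sum(num)
}

# Random fitted network with <= max_states total states (product of level
# counts), random DAG, random positive CPTs.
random_bn_fit <- function(seed, max_nodes = 6, max_states = 20) {
  set.seed(seed)
  repeat {
    p <- sample(2:max_nodes, 1)
    nlev <- sample(2:3, p, replace = TRUE)
    if (prod(nlev) <= max_states) break
  }
  nodes <- paste0("v", seq_len(p))
  arcs <- NULL
  for (j in 2:p) {
    pa <- which(stats::runif(j - 1) < 0.5)
    if (length(pa)) arcs <- rbind(arcs, data.frame(from = nodes[pa], to = nodes[j]))
  }
  dag <- bnconsensus::bn_dag(nodes, arcs)
  levels <- lapply(nlev, function(r) paste0("l", seq_len(r)))
  names(levels) <- nodes
  cpts <- lapply(nodes, function(v) {
    pa <- bnconsensus::parents(dag, v)
    r <- length(levels[[v]])
    q_dims <- vapply(levels[pa], length, integer(1))
    q <- prod(q_dims)
    rows <- vapply(seq_len(max(q, 1)), function(j) {
      x <- stats::rgamma(r, 1) + 0.05
      x / sum(x)
    }, numeric(r))
    array(rows, dim = c(r, q_dims), dimnames = c(setNames(list(levels[[v]]), v), levels[pa]))
  })
  names(cpts) <- nodes
  structure(
    list(dag = dag, levels = levels, cpts = cpts, smoothing = 0,
         unobserved_configs = list()),
    class = "bn_fit"
  )
}

# Betweenness by explicit shortest-path enumeration on an undirected graph
# given as an adjacency matrix (small n only).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  paths_between <- function(s, t) {
    # all simple paths s -> t, then keep the shortest
    out <- list()
    walk <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (w in which(adj[v, ])) {
        if (!w %in% path) walk(c(path, w))
      }
    }
    walk(s)
    if (!length(out)) return(list())
    len <- vapply(out, length, integer(1))
    out[len == min(len)]
  }
  b <- numeric(n)
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      sp <- paths_between(s, t)
      if (!length(sp)) next
      for (v in setdiff(1:n, c(s, t))) {
        thru <- sum(vapply(sp, function(p) v %in% p, logical(1)))
        b[v] <- b[v] + thru / length(sp)
      }
    }
  }
  b / ((n - 1) * (n - 2) / 2)
}

# Toy count table: subjects x taxa tibble.
toy_counts <- function(m, ids = paste0("s", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% paste0("t", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(subject_id = ids), tibble::as_tibble(m))
}

# Small complete discrete data frame of factors.
rand_factor_df <- function(n, nlev, seed) {
  set.seed(seed)
  out <- lapply(seq_along(nlev), function(j) {
    factor(sample(paste0("l", seq_len(nlev[j])), n, replace = TRUE),
           levels = paste0("l", seq_len(nlev[j])))
  })
  names(out) <- paste0("v", seq_along(nlev))
  tibble::as_tibble(out)
}

# Recovery study conditions: 15-node layered truth with strong effects.
recovery_config <- function(master_seed = 7) {
  bnconsensus::sim_config(
    n_subjects = 2000, n_taxa = 5, n_habits = 4, n_symptoms = 2,
    n_nuisance_taxa = 0, n_filler_missing = 0, n_filler_sparse = 0,
    effect_strength = 0.9, level_floor = 0.05, edge_density = 0.2,
    missing_rate = 0, n_low_depth = 0, master_seed = master_seed
  )
}

# Paths where the deposited study supplementary tables would live if
# available; the replication tests run against them.
study_file <- function(name) {
  file.path(system.file("extdata", package = "bnconsensus"), "study", name)
}
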