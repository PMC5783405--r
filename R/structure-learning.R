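# BDeu scoring and constrained hill climbing.
#
# All scoring works on an integer-coded view of the dataset (level indices),
# so scores are functions of contingency counts only and never depend on row
# order. Local scores are memoised per (child, parent-set).

new_score_ctx <- function(mat, nlev, alpha) {
  env <- new.env(parent = emptyenv())
  env$mat <- mat
  env$nlev <- nlev
  env$alpha <- alpha
  env$cache <- new.env(parent = emptyenv(), hash = TRUE)
  env
}

# BDeu log marginal likelihood of one node given a parent set, uniform
# pseudo-counts alpha/(r*q) per cell. Unobserved configurations contribute
# zero and are skipped.
local_score_codes <- function(ctx, child, parent_idx) {
  key <- paste0(child, "|", paste(sort(parent_idx), collapse = ","))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  mat <- ctx$mat
  nlev <- ctx$nlev
  alpha <- ctx$alpha
  n <- nrow(mat)
  r <- nlev[child]
  q <- if (length(parent_idx)) prod(as.numeric(nlev[parent_idx])) else 1
  val <- 0
  if (n > 0L) {
    if (length(parent_idx)) {
      cfg <- numeric(n)
      for (p in parent_idx) cfg <- cfg * nlev[p] + (mat[, p] - 1)
    } else {
      cfg <- numeric(n)
    }
    cell <- cfg * r + (mat[, child] - 1)
    uc <- unique(cell)
    n_jk <- tabulate(match(cell, uc))
    ucfg <- floor(uc / r + 1e-9)
    grp <- match(ucfg, unique(ucfg))
    n_j <- as.numeric(rowsum(n_jk, grp))
    a_j <- alpha / q
    a_jk <- alpha / (r * q)
    val <- sum(lgamma(a_j) - lgamma(a_j + n_j)) +
      sum(lgamma(a_jk + n_jk) - lgamma(a_jk))
  }
  ctx$cache[[key]] <- val
  val
}

coerce_dataset <- function(data) {
  if (inherits(data, "bn_dataset")) data else bn_dataset(data)
}

# Light coercion for scoring and fitting: factors keep their declared level
# sets (the BDeu cell count r and CPT dimensions depend on them), constant
# columns are allowed, no completeness-filter invariants are enforced.
default_constraints <- function(data, nodes) {
  if (inherits(data, "bn_dataset")) {
    constraints_from_roles(data)
  } else {
    structural_constraints(nodes)
  }
}

scoring_codes <- function(data) {
  if (inherits(data, "bn_dataset")) return(dataset_codes(data))
  df <- as.data.frame(data)
  if (anyNA(df)) abort("data must be complete-case")
  df[] <- lapply(df, function(x) if (is.factor(x)) x else factor(x))
  mat <- vapply(df, as.integer, integer(nrow(df)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = ncol(df))
  colnames(mat) <- names(df)
  list(
    mat = mat,
    nlev = vapply(df, nlevels, integer(1)),
    levels = lapply(df, levels)
  )
}

#' Local BDeu score of one node given a parent set
#'
#' Log of the Dirichlet-multinomial marginal likelihood of the child's
#' conditional distribution under a uniform BDeu prior: the imaginary sample
#' size `alpha` is split evenly over the `r * q` cells of the child-by-
#' parent-configuration table.
#'
#' @param child Child variable name.
#' @param parent_set Character vector of parent names (may be empty).
#' @param data A [bn_dataset()] or data frame of factors.
#' @param alpha Imaginary sample size, > 0.
#' @return The log score (0 for empty data).
#' @export
local_bde_score <- function(child, parent_set, data, alpha = 1) {
  if (alpha <= 0) abort("alpha must be positive")
  if (child %in% parent_set) abort("child cannot be its own parent")
  codes <- scoring_codes(data)
  ctx <- new_score_ctx(codes$mat, codes$nlev, alpha)
  vars <- colnames(codes$mat)
  local_score_codes(ctx, match(child, vars), match(parent_set, vars))
}

#' Network BDe score (decomposable sum of local scores)
#'
#' @param dag A `bn_dag` over the data's variables.
#' @param data A [bn_dataset()] or data frame of factors.
#' @param alpha Imaginary sample size, > 0.
#' @return The log score of the DAG.
#' @export
network_score <- function(dag, data, alpha = 1) {
  if (alpha <= 0) abort("alpha must be positive")
  codes <- scoring_codes(data)
  vars <- colnames(codes$mat)
  if (!all(dag$nodes %in% vars)) abort("dag has nodes absent from the data")
  ctx <- new_score_ctx(codes$mat, codes$nlev, alpha)
  sum(vapply(dag$nodes, function(v) {
    local_score_codes(ctx, match(v, vars), match(parents(dag, v), vars))
  }, numeric(1)))
}

# Core greedy search on integer codes. Returns list(adj, trace, score).
#
# Incremental implementation: `gain_add[i, j]` holds the score delta of
# giving j the extra parent i (defined for every ordered pair), and
# `gain_del[i, j]` the delta of removing an existing arc i -> j. After a
# move only the affected children's entries are recomputed. Exact ties are
# broken by a seed-derived priority matrix, so the search is deterministic
# per seed while different seeds can walk different plateaus.
hill_climb_codes <- function(mat, nlev, nodes, forb, req, alpha, seed,
                             max_moves = 10000L, tol = 1e-8) {
  n <- length(nodes)
  ctx <- new_score_ctx(mat, nlev, alpha)
  adj <- matrix(FALSE, n, n)
  pa <- replicate(n, integer(0), simplify = FALSE)
  if (any(req)) {
    for (j in seq_len(n)) {
      pa[[j]] <- which(req[, j])
      adj[pa[[j]], j] <- TRUE
    }
  }
  ls_cur <- vapply(seq_len(n), function(j) local_score_codes(ctx, j, pa[[j]]), numeric(1))
  priority <- with_seed(seed, matrix(runif(n * n), n, n))

  gain_add <- matrix(-Inf, n, n)
  gain_del <- matrix(-Inf, n, n)
  refresh_child <- function(j) {
    for (i in seq_len(n)) {
      if (i == j) next
      gain_add[i, j] <<- if (i %in% pa[[j]]) {
        -Inf
      } else {
        local_score_codes(ctx, j, sort(c(pa[[j]], i))) - ls_cur[j]
      }
      gain_del[i, j] <<- if (i %in% pa[[j]]) {
        local_score_codes(ctx, j, setdiff(pa[[j]], i)) - ls_cur[j]
      } else {
        -Inf
      }
    }
  }
  for (j in seq_len(n)) refresh_child(j)

  trace <- list()
  score <- sum(ls_cur)
  t_forb <- t(forb)
  for (move_i in seq_len(max_moves)) {
    # reach[u, v]: a directed path u -> v of length >= 1 exists; computed by
    # iterated boolean matrix products so the acyclicity mask for additions
    # is vectorized (add i -> j is cyclic iff reach[j, i])
    reach <- adj
    repeat {
      # repeated squaring: path lengths double each round
      new_reach <- reach | (reach %*% reach > 0)
      if (identical(new_reach, reach)) break
      reach <- new_reach
    }
    add_ok <- !adj & !t(adj) & !forb & !t(reach)
    del_ok <- adj & !req
    rev_ok <- del_ok & !t_forb
    g_add <- ifelse(add_ok, gain_add, -Inf)
    g_del <- ifelse(del_ok, gain_del, -Inf)
    g_rev <- ifelse(rev_ok, gain_del + t(gain_add), -Inf)
    best <- NULL
    repeat {
      m <- pmax(max(g_add), max(g_del), max(g_rev))
      if (m <= tol) break
      # among all moves within 1e-12 of the max gain, take highest priority
      pick_from <- function(g, type) {
        hits <- which(g >= m - 1e-12)
        if (!length(hits)) return(NULL)
        hit <- hits[which.max(priority[hits])]
        ij <- arrayInd(hit, c(n, n))
        list(type = type, i = ij[1], j = ij[2], gain = g[hit], prio = priority[hit])
      }
      cands <- Filter(Negate(is.null), list(
        pick_from(g_add, "add"), pick_from(g_del, "delete"), pick_from(g_rev, "reverse")
      ))
      best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "prio"))]]
      # reversals still need a per-candidate check: reversing i -> j is
      # cyclic iff another i -> j path survives removal of the direct arc
      if (best$type == "reverse") {
        adj[best$i, best$j] <- FALSE
        cyc <- has_path(adj, best$i, best$j)
        adj[best$i, best$j] <- TRUE
        if (cyc) {
          g_rev[best$i, best$j] <- -Inf
          best <- NULL
          next
        }
      }
      break
    }
    if (is.null(best)) break
    i <- best$i
    j <- best$j
    touched <- j
    if (best$type == "add") {
      adj[i, j] <- TRUE
      pa[[j]] <- sort(c(pa[[j]], i))
    } else if (best$type == "delete") {
      adj[i, j] <- FALSE
      pa[[j]] <- setdiff(pa[[j]], i)
    } else {
      adj[i, j] <- FALSE
      adj[j, i] <- TRUE
      pa[[j]] <- setdiff(pa[[j]], i)
      pa[[i]] <- sort(c(pa[[i]], j))
      touched <- c(j, i)
    }
    for (v in touched) {
      ls_cur[v] <- local_score_codes(ctx, v, pa[[v]])
      refresh_child(v)
    }
    tadj <- t(adj)
    score <- sum(ls_cur)
    trace[[length(trace) + 1]] <- data.frame(
      move = best$type, from = nodes[i], to = nodes[j], score = score
    )
  }
  list(adj = adj, trace = trace, score = score)
}

#' Learn a DAG by constrained greedy hill climbing
#'
#' Starts from the empty graph (plus any required arcs) and repeatedly
#' applies the single-arc addition, deletion or reversal with the largest
#' positive BDeu score gain, subject to acyclicity and the structural
#' constraints, until a local optimum is reached. The seed fixes the
#' candidate-move visitation order (which breaks exact ties), making each
#' run deterministic while allowing multi-seed restarts.
#'
#' @param data A [bn_dataset()] or data frame of factors (complete cases).
#' @param constraints A [structural_constraints()] object, or `NULL` to use
#'   the roles declared on the dataset.
#' @param alpha Imaginary sample size, > 0.
#' @param seed Integer seed controlling move visitation order.
#' @return A `bn_dag` with attributes `score` (final log BDe score) and
#'   `trace` (tibble of accepted moves with running scores).
#' @export
hill_climb <- function(data, constraints = NULL, alpha = 1, seed = 1) {
  if (alpha <= 0) abort("alpha must be positive")
  codes <- scoring_codes(data)
  nodes <- colnames(codes$mat)
  constraints <- constraints %||% default_constraints(data, nodes)
  if (!setequal(constraints$nodes, nodes)) abort("constraints cover different nodes")
  forb <- constraints$forbidden[nodes, nodes]
  req <- constraints$required[nodes, nodes]
  fit <- hill_climb_codes(codes$mat, codes$nlev, nodes, forb, req, alpha, seed)
  arcs_idx <- which(fit$adj, arr.ind = TRUE)
  dag <- bn_dag(nodes, tibble::tibble(
    from = nodes[arcs_idx[, 1]], to = nodes[arcs_idx[, 2]]
  ))
  attr(dag, "score") <- fit$score
  attr(dag, "trace") <- if (length(fit$trace)) {
    tibble::as_tibble(do.call(rbind, fit$trace))
  } else {
    tibble::tibble(move = character(), from = character(), to = character(), score = numeric())
  }
  dag
}

#' Estimate the imaginary sample size by alternating optimization
#'
#' Alternates between learning a structure at the current `alpha` and
#' maximizing the network BDe score over `alpha` by one-dimensional search
#' on a log scale over `interval`, until the change in `alpha` drops below
#' `tol` or `max_iter` rounds have run.
#'
#' @param data A [bn_dataset()] or data frame of factors.
#' @param constraints Optional [structural_constraints()].
#' @param seed Integer seed (passed to the inner hill climbs).
#' @param interval Search bounds for `alpha`. Default `c(1e-2, 1e2)`.
#' @param tol Convergence tolerance on `alpha`. Default 1e-3.
#' @param max_iter Maximum alternation rounds. Default 10.
#' @return List with `alpha`, `dag` (structure learned at the final alpha),
#'   `converged`, and `iterations`. Warns on non-convergence.
#' @export
estimate_alpha_star <- function(data, constraints = NULL, seed = 1,
                                interval = c(1e-2, 1e2), tol = 1e-3, max_iter = 10) {
  if (nrow(scoring_codes(data)$mat) == 0) abort("empty data")
  alpha <- 1
  converged <- FALSE
  dag <- NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    dag <- hill_climb(data, constraints, alpha = alpha, seed = seed)
    opt <- stats::optimize(
      function(la) network_score(dag, data, alpha = exp(la)),
      interval = log(interval), maximum = TRUE, tol = 1e-6
    )
    alpha_new <- exp(opt$maximum)
    if (abs(alpha_new - alpha) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  if (!converged) {
    warn(sprintf("alpha estimation did not converge in %d iterations", max_iter))
  }
  list(alpha = alpha, dag = dag, converged = converged, iterations = iter)
}
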