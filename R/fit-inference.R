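# Parameter fitting on a fixed DAG and exact probabilistic queries.

#' Fit conditional probability tables by maximum likelihood
#'
#' For each node, `P(level k | parent config j) = (N_jk + s) / (N_j + s * r)`
#' with pseudo-count `s` (default 0, pure MLE). With `s = 0`, parent
#' configurations never observed in the data fall back to the uniform
#' distribution; such configurations are recorded on the result and a
#' warning is raised.
#'
#' @param dag A `bn_dag` whose nodes are variables of the data.
#' @param data A [bn_dataset()] or data frame of factors (complete cases).
#' @param smoothing Pseudo-count `s >= 0`. Default 0.
#' @return An object of class `bn_fit`: list with `dag`, `levels` (named
#'   list of level labels) and `cpts` (named list of arrays; first dimension
#'   is the node, remaining dimensions its parents).
#' @export
fit_mle <- function(dag, data, smoothing = 0) {
  stopifnot(smoothing >= 0)
  df <- if (inherits(data, "bn_dataset")) data$data else {
    d <- as.data.frame(data)
    if (anyNA(d)) abort("data must be complete-case")
    d[] <- lapply(d, function(x) if (is.factor(x)) x else factor(x))
    tibble::as_tibble(d)
  }
  if (!all(dag$nodes %in% names(df))) abort("dag has nodes absent from the data")
  # a CPT enumerates the full parent-level product; refuse infeasible tables
  for (v in dag$nodes) {
    q <- prod(vapply(df[parents(dag, v)], nlevels, integer(1)))
    if (q > 2^20) {
      abort(sprintf(
        "node '%s' has %.3g parent configurations; CPT is infeasible (use a sparser consensus, e.g. a higher support threshold)",
        v, q
      ))
    }
  }
  unobserved <- list()
  cpts <- lapply(dag$nodes, function(v) {
    pa <- parents(dag, v)
    counts <- table(df[c(v, pa)])
    counts <- counts + smoothing
    if (length(pa) == 0L) {
      p <- as.numeric(counts) / sum(counts)
      arr <- array(p, dim = length(p), dimnames = setNames(list(levels(df[[v]])), v))
      return(arr)
    }
    arr <- unclass(counts)
    n_j <- apply(arr, seq_along(pa) + 1L, sum)
    probs <- sweep(arr, seq_along(pa) + 1L, n_j, "/")
    if (any(n_j == 0)) {
      probs[is.nan(probs)] <- 1 / dim(arr)[1]
      unobserved[[v]] <<- sum(n_j == 0)
    }
    probs
  })
  names(cpts) <- dag$nodes
  if (length(unobserved)) {
    warn(sprintf(
      "unobserved parent configurations set to uniform for: %s",
      paste(names(unobserved), collapse = ", ")
    ))
  }
  structure(
    list(
      dag = dag,
      levels = lapply(df[dag$nodes], levels),
      cpts = cpts,
      smoothing = smoothing,
      unobserved_configs = unobserved
    ),
    class = "bn_fit"
  )
}

#' @export
print.bn_fit <- function(x, ...) {
  cat(sprintf(
    "<bn_fit> %d nodes, %d arcs, smoothing s=%g\n",
    length(x$dag$nodes), nrow(x$dag$arcs), x$smoothing
  ))
  invisible(x)
}

#' All conditional probabilities of a fitted network as a tibble
#' @param x A `bn_fit`.
#' @param ... Unused.
#' @return Tibble with `node`, `level`, one column per parent assignment
#'   (collapsed to a `parents` string) and `prob`.
#' @export
tidy.bn_fit <- function(x, ...) {
  purrr::map_dfr(x$dag$nodes, function(v) {
    cpt <- x$cpts[[v]]
    df <- as.data.frame.table(as.table(cpt), responseName = "prob", stringsAsFactors = FALSE)
    pa <- setdiff(names(df), c(v, "prob"))
    tibble::tibble(
      node = v,
      level = df[[v]],
      parents = if (length(pa)) {
        apply(df[, pa, drop = FALSE], 1, function(r) paste(pa, r, sep = "=", collapse = ","))
      } else {
        ""
      },
      prob = df$prob
    )
  })
}

#' @export
glance.bn_fit <- function(x, ...) {
  dplyr::mutate(
    glance.bn_dag(x$dag),
    n_parameters = sum(vapply(x$dag$nodes, function(v) {
      d <- dim(x$cpts[[v]])
      (d[1] - 1) * prod(d[-1])
    }, numeric(1))),
    smoothing = x$smoothing
  )
}

#' Markov blanket of a node
#'
#' Parents, children and the children's other parents; the node itself is
#' excluded.
#'
#' @param dag A `bn_dag`.
#' @param node Node name.
#' @return Character vector (sorted, possibly empty).
#' @export
markov_blanket <- function(dag, node) {
  if (!node %in% dag$nodes) abort(sprintf("unknown node '%s'", node))
  ch <- children(dag, node)
  co <- unlist(lapply(ch, function(c) parents(dag, c)))
  sort(setdiff(unique(c(parents(dag, node), ch, co)), node))
}

# ---- factors for variable elimination --------------------------------------

# A factor is list(vars = chr, tab = array with dimnames over levels); a
# factor over zero variables stores a scalar.
cpt_factor <- function(fbn, v) {
  list(vars = c(v, parents(fbn$dag, v)), tab = fbn$cpts[[v]])
}

factor_reduce <- function(f, evidence) {
  for (v in intersect(f$vars, names(evidence))) {
    d <- match(v, f$vars)
    li <- match(evidence[[v]], dimnames(f$tab)[[d]])
    if (is.na(li)) abort(sprintf("'%s' is not a level of '%s'", evidence[[v]], v))
    f$tab <- slice_array(f$tab, d, li)
    f$vars <- f$vars[-d]
  }
  f
}

slice_array <- function(arr, dim_i, level_i) {
  d <- dim(arr)
  dn <- dimnames(arr)
  idx <- lapply(d, seq_len)
  idx[[dim_i]] <- level_i
  out <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  if (length(d) == 1L) return(as.numeric(out))
  array(out, dim = d[-dim_i], dimnames = dn[-dim_i])
}

factor_product <- function(a, b) {
  if (length(a$vars) == 0L && length(b$vars) == 0L) {
    return(list(vars = character(), tab = as.numeric(a$tab) * as.numeric(b$tab)))
  }
  if (length(a$vars) == 0L) return(list(vars = b$vars, tab = b$tab * as.numeric(a$tab)))
  if (length(b$vars) == 0L) return(list(vars = a$vars, tab = a$tab * as.numeric(b$tab)))
  all_vars <- union(a$vars, b$vars)
  lev <- setNames(vector("list", length(all_vars)), all_vars)
  lev[a$vars] <- dimnames(a$tab)
  lev[b$vars] <- dimnames(b$tab)
  dims <- lengths(lev)
  expand <- function(f) {
    miss <- setdiff(all_vars, f$vars)
    tab <- f$tab
    vars <- f$vars
    if (length(miss)) {
      tab <- array(rep(as.vector(tab), times = prod(dims[miss])), dim = c(dim(f$tab), dims[miss]))
      vars <- c(vars, miss)
    }
    aperm(tab, match(all_vars, vars))
  }
  out <- expand(a) * expand(b)
  list(vars = all_vars, tab = array(out, dim = dims, dimnames = lev))
}

factor_marginalize <- function(f, v) {
  d <- match(v, f$vars)
  if (is.na(d)) return(f)
  if (length(f$vars) == 1L) {
    return(list(vars = character(), tab = sum(f$tab)))
  }
  tab <- apply(f$tab, seq_along(f$vars)[-d], sum)
  dn <- dimnames(f$tab)[-d]
  list(vars = f$vars[-d], tab = array(tab, dim = lengths(dn), dimnames = dn))
}

#' Exact conditional query on a fitted network
#'
#' Computes `P(target | evidence)` by variable elimination with a
#' min-degree elimination ordering. Evidence with zero probability under
#' the model is an error.
#'
#' @param fbn A `bn_fit`.
#' @param target Target variable name (not in the evidence).
#' @param evidence Named list or character vector of `variable = level`
#'   assignments (may be empty for the prior marginal).
#' @param method `"exact"` (variable elimination, default) or `"sampling"`
#'   (logic sampling with rejection; see `n_samples`).
#' @param n_samples Draws for the sampling method. Default 10000.
#' @param seed Seed for the sampling method.
#' @return An object of class `bn_query`: tibble with `level` and `prob`
#'   (summing to one), with the query recorded in attributes.
#' @export
query <- function(fbn, target, evidence = list(), method = c("exact", "sampling"),
                  n_samples = 10000, seed = 1) {
  method <- match.arg(method)
  evidence <- as.list(evidence)
  if (!target %in% fbn$dag$nodes) abort(sprintf("unknown target '%s'", target))
  if (target %in% names(evidence)) abort("target cannot be part of the evidence")
  bad <- setdiff(names(evidence), fbn$dag$nodes)
  if (length(bad)) abort(sprintf("evidence variable '%s' not in the network", bad[1]))

  if (method == "sampling") {
    return(query_sampling(fbn, target, evidence, n_samples, seed))
  }

  factors <- lapply(fbn$dag$nodes, function(v) factor_reduce(cpt_factor(fbn, v), evidence))
  eliminate <- setdiff(fbn$dag$nodes, c(target, names(evidence)))
  while (length(eliminate)) {
    # min-degree: eliminate the variable appearing with the fewest distinct
    # neighbours across current factors
    degree <- vapply(eliminate, function(v) {
      nb <- unique(unlist(lapply(factors, function(f) if (v %in% f$vars) f$vars else NULL)))
      length(setdiff(nb, v))
    }, numeric(1))
    v <- eliminate[which.min(degree)]
    eliminate <- setdiff(eliminate, v)
    touch <- vapply(factors, function(f) v %in% f$vars, logical(1))
    if (!any(touch)) next
    prod_f <- purrr::reduce(factors[touch], factor_product)
    factors <- c(factors[!touch], list(factor_marginalize(prod_f, v)))
  }
  final <- purrr::reduce(factors, factor_product)
  for (v in setdiff(final$vars, target)) final <- factor_marginalize(final, v)
  tab <- final$tab
  z <- sum(tab)
  if (z <= 0 || !is.finite(z)) abort("evidence has zero probability under the model")
  dist <- as.numeric(tab) / z
  new_bn_query(fbn$levels[[target]], dist, target, evidence, "exact")
}

new_bn_query <- function(levels, dist, target, evidence, method) {
  out <- tibble::tibble(level = levels, prob = dist)
  structure(
    out,
    class = c("bn_query", class(out)),
    target = target, evidence = evidence, method = method
  )
}

#' @export
print.bn_query <- function(x, ...) {
  ev <- attr(x, "evidence")
  cat(sprintf(
    "P(%s | %s) by %s\n",
    attr(x, "target"),
    if (length(ev)) paste(names(ev), unlist(ev), sep = "=", collapse = ", ") else "-",
    attr(x, "method")
  ))
  NextMethod()
}

query_sampling <- function(fbn, target, evidence, n_samples, seed) {
  tab <- forward_sample_fit(fbn, n_samples, seed)
  keep <- rep(TRUE, n_samples)
  for (v in names(evidence)) keep <- keep & tab[[v]] == evidence[[v]]
  if (!any(keep)) abort("no samples consistent with the evidence; use method = 'exact'")
  counts <- table(factor(tab[[target]][keep], levels = fbn$levels[[target]]))
  new_bn_query(fbn$levels[[target]], as.numeric(counts) / sum(counts), target, evidence, "sampling")
}

# Ancestral sampling from a fitted network (used by the sampling query mode).
forward_sample_fit <- function(fbn, n, seed) {
  ord <- topological_order(fbn$dag)
  out <- vector("list", length(ord))
  names(out) <- ord
  with_seed(seed, {
    for (v in ord) {
      pa <- parents(fbn$dag, v)
      lev <- fbn$levels[[v]]
      cpt <- fbn$cpts[[v]]
      if (length(pa) == 0L) {
        out[[v]] <- sample(lev, n, replace = TRUE, prob = as.numeric(cpt))
      } else {
        cfg <- rep(1L, n)
        mult <- 1L
        dims <- dim(cpt)[-1]
        for (d in seq_along(pa)) {
          li <- match(out[[pa[d]]], fbn$levels[[pa[d]]])
          cfg <- cfg + (li - 1L) * mult
          mult <- mult * dims[d]
        }
        r <- dim(cpt)[1]
        flat <- matrix(cpt, nrow = r)
        u <- runif(n)
        cum <- apply(flat, 2, cumsum)
        pick <- integer(n)
        for (k in seq_len(r)) {
          newly <- pick == 0L & u <= cum[k, cfg]
          pick[newly] <- k
        }
        pick[pick == 0L] <- r
        out[[v]] <- lev[pick]
      }
    }
  })
  tibble::as_tibble(out)
}

#' Batch conditional-probability report
#'
#' Runs a list of queries and returns a tidy table; used for reporting the
#' probabilities behind specific network findings.
#'
#' @param fbn A `bn_fit`.
#' @param queries List of specs, each a list with `target` and `evidence`
#'   (named list; may be empty).
#' @return Tibble with `target`, `evidence` (string), `level`, `prob`.
#' @export
conditional_probability_report <- function(fbn, queries) {
  purrr::map_dfr(queries, function(qs) {
    res <- query(fbn, qs$target, qs$evidence %||% list())
    ev <- qs$evidence %||% list()
    tibble::tibble(
      target = qs$target,
      evidence = if (length(ev)) paste(names(ev), unlist(ev), sep = "=", collapse = ",") else "",
      level = res$level,
      prob = res$prob
    )
  })
}

#' Sweep a node's full parent-configuration grid
#'
#' Computes `P(target = level | each parent configuration)` for every
#' combination of the target's parents (the computation behind
#' conditional-probability heat maps over parent states).
#'
#' @param fbn A `bn_fit`.
#' @param target Target node.
#' @return Tibble with one row per parent configuration and target level:
#'   parent columns, `level`, `prob`.
#' @export
parent_sweep <- function(fbn, target) {
  pa <- parents(fbn$dag, target)
  if (length(pa) == 0L) {
    res <- query(fbn, target)
    return(tibble::tibble(level = res$level, prob = res$prob))
  }
  grid <- expand.grid(lapply(fbn$levels[pa], identity), stringsAsFactors = FALSE)
  names(grid) <- pa
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    ev <- as.list(grid[i, , drop = FALSE])
    res <- query(fbn, target, ev)
    dplyr::bind_cols(
      tibble::as_tibble(grid[i, , drop = FALSE]),
      tibble::tibble(level = res$level, prob = res$prob)
    )
  })
}
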