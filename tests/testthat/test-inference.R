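test_that("MLE fitting reproduces empirical frequencies and handles edge cases", {
  d <- data.frame(
    a = factor(c("x", "x", "y", "y", "y")),
    b = factor(c("u", "u", "u", "v", "v"))
  )
  dag <- bn_dag(c("a", "b"), data.frame(from = "a", to = "b"))
  fit <- fit_mle(dag, d)
  expect_equal(as.numeric(fit$cpts$a), c(2 / 5, 3 / 5))
  expect_equal(unname(fit$cpts$b["u", "x"]), 1)
  expect_equal(unname(fit$cpts$b["v", "y"]), 2 / 3)
  # every CPT column sums to one
  expect_equal(unname(colSums(fit$cpts$b)), c(1, 1), tolerance = 1e-12)

  # deterministic all-(a1, b1) data
  d2 <- data.frame(
    a = factor(rep("a1", 4), levels = c("a1", "a2")),
    b = factor(rep("b1", 4), levels = c("b1", "b2"))
  )
  ds2 <- structure(
    list(
      data = tibble::as_tibble(d2), subject_ids = as.character(1:4),
      meta = tibble::tibble(
        variable = c("a", "b"), category = NA_character_, role = "free",
        levels = list(c("a1", "a2"), c("b1", "b2"))
      )
    ),
    class = "bn_dataset"
  )
  expect_warning(fit2 <- fit_mle(dag, ds2), "unobserved")
  expect_equal(unname(fit2$cpts$b["b1", "a1"]), 1)
  # unobserved parent config falls back to uniform
  expect_equal(unname(fit2$cpts$b[, "a2"]), c(0.5, 0.5))

  # smoothing formula
  fit3 <- suppressWarnings(fit_mle(dag, ds2, smoothing = 1))
  expect_equal(unname(fit3$cpts$b[, "a1"]), c((4 + 1) / (4 + 2), 1 / (4 + 2)))
})

test_that("exact queries equal the joint-enumeration oracle on random networks", {
  worst <- 0
  for (seed in 1:200) {
    fit <- random_bn_fit(seed)
    nodes <- fit$dag$nodes
    target <- sample(nodes, 1)
    n_ev <- sample(0:min(2, length(nodes) - 1), 1)
    ev_vars <- sample(setdiff(nodes, target), n_ev)
    evidence <- lapply(ev_vars, function(v) sample(fit$levels[[v]], 1))
    names(evidence) <- ev_vars
    got <- query(fit, target, evidence)
    want <- oracle_enumeration_query(fit, target, evidence)
    worst <- max(worst, max(abs(got$prob - want)))
  }
  expect_lt(worst, 1e-10)
})

test_that("deterministic chains compose like matrix products", {
  # a -> b -> c with hand-set stochastic tables
  levels <- list(a = c("0", "1"), b = c("0", "1"), c = c("0", "1"))
  tab_b <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, dimnames = list(b = levels$b, a = levels$a))
  tab_c <- matrix(c(0.7, 0.3, 0.4, 0.6), 2, dimnames = list(c = levels$c, b = levels$b))
  fit <- structure(
    list(
      dag = bn_dag(c("a", "b", "c"), data.frame(from = c("a", "b"), to = c("b", "c"))),
      levels = levels,
      cpts = list(
        a = array(c(0.5, 0.5), dim = 2, dimnames = list(a = levels$a)),
        b = array(tab_b, dim = c(2, 2), dimnames = dimnames(tab_b)),
        c = array(tab_c, dim = c(2, 2), dimnames = dimnames(tab_c))
      ),
      smoothing = 0, unobserved_configs = list()
    ),
    class = "bn_fit"
  )
  got <- query(fit, "c", list(a = "0"))
  want <- as.numeric(tab_c %*% tab_b[, "0"])
  expect_equal(got$prob, want, tolerance = 1e-12)

  # empty evidence returns the prior marginal
  prior <- query(fit, "b")
  expect_equal(prior$prob, as.numeric(tab_b %*% c(0.5, 0.5)), tolerance = 1e-12)
  expect_equal(sum(prior$prob), 1, tolerance = 1e-12)
})

test_that("impossible evidence is rejected", {
  levels <- list(a = c("0", "1"), b = c("0", "1"))
  fit <- structure(
    list(
      dag = bn_dag(c("a", "b"), data.frame(from = "a", to = "b")),
      levels = levels,
      cpts = list(
        a = array(c(1, 0), dim = 2, dimnames = list(a = levels$a)),
        b = array(c(1, 0, 0, 1), dim = c(2, 2), dimnames = list(b = levels$b, a = levels$a))
      ),
      smoothing = 0, unobserved_configs = list()
    ),
    class = "bn_fit"
  )
  expect_error(query(fit, "a", list(b = "1")), "zero probability")
  expect_error(query(fit, "a", list(a = "1")), "evidence")
  expect_error(query(fit, "zz"), "unknown target")
})

test_that("queries are self-consistent with the fitting data at s = 0", {
  set.seed(12)
  n <- 400
  a <- sample(c("0", "1"), n, TRUE)
  b <- ifelse(runif(n) < 0.8, a, sample(c("0", "1"), n, TRUE))
  d <- data.frame(a = factor(a), b = factor(b))
  dag <- bn_dag(c("a", "b"), data.frame(from = "a", to = "b"))
  fit <- fit_mle(dag, d)
  got <- query(fit, "b", list(a = "1"))
  emp <- prop.table(table(d$b[d$a == "1"]))
  expect_equal(got$prob, as.numeric(emp), tolerance = 1e-12)
})

test_that("sampling queries agree with exact inference", {
  fit <- random_bn_fit(424)
  target <- fit$dag$nodes[1]
  exact <- query(fit, target)
  samp <- query(fit, target, method = "sampling", n_samples = 30000, seed = 2)
  expect_equal(samp$prob, exact$prob, tolerance = 0.03)
})

test_that("Markov blankets collect parents, children and co-parents", {
  v <- bn_dag(c("A", "B", "C"), data.frame(from = c("A", "B"), to = c("C", "C")))
  expect_equal(markov_blanket(v, "A"), c("B", "C"))
  expect_equal(markov_blanket(v, "C"), c("A", "B"))
  iso <- bn_dag(c("A", "B"))
  expect_equal(markov_blanket(iso, "A"), character())
  expect_error(markov_blanket(v, "Z"), "unknown node")
})

test_that("parent sweeps cover every configuration with normalized rows", {
  fit <- random_bn_fit(77)
  # pick a node with at least one parent if available
  target <- NULL
  for (v in fit$dag$nodes) {
    if (length(parents(fit$dag, v)) >= 1) target <- v
  }
  if (is.null(target)) {
    fit <- random_bn_fit(78)
    for (v in fit$dag$nodes) if (length(parents(fit$dag, v)) >= 1) target <- v
  }
  sweep <- parent_sweep(fit, target)
  pa <- parents(fit$dag, target)
  q <- prod(vapply(fit$levels[pa], length, integer(1)))
  expect_equal(nrow(sweep), q * length(fit$levels[[target]]))
  sums <- tapply(sweep$prob, apply(sweep[, pa, drop = FALSE], 1, paste, collapse = "/"), sum)
  expect_equal(unname(as.numeric(sums)), rep(1, q), tolerance = 1e-12)
  # the sweep at a configuration equals the CPT column (target's parents
  # screen off everything else)
  first_cfg <- sweep[seq_along(fit$levels[[target]]), ]
  idx <- c(list(fit$levels[[target]]), as.list(unname(first_cfg[1, pa])))
  expect_equal(
    first_cfg$prob,
    as.numeric(do.call(`[`, c(list(fit$cpts[[target]]), idx))),
    tolerance = 1e-10
  )
})

test_that("batch reports run multiple queries tidily", {
  fit <- random_bn_fit(99)
  nodes <- fit$dag$nodes
  specs <- list(
    list(target = nodes[1]),
    list(target = nodes[2], evidence = setNames(list(fit$levels[[nodes[1]]][1]), nodes[1]))
  )
  rep <- conditional_probability_report(fit, specs)
  expect_setequal(unique(rep$target), nodes[1:2])
  expect_equal(
    sum(rep$prob[rep$target == nodes[1]]), 1, tolerance = 1e-12
  )
  expect_match(rep$evidence[rep$target == nodes[2]][1], "=")
})
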