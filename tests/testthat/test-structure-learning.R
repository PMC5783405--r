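test_that("local BDeu score matches the closed-form single-node case", {
  d <- data.frame(x = factor(c("a", "b")))
  expect_equal(local_bde_score("x", character(), d, alpha = 1), log(1 / 8))
  expect_error(local_bde_score("x", character(), d, alpha = 0), "positive")
  expect_error(local_bde_score("x", "x", d), "own parent")
})

test_that("empty data scores zero for any node and parent set", {
  d <- data.frame(
    x = factor(character(), levels = c("a", "b")),
    y = factor(character(), levels = c("a", "b", "c"))
  )
  expect_equal(local_bde_score("x", character(), d, alpha = 2), 0)
  expect_equal(local_bde_score("x", "y", d, alpha = 2), 0)
})

test_that("local scores equal the sequential posterior-predictive oracle", {
  for (seed in 1:40) {
    set.seed(seed)
    p <- sample(1:3, 1)
    n <- sample(1:8, 1)
    alpha <- sample(c(0.5, 1, 2, 7.3), 1)
    df <- rand_factor_df(n, rep(2, p), seed = seed + 1000)
    child <- sample(names(df), 1)
    parent_set <- setdiff(names(df), child)
    if (length(parent_set)) {
      parent_set <- sample(parent_set, sample(0:length(parent_set), 1))
    }
    expect_equal(
      local_bde_score(child, parent_set, df, alpha = alpha),
      oracle_local_marginal(df, child, parent_set, alpha),
      tolerance = 1e-10,
      info = sprintf("seed %d", seed)
    )
  }
})

test_that("Markov-equivalent DAGs receive identical BDe scores", {
  for (seed in 1:10) {
    d2 <- rand_factor_df(25, c(2, 3), seed = seed)
    names(d2) <- c("a", "b")
    s_ab <- network_score(bn_dag(c("a", "b"), data.frame(from = "a", to = "b")), d2, alpha = 1.3)
    s_ba <- network_score(bn_dag(c("a", "b"), data.frame(from = "b", to = "a")), d2, alpha = 1.3)
    expect_equal(s_ab, s_ba, tolerance = 1e-10)

    d3 <- rand_factor_df(30, c(2, 2, 3), seed = seed + 50)
    names(d3) <- c("a", "b", "c")
    chain1 <- bn_dag(names(d3), data.frame(from = c("a", "b"), to = c("b", "c")))
    chain2 <- bn_dag(names(d3), data.frame(from = c("c", "b"), to = c("b", "a")))
    fork <- bn_dag(names(d3), data.frame(from = c("b", "b"), to = c("a", "c")))
    s <- vapply(list(chain1, chain2, fork), network_score, numeric(1), data = d3, alpha = 2)
    expect_equal(s[1], s[2], tolerance = 1e-10)
    expect_equal(s[1], s[3], tolerance = 1e-10)
  }
})

test_that("network score is the decomposable sum of local scores", {
  df <- rand_factor_df(40, c(2, 2, 3), seed = 3)
  names(df) <- c("a", "b", "c")
  dag <- bn_dag(names(df), data.frame(from = c("a", "a"), to = c("b", "c")))
  manual <- local_bde_score("a", character(), df, 1) +
    local_bde_score("b", "a", df, 1) +
    local_bde_score("c", "a", df, 1)
  expect_equal(network_score(dag, df, 1), manual)
  # empty DAG = sum of parent-free local scores
  empty <- bn_dag(names(df))
  expect_equal(
    network_score(empty, df, 1),
    sum(vapply(names(df), local_bde_score, numeric(1),
               parent_set = character(), data = df, alpha = 1))
  )
  expect_error(
    bn_dag(c("a", "b"), data.frame(from = c("a", "b"), to = c("b", "a"))),
    "cycle"
  )
})

test_that("hill climbing finds the right structure in clear-cut cases", {
  # two independent uniform binaries: empty graph
  set.seed(5)
  n <- 1000
  ind <- data.frame(
    a = factor(sample(c("0", "1"), n, TRUE)),
    b = factor(sample(c("0", "1"), n, TRUE))
  )
  g <- hill_climb(ind, structural_constraints(c("a", "b")), alpha = 1, seed = 1)
  expect_equal(nrow(tidy(g)), 0)

  # b an exact copy of a: exactly one arc between them (either direction)
  a <- sample(c("0", "1"), 50, TRUE)
  copy <- data.frame(a = factor(a), b = factor(a))
  g2 <- hill_climb(copy, structural_constraints(c("a", "b")), alpha = 1, seed = 2)
  expect_equal(nrow(tidy(g2)), 1)
  expect_setequal(unlist(tidy(g2)), c("a", "b"))

  # all arcs forbidden: empty result regardless of the data
  forb <- expand.grid(from = c("a", "b"), to = c("a", "b"), stringsAsFactors = FALSE)
  cons <- structural_constraints(c("a", "b"), forbidden = forb[forb$from != forb$to, ])
  g3 <- hill_climb(copy, cons, alpha = 1, seed = 3)
  expect_equal(nrow(tidy(g3)), 0)
})

test_that("hill climbing respects constraints, never decreases the score, and is seed-deterministic", {
  cfg <- recovery_config(master_seed = 31)
  gt <- make_ground_truth(cfg)
  tab <- forward_sample(gt, 400, seed = 8)
  ds <- bn_dataset(tab[-1], roles = c(age = "root", ethnicity = "root", nugent = "leaf"))
  g <- hill_climb(ds, alpha = 1, seed = 11)
  arcs <- tidy(g)
  expect_false(any(arcs$to %in% c("age", "ethnicity")))
  expect_false(any(arcs$from == "nugent"))
  tr <- attr(g, "trace")
  expect_true(all(diff(tr$score) > 0))
  expect_equal(attr(g, "score"), network_score(g, ds, alpha = 1))
  g2 <- hill_climb(ds, alpha = 1, seed = 11)
  expect_identical(tidy(g), tidy(g2))
})

test_that("learned skeleton recovers most true adjacencies on strong synthetic data", {
  f1s <- vapply(1:3, function(k) {
    cfg <- recovery_config(master_seed = 100 + k)
    gt <- make_ground_truth(cfg)
    tab <- forward_sample(gt, 2000, seed = 200 + k)
    ds <- bn_dataset(tab[-1], roles = c(age = "root", ethnicity = "root", nugent = "leaf"))
    g <- hill_climb(ds, alpha = 1, seed = 300 + k)
    skeleton_f1(g, gt$dag)$recall
  }, numeric(1))
  expect_gte(mean(f1s), 0.8)
})

test_that("alpha estimation stays in bounds, matches a grid oracle, and ignores row order", {
  d <- data.frame(x = factor(rep(c("a", "b"), each = 50)))
  est <- estimate_alpha_star(d, structural_constraints("x"), seed = 1)
  expect_gte(est$alpha, 1e-2)
  expect_lte(est$alpha, 1e2)
  # grid oracle at 1e-3 resolution on the fixed (single-node) structure
  grid <- exp(seq(log(1e-2), log(1e2), length.out = 20000))
  vals <- vapply(grid, function(a) local_bde_score("x", character(), d, a), numeric(1))
  a_star <- grid[which.max(vals)]
  expect_equal(est$alpha, a_star, tolerance = 1e-2)

  d2 <- rand_factor_df(60, c(2, 2, 3), seed = 9)
  perm <- d2[sample(nrow(d2)), , drop = FALSE]
  e1 <- estimate_alpha_star(d2, structural_constraints(names(d2)), seed = 4)
  e2 <- estimate_alpha_star(perm, structural_constraints(names(d2)), seed = 4)
  expect_equal(e1$alpha, e2$alpha, tolerance = 1e-6)
})
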