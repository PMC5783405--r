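test_that("Hellinger transform is the rowwise square-root of relative abundances", {
  h <- hellinger_transform(toy_counts(matrix(c(1, 1, 1, 1), nrow = 1)))
  expect_equal(as.numeric(h[1, -1]), rep(0.5, 4))
  h2 <- hellinger_transform(toy_counts(matrix(c(4, 0), nrow = 1)))
  expect_equal(as.numeric(h2[1, -1]), c(1, 0))
  set.seed(3)
  m <- matrix(rpois(50, 20), nrow = 5)
  h3 <- hellinger_transform(toy_counts(m))
  expect_equal(unname(rowSums(as.matrix(h3[, -1])^2)), rep(1, 5), tolerance = 1e-12)
  expect_error(
    hellinger_transform(toy_counts(matrix(c(0, 0, 1, 1), nrow = 2, byrow = TRUE))),
    "zero-total"
  )
})

test_that("distance matrices are symmetric Euclidean with zero diagonal", {
  set.seed(4)
  m <- matrix(rpois(40, 30), nrow = 4)
  d <- community_distances(hellinger_transform(toy_counts(m)))
  dm <- as.matrix(d)
  expect_equal(dm, t(dm))
  expect_equal(unname(diag(dm)), rep(0, 4))
  expect_true(all(dm >= 0))
})

test_that("NMDS recovers embeddable configurations and flags hard ones", {
  set.seed(5)
  pts <- matrix(rnorm(30), ncol = 2)
  d <- stats::dist(pts)
  ord <- nmds(d, k = 2, n_starts = 5, seed = 1)
  expect_lt(attr(ord, "stress"), 0.01)
  expect_equal(nrow(ord), 15)

  # a genuinely high-dimensional configuration cannot be represented in the
  # plane without distortion
  set.seed(55)
  hi <- matrix(rnorm(25 * 10), ncol = 10)
  ord_hi <- suppressWarnings(nmds(stats::dist(hi), k = 2, n_starts = 5, seed = 1))
  expect_gt(attr(ord_hi, "stress"), 0.05)

  # best-of-starts stress is non-increasing in the number of starts
  set.seed(6)
  m <- matrix(rpois(200, 25), nrow = 20)
  dd <- community_distances(hellinger_transform(toy_counts(m)))
  s1 <- attr(nmds(dd, n_starts = 1, seed = 9), "stress")
  s10 <- attr(nmds(dd, n_starts = 10, seed = 9), "stress")
  expect_lte(s10, s1 + 1e-9)
})

test_that("ANOSIM matches a hand-computed rank oracle and detects separation", {
  # 6 points, two groups; hand oracle from the rank formula
  dm <- matrix(0, 6, 6)
  coords <- c(0, 0.1, 0.2, 5, 5.1, 5.3)
  for (i in 1:6) for (j in 1:6) dm[i, j] <- abs(coords[i] - coords[j])
  d <- stats::as.dist(dm)
  grp <- factor(rep(c("g1", "g2"), each = 3))
  res <- anosim_test(d, grp, n_perm = 99, seed = 1)
  ranks <- rank(as.numeric(d))
  between <- outer(grp, grp, FUN = function(a, b) a != b)
  between <- between[lower.tri(between)]
  r_oracle <- (mean(ranks[between]) - mean(ranks[!between])) / (length(ranks) / 2)
  expect_equal(res$statistic, r_oracle, tolerance = 1e-12)
  # all between > all within forces the maximum R = 1; with only C(6,3) = 20
  # distinct label arrangements the permutation p cannot go below ~0.1
  expect_equal(res$statistic, 1)
  expect_lte(res$p, 0.2)

  # R near zero for labels unrelated to the distances
  set.seed(11)
  m <- matrix(rpois(600, 25), nrow = 30)
  dr <- community_distances(hellinger_transform(toy_counts(m)))
  rnd <- factor(rep(c("x", "y"), 15))
  res2 <- anosim_test(dr, rnd, n_perm = 199, seed = 2)
  expect_lt(abs(res2$statistic), 0.3)
  expect_error(anosim_test(dr, factor(rep("x", 30))), "groups")
})

test_that("PERMANOVA partitions variance correctly and matches a hand oracle", {
  # two-block response with a block-matching predictor: R2 = 1
  block <- rbind(
    matrix(rep(c(10, 0, 0, 0), each = 4), nrow = 4),
    matrix(rep(c(0, 0, 10, 10), each = 4), nrow = 4)
  )
  h <- toy_counts(block)  # raw block structure; zero within-block variance
  pred <- data.frame(g = factor(rep(c("a", "b"), each = 4)))
  res <- permanova(h, pred, n_perm = 99, seed = 1)
  expect_equal(attr(res, "full_r2"), 1, tolerance = 1e-6)

  # constant predictor is dropped with a warning and explains nothing
  expect_warning(
    res0 <- permanova(h, data.frame(g = factor(rep("a", 8)))),
    "constant"
  )
  expect_equal(attr(res0, "full_r2"), 0)

  # hand sums-of-squares oracle on 6 subjects
  set.seed(13)
  m <- matrix(rpois(36, 20), nrow = 6)
  hel <- hellinger_transform(toy_counts(m))
  g <- factor(c("a", "a", "b", "b", "c", "c"))
  res6 <- permanova(hel, data.frame(g = g), n_perm = 199, seed = 3)
  y <- scale(as.matrix(hel[, -1]), center = TRUE, scale = FALSE)
  fit <- stats::lm.fit(stats::model.matrix(~g), y)
  ss_fit <- sum((y - fit$residuals)^2)
  ss_res <- sum(fit$residuals^2)
  f_oracle <- (ss_fit / 2) / (ss_res / 3)
  r2_oracle <- ss_fit / (ss_fit + ss_res)
  expect_equal(res6$statistic[res6$term == "g"], f_oracle, tolerance = 1e-10)
  expect_equal(attr(res6, "full_r2"), r2_oracle, tolerance = 1e-10)
  expect_equal(res6$R2[res6$term == "g"], r2_oracle, tolerance = 1e-10)
  expect_gte(min(res6$p), 1 / (199 + 1))
})

test_that("forward stepwise selection prefers informative predictors and stops on noise", {
  set.seed(17)
  n <- 60
  g <- factor(rep(c("a", "b"), each = n / 2))
  m <- matrix(rpois(n * 8, 20), nrow = n)
  m[g == "b", 1:4] <- m[g == "b", 1:4] + 60
  hel <- hellinger_transform(toy_counts(m))
  cand <- data.frame(
    signal = g,
    noise1 = factor(sample(c("x", "y"), n, TRUE)),
    noise2 = factor(sample(c("x", "y"), n, TRUE))
  )
  path <- stepwise_select(hel, cand)
  expect_equal(attr(path, "selected")[1], "signal")
  expect_true(all(diff(path$aic) < 0))

  # a duplicate of a selected predictor is never added
  cand2 <- data.frame(signal = g, dup = g)
  path2 <- stepwise_select(hel, cand2)
  expect_equal(attr(path2, "selected"), "signal")

  # all-noise candidates at large n: empty or near-empty model
  set.seed(18)
  m2 <- matrix(rpois(200 * 6, 20), nrow = 200)
  hel2 <- hellinger_transform(toy_counts(m2))
  noise <- data.frame(
    n1 = factor(sample(c("x", "y"), 200, TRUE)),
    n2 = factor(sample(c("x", "y"), 200, TRUE)),
    n3 = factor(sample(c("x", "y"), 200, TRUE))
  )
  path3 <- stepwise_select(hel2, noise)
  expect_lte(length(attr(path3, "selected")), 1)
})
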