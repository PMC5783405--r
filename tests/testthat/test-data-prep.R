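test_that("depth filter keeps samples at or above the threshold, in order", {
  m <- matrix(c(900, 0, 600, 600, 700, 800), nrow = 3, byrow = TRUE)
  counts <- toy_counts(m)
  kept <- filter_samples(counts, min_total = 1000)
  expect_equal(kept$subject_id, c("s2", "s3"))

  expect_equal(filter_samples(counts, min_total = 100), counts)
  expect_error(filter_samples(counts, min_total = 1e6), "below threshold")
})

test_that("normalization scales every sample to the minimum depth and conserves proportions", {
  m <- matrix(c(600, 600, 500, 1000), nrow = 2, byrow = TRUE)
  norm <- normalize_to_min_depth(toy_counts(m))
  expect_equal(attr(norm, "norm_depth"), 1200)
  expect_equal(unname(rowSums(as.matrix(norm[, -1]))), c(1200, 1200))
  expect_equal(as.numeric(norm[2, -1]), c(500, 1000) * 0.8)
  # proportions before == after
  expect_equal(as.numeric(norm[2, -1]) / 1200, c(500, 1000) / 1500)

  one <- toy_counts(matrix(c(3, 7), nrow = 1))
  expect_equal(
    as.matrix(normalize_to_min_depth(one)[, -1]),
    as.matrix(one[, -1])
  )
  zero <- toy_counts(matrix(c(0, 0, 1, 2), nrow = 2, byrow = TRUE))
  expect_error(normalize_to_min_depth(zero), "zero-total")
})

test_that("rare-taxon filter drops taxa under the grand-total share", {
  m <- matrix(c(500, 5, 0.5, 500, 5, 0), nrow = 2, byrow = TRUE)
  out <- filter_rare_taxa(toy_counts(m), frac = 0.001)
  expect_equal(setdiff(colnames(m) %||% paste0("t", 1:3), names(out)[-1]), "t3")
  expect_equal(attr(out, "dropped_taxa"), "t3")

  single <- toy_counts(matrix(c(1, 2), ncol = 1))
  expect_equal(ncol(filter_rare_taxa(single, 0.5)), 2)
})

test_that("dichotomization marks any positive (possibly fractional) count present", {
  m <- matrix(c(0, 0.4, 0, 12), nrow = 2, byrow = TRUE)
  pa <- dichotomize(toy_counts(m))
  expect_equal(as.character(pa$t1), c("absent", "absent"))
  expect_equal(as.character(pa$t2), c("present", "present"))
  expect_equal(levels(pa$t1), c("absent", "present"))
})

test_that("survey filter applies missingness, complete-case and sparseness in order", {
  n <- 100
  survey <- tibble::tibble(
    subject_id = paste0("s", 1:n),
    q_missing = c(rep(NA, 6), rep("yes", n - 6)),          # 6% missing -> dropped
    q_ok = c(rep(NA, 4), rep(c("yes", "no"), 48)),         # 4% missing -> kept
    q_sparse = c(rep("yes", 4), rep("no", n - 4)),         # 4% minority -> dropped
    q_constant = rep("no", n),                             # single level -> dropped
    q_good = rep(c("a", "b", "c"), length.out = n)
  )
  out <- filter_survey(survey, max_missing_frac = 0.05, min_level_frac = 0.05)
  expect_setequal(names(out)[-1], c("q_ok", "q_good"))
  # complete case happened after dropping q_missing: only q_ok's 4 NA rows go
  expect_equal(nrow(out), 96)
  # post-filter guarantee: every retained level holds >= 5% of subjects
  for (v in names(out)[-1]) {
    expect_gte(min(table(out[[v]])) / nrow(out), 0.05)
  }
  # idempotence on already-filtered output
  again <- filter_survey(out, 0.05, 0.05)
  strip <- function(x) {
    attr(x, "survey_trace") <- NULL
    tibble::as_tibble(x)
  }
  expect_equal(strip(again), strip(out))
})

test_that("count-preparation chain is idempotent on its own output", {
  set.seed(42)
  m <- matrix(rpois(60, 40) * rbinom(60, 1, 0.7), nrow = 6)
  prep_chain <- function(x) {
    filter_rare_taxa(normalize_to_min_depth(filter_samples(x, 50)), 0.001)
  }
  once <- prep_chain(toy_counts(m))
  twice <- prep_chain(once)
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once))
})

test_that("fixed discretization schemes reproduce the printed bins", {
  expect_equal(
    as.character(discretize_variable("age", c(30, 31, 40, 41))),
    c("<=30", "31-40", "31-40", ">40")
  )
  expect_equal(
    as.character(discretize_variable("nugent", c(0, 3, 4, 6, 7, 10))),
    c("low", "low", "medium", "medium", "high", "high")
  )
  expect_equal(
    as.character(discretize_variable("menarche_age", c(10, 11, 15, 16))),
    c("<11", "11-15", "11-15", ">15")
  )
  expect_equal(
    as.character(discretize_variable("partners_60d", c(0, 1, 2, 3))),
    c("0", "1", ">1", ">1")
  )
  expect_equal(
    as.character(discretize_variable("vaginal_births", 0:3)),
    c("0", "1", "2", "3")
  )
  expect_equal(
    as.character(discretize_variable("period_length", 1:4)),
    c("1", "2", "3", "4")
  )
  expect_error(discretize_variable("nugent", 11), "admissible range")
  expect_error(discretize_variable("age", -1), "admissible range")
  expect_error(discretize_variable("bmi", 20), "no discretization scheme")
})

test_that("subject exclusions drop disqualifying and (optionally) missing answers", {
  survey <- tibble::tibble(
    subject_id = paste0("s", 1:5),
    health = c("yes", "no", NA, "yes", "yes"),
    other = letters[1:5]
  )
  out <- exclude_subjects(survey, "health", "no")
  expect_equal(out$subject_id, c("s1", "s4", "s5"))
  expect_false("health" %in% names(out))
  out2 <- exclude_subjects(survey, "health", "no", drop_missing = FALSE)
  expect_equal(out2$subject_id, c("s1", "s3", "s4", "s5"))
})

test_that("odor-style collapsing ORs binary questions into one", {
  survey <- tibble::tibble(
    subject_id = paste0("s", 1:4),
    odor_fishy = c("yes", "no", NA, "no"),
    odor_musty = c("no", "no", "yes", NA)
  )
  out <- collapse_any(survey, c("odor_fishy", "odor_musty"), "any_odor")
  expect_equal(out$any_odor, c("yes", "no", "yes", NA))
  expect_false(any(c("odor_fishy", "odor_musty") %in% names(out)))
})

test_that("assembly intersects subjects, assigns roles, and round-trips through CSV", {
  pres <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    t1 = factor(c("present", "absent", "present"), levels = c("absent", "present"))
  )
  survey <- tibble::tibble(subject_id = c("b", "c", "d"), q1 = c("no", "yes", "yes"))
  spec <- tibble::tibble(
    subject_id = c("a", "b", "c"),
    age = factor(c("<=30", "31-40", "<=30")),
    nugent = factor(c("low", "high", "low"))
  )
  ds <- assemble_dataset(pres, survey, spec)
  expect_equal(ds$subject_ids, c("b", "c"))
  expect_equal(unname(variable_roles(ds)[c("age", "nugent")]), c("root", "leaf"))

  disjoint <- tibble::tibble(subject_id = c("x", "y"), q1 = c("a", "b"))
  expect_error(assemble_dataset(pres, disjoint), "disjoint")

  tmp_data <- withr::local_tempfile(fileext = ".csv")
  tmp_meta <- withr::local_tempfile(fileext = ".csv")
  write_bn_dataset(ds, tmp_data, tmp_meta)
  back <- read_bn_dataset(tmp_data, tmp_meta)
  expect_equal(as_tibble(back), as_tibble(ds))
  expect_equal(back$meta$role, ds$meta$role)
})

test_that("the full preparation chain recovers the generator's discrete truth", {
  cfg <- sim_config(
    n_subjects = 160, n_taxa = 6, n_habits = 5, n_symptoms = 2,
    n_nuisance_taxa = 10, n_filler_missing = 3, n_filler_sparse = 2,
    n_low_depth = 2, missing_rate = 0.004, master_seed = 21
  )
  sim <- suppressWarnings(simulate_study(cfg))
  prep <- prepare_data(
    sim$counts, sim$survey,
    exclusions = list(
      list(question = "good_health", disqualifying = "no"),
      list(question = "ever_tss", disqualifying = "yes")
    ),
    discretize = c(
      age = "age", nugent = "nugent", menarche_age = "menarche_age",
      partners_60d = "partners_60d", vaginal_births = "vaginal_births",
      period_length = "period_length"
    ),
    categories = sim$categories
  )
  ds <- as_tibble(prep$dataset)
  truth <- sim$discrete
  common <- intersect(ds$subject_id, truth$subject_id)
  expect_gt(length(common), 50)
  for (v in setdiff(intersect(names(ds), names(truth)), "subject_id")) {
    expect_equal(
      as.character(ds[[v]][match(common, ds$subject_id)]),
      as.character(truth[[v]][match(common, truth$subject_id)]),
      info = v
    )
  }
  # retention trace is monotone non-increasing per column
  tr <- prep$trace
  expect_true(all(diff(tr$n_subjects) <= 0))
  expect_true(all(diff(tr$n_taxa) <= 0))
  expect_true(all(diff(tr$n_questions) <= 0))
})
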