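#' Sequencing-depth helpers for subject-by-taxon count tables
#'
#' A count table is a data frame whose first column is the subject ID and
#' whose remaining columns are non-negative (possibly fractional, after
#' normalization) counts, one per taxon.
#'
#' @param counts A count table.
#' @return `sample_depths()`: a tibble with `subject_id` and `depth` (row
#'   total).
#' @export
sample_depths <- function(counts) {
  validate_count_table(counts)
  tibble::tibble(
    subject_id = as.character(counts[[1]]),
    depth = rowSums(as.matrix(counts[, -1, drop = FALSE]))
  )
}

validate_count_table <- function(counts) {
  if (ncol(counts) < 2L) abort("count table needs a subject column plus taxa")
  first_col_ids(counts, "count table")
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("taxon columns must be numeric")
  if (anyNA(m) || any(m < 0)) abort("counts must be non-negative and complete")
  if (anyDuplicated(colnames(m))) abort("duplicate taxon names")
  invisible(counts)
}

#' Remove samples with too few total counts
#'
#' @param counts A count table (see [sample_depths()]).
#' @param min_total Minimum per-sample total; samples strictly below it are
#'   dropped. Default 1000.
#' @return The filtered count table, original row order preserved.
#' @export
filter_samples <- function(counts, min_total = 1000) {
  validate_count_table(counts)
  stopifnot(min_total > 0)
  keep <- sample_depths(counts)$depth >= min_total
  if (!any(keep)) abort("all samples below threshold")
  counts[keep, , drop = FALSE]
}

#' Normalize all samples to the lowest sequencing depth
#'
#' Deterministic proportional scaling: every row is multiplied by
#' (minimum row total / own row total), so all totals equal the minimum and
#' within-sample proportions are conserved exactly. Values may be fractional.
#'
#' @param counts A count table; all row totals must be positive.
#' @return The scaled count table, with the normalization constant attached
#'   as attribute `"norm_depth"`.
#' @export
normalize_to_min_depth <- function(counts) {
  validate_count_table(counts)
  depth <- sample_depths(counts)$depth
  if (any(depth <= 0)) abort("zero-total sample; cannot normalize")
  target <- min(depth)
  m <- as.matrix(counts[, -1, drop = FALSE]) * (target / depth)
  out <- dplyr::bind_cols(counts[, 1, drop = FALSE], tibble::as_tibble(m))
  attr(out, "norm_depth") <- target
  out
}

#' Remove taxa below a share of the total counts
#'
#' A taxon is dropped when its grand total is `< frac` times the grand total
#' over all taxa (computed on the table as given, typically after depth
#' normalization).
#'
#' @param counts A count table.
#' @param frac Minimum grand-total share, in (0, 1). Default 0.001 (0.1%).
#' @return The count table restricted to retained taxa; dropped taxon names
#'   are attached as attribute `"dropped_taxa"`.
#' @export
filter_rare_taxa <- function(counts, frac = 0.001) {
  validate_count_table(counts)
  stopifnot(frac > 0, frac < 1)
  m <- as.matrix(counts[, -1, drop = FALSE])
  totals <- colSums(m)
  keep <- totals >= frac * sum(totals)
  out <- dplyr::bind_cols(
    counts[, 1, drop = FALSE],
    tibble::as_tibble(m[, keep, drop = FALSE])
  )
  attr(out, "dropped_taxa") <- colnames(m)[!keep]
  out
}

#' Convert counts to presence/absence
#'
#' Presence is strictly positive count (any fractional value after
#' normalization counts as present).
#'
#' @param counts A count table.
#' @return A tibble with `subject_id` plus one factor column per taxon with
#'   levels `absent`, `present`, aligned with the input.
#' @export
dichotomize <- function(counts) {
  validate_count_table(counts)
  m <- as.matrix(counts[, -1, drop = FALSE])
  pa <- tibble::as_tibble(as.data.frame(lapply(
    as.data.frame(m),
    function(x) factor(ifelse(x > 0, "present", "absent"), levels = c("absent", "present"))
  ), check.names = FALSE))
  dplyr::bind_cols(
    tibble::tibble(subject_id = as.character(counts[[1]])),
    pa
  )
}

#' Drop subjects by a disqualifying answer to a screening question
#'
#' Generic subject-exclusion rule (e.g. overall-health or toxic-shock
#' screening): subjects whose answer is in `disqualifying`, or missing when
#' `drop_missing = TRUE`, are removed; the question column itself is dropped.
#'
#' @param survey Survey table (first column subject ID, `NA` = missing).
#' @param question Question column name.
#' @param disqualifying Character vector of disqualifying answers.
#' @param drop_missing Also exclude subjects who did not answer. Default TRUE.
#' @return The survey without excluded subjects and without the question.
#' @export
exclude_subjects <- function(survey, question, disqualifying, drop_missing = TRUE) {
  if (!question %in% names(survey)) abort(sprintf("unknown question '%s'", question))
  ans <- as.character(survey[[question]])
  out <- ans %in% disqualifying | (drop_missing & is.na(ans))
  survey <- survey[!out, setdiff(names(survey), question), drop = FALSE]
  survey
}

#' Collapse several binary questions into a single any-of indicator
#'
#' Logical OR over yes/no questions (e.g. the four specific vaginal-odor
#' questions into one "any odor" variable). Missing any component makes the
#' collapsed answer missing unless another component is already `yes`.
#'
#' @param survey Survey table.
#' @param questions Columns to collapse (answers `yes`/`no`).
#' @param name Name of the new collapsed column.
#' @param yes Value counting as a positive answer. Default `"yes"`.
#' @return The survey with the component questions replaced by the collapsed
#'   column.
#' @export
collapse_any <- function(survey, questions, name, yes = "yes") {
  missing_q <- setdiff(questions, names(survey))
  if (length(missing_q)) abort(sprintf("unknown question '%s'", missing_q[1]))
  block <- as.matrix(as.data.frame(lapply(survey[questions], as.character)))
  any_yes <- apply(block, 1, function(r) any(r == yes, na.rm = TRUE))
  any_na <- apply(block, 1, function(r) anyNA(r))
  val <- ifelse(any_yes, yes, ifelse(any_na, NA_character_, "no"))
  survey <- survey[, setdiff(names(survey), questions), drop = FALSE]
  survey[[name]] <- val
  survey
}

#' Filter survey questions by missingness and level sparseness
#'
#' Applied in this fixed order: (1) drop questions whose missing fraction
#' exceeds `max_missing_frac`; (2) drop subjects with any remaining missing
#' answer (complete case); (3) drop questions with any outcome level held by
#' fewer than `min_level_frac` of the remaining subjects.
#'
#' @param survey Survey table (first column subject ID, `NA` = missing).
#' @param max_missing_frac Questions with missing fraction strictly above
#'   this are dropped. Default 0.05.
#' @param min_level_frac Questions with any level strictly below this share
#'   of remaining subjects are dropped. Default 0.05.
#' @return The filtered survey; attribute `"survey_trace"` records question
#'   and subject counts after each step.
#' @export
filter_survey <- function(survey, max_missing_frac = 0.05, min_level_frac = 0.05) {
  stopifnot(
    max_missing_frac > 0, max_missing_frac < 1,
    min_level_frac > 0, min_level_frac < 1
  )
  first_col_ids(survey, "survey table")
  ids <- survey[, 1, drop = FALSE]
  q <- survey[, -1, drop = FALSE]

  miss_frac <- vapply(q, function(x) mean(is.na(x)), numeric(1))
  q <- q[, miss_frac <= max_missing_frac, drop = FALSE]
  n_after_missing <- ncol(q)

  complete <- stats::complete.cases(q)
  q <- q[complete, , drop = FALSE]
  ids <- ids[complete, , drop = FALSE]
  if (nrow(q) == 0L) abort("no complete-case subjects remain")

  # a question with a single observed level is maximally sparse (its other
  # levels hold 0% of subjects) and is dropped
  min_share <- vapply(q, function(x) {
    tab <- table(x)
    if (length(tab) < 2) 0 else min(tab) / nrow(q)
  }, numeric(1))
  q <- q[, min_share >= min_level_frac, drop = FALSE]
  if (ncol(q) == 0L) abort("all questions filtered out; over-filtering")

  out <- dplyr::bind_cols(tibble::as_tibble(ids), tibble::as_tibble(q))
  attr(out, "survey_trace") <- tibble::tibble(
    step = c("missingness_filter", "complete_case", "sparseness_filter"),
    n_questions = c(n_after_missing, n_after_missing, ncol(q)),
    n_subjects = c(nrow(survey), nrow(q), nrow(q))
  )
  out
}

# Fixed discretization schemes, with the printed closed bin bounds.
discretization_schemes <- list(
  age = list(
    breaks = c(-Inf, 30, 40, Inf),
    labels = c("<=30", "31-40", ">40"),
    range = c(0, 120)
  ),
  nugent = list(
    breaks = c(-Inf, 3, 6, Inf),
    labels = c("low", "medium", "high"),
    range = c(0, 10)
  ),
  menarche_age = list(
    breaks = c(-Inf, 10, 15, Inf),
    labels = c("<11", "11-15", ">15"),
    range = c(0, 60)
  ),
  partners_60d = list(
    breaks = c(-Inf, 0, 1, Inf),
    labels = c("0", "1", ">1"),
    range = c(0, Inf)
  ),
  vaginal_births = list(
    breaks = c(-Inf, 0, 1, 2, Inf),
    labels = c("0", "1", "2", "3"),
    range = c(0, 3)
  ),
  period_length = list(
    breaks = c(-Inf, 1, 2, 3, Inf),
    labels = c("1", "2", "3", "4"),
    range = c(1, 4)
  )
)

#' Discretize a numeric study variable with its fixed bins
#'
#' Schemes: `age` (<=30, 31-40, >40 years), `nugent` (low 0-3, medium 4-6,
#' high 7-10), `menarche_age` (<11, 11-15, >15 years), `partners_60d`
#' (0, 1, >1), `vaginal_births` (0-3, four levels), `period_length`
#' (1-4 days, four levels).
#'
#' @param name Scheme name (one of the above).
#' @param values Numeric vector.
#' @return Factor with the scheme's labels.
#' @export
discretize_variable <- function(name, values) {
  scheme <- discretization_schemes[[name]]
  if (is.null(scheme)) {
    abort(sprintf(
      "no discretization scheme '%s' (have: %s)",
      name, paste(names(discretization_schemes), collapse = ", ")
    ))
  }
  if (anyNA(values)) abort("missing values cannot be discretized")
  out_of_range <- values < scheme$range[1] | values > scheme$range[2]
  if (any(out_of_range)) {
    abort(sprintf(
      "%s value %s outside admissible range [%s, %s]",
      name, format(values[out_of_range][1]), scheme$range[1], scheme$range[2]
    ))
  }
  cut(values, breaks = scheme$breaks, labels = scheme$labels, right = TRUE)
}

#' Column-bind prepared blocks into a discrete dataset
#'
#' Takes any number of prepared blocks (presence/absence taxa, filtered
#' survey questions, discretized demographics and diagnostics), each a data
#' frame whose first column is `subject_id`. The subject intersection is
#' taken, remaining incomplete rows are dropped, and roles/categories are
#' attached.
#'
#' @param ... Data frames keyed by a `subject_id` first column.
#' @param roles Named character vector (`root`/`leaf`) for structural roles;
#'   default declares `age` and `ethnicity` roots and `nugent` leaf when
#'   present.
#' @param categories Named character vector over the five-level scheme.
#' @return A [bn_dataset()].
#' @export
assemble_dataset <- function(..., roles = NULL, categories = NULL) {
  blocks <- list(...)
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  blocks <- blocks[vapply(blocks, function(b) ncol(b) > 1L, logical(1))]
  if (!length(blocks)) abort("no non-empty blocks to assemble")
  blocks <- lapply(blocks, function(b) {
    names(b)[1] <- "subject_id"
    b$subject_id <- as.character(b$subject_id)
    tibble::as_tibble(b)
  })
  merged <- purrr::reduce(blocks, function(a, b) dplyr::inner_join(a, b, by = "subject_id"))
  if (nrow(merged) == 0L) abort("disjoint subject sets; misaligned inputs")
  merged <- merged[stats::complete.cases(merged), , drop = FALSE]
  ids <- merged$subject_id
  merged$subject_id <- NULL
  if (is.null(roles)) {
    roles <- c(age = "root", ethnicity = "root", nugent = "leaf")
    roles <- roles[names(roles) %in% names(merged)]
  }
  if (!is.null(categories)) categories <- categories[names(categories) %in% names(merged)]
  bn_dataset(merged, subject_ids = ids, categories = categories, roles = roles)
}

#' Run the full data-preparation chain
#'
#' Order of operations: sample-depth filter on the counts; subject
#' exclusions from screening questions; depth normalization; rare-taxon
#' filter; dichotomization; survey question-missingness filter; survey
#' complete-case; survey level-sparseness filter; discretization of numeric
#' variables; assembly into a complete-case discrete dataset.
#'
#' @param counts Raw count table (subject ID first column, taxa columns).
#' @param survey Raw survey table (subject ID first column; `NA` missing).
#' @param special_vars Columns of `survey` (e.g. `age`, `ethnicity`, `ph`,
#'   `nugent`) that bypass the question-level filters but still require
#'   complete cases.
#' @param min_depth,rare_frac,max_missing,min_level The four filter
#'   parameters (defaults 1000, 0.001, 0.05, 0.05).
#' @param exclusions List of subject-exclusion rules, each a list with
#'   `question`, `disqualifying`, and optional `drop_missing`.
#' @param collapse Named list: new column name -> character vector of binary
#'   questions to OR together before filtering.
#' @param drop_questions Questions removed up front (study-design fields).
#' @param discretize Named character vector: column name -> scheme name from
#'   [discretize_variable()].
#' @param roles,categories Passed to [assemble_dataset()].
#' @return A list with `dataset` (a [bn_dataset()]) and `trace` (tibble of
#'   per-stage subject/taxon/question retention counts).
#' @export
prepare_data <- function(counts, survey,
                         special_vars = intersect(c("age", "ethnicity", "ph", "nugent"), names(survey)),
                         min_depth = 1000, rare_frac = 0.001,
                         max_missing = 0.05, min_level = 0.05,
                         exclusions = list(), collapse = list(),
                         drop_questions = character(),
                         discretize = c(age = "age", nugent = "nugent"),
                         roles = NULL, categories = NULL) {
  trace <- list()
  note <- function(stage, subjects, taxa, questions) {
    trace[[length(trace) + 1]] <<- tibble::tibble(
      stage = stage, n_subjects = subjects, n_taxa = taxa, n_questions = questions
    )
  }
  n_q <- function(s) length(setdiff(names(s)[-1], special_vars))
  note("input", nrow(counts), ncol(counts) - 1L, n_q(survey))

  counts <- filter_samples(counts, min_total = min_depth)
  note("depth_filter", nrow(counts), ncol(counts) - 1L, n_q(survey))

  if (length(drop_questions)) {
    survey <- survey[, setdiff(names(survey), drop_questions), drop = FALSE]
  }
  for (nm in names(collapse)) {
    survey <- collapse_any(survey, collapse[[nm]], nm)
  }
  for (rule in exclusions) {
    survey <- exclude_subjects(
      survey, rule$question, rule$disqualifying,
      drop_missing = rule$drop_missing %||% TRUE
    )
  }
  common <- intersect(as.character(counts[[1]]), as.character(survey[[1]]))
  counts <- counts[as.character(counts[[1]]) %in% common, , drop = FALSE]
  survey <- survey[as.character(survey[[1]]) %in% common, , drop = FALSE]
  note("subject_exclusions", length(common), ncol(counts) - 1L, n_q(survey))

  counts <- normalize_to_min_depth(counts)
  norm_depth <- attr(counts, "norm_depth")
  counts <- filter_rare_taxa(counts, frac = rare_frac)
  note("rare_taxon_filter", nrow(counts), ncol(counts) - 1L, n_q(survey))

  presence <- dichotomize(counts)

  specials <- survey[, c(names(survey)[1], intersect(special_vars, names(survey))), drop = FALSE]
  questions <- survey[, setdiff(names(survey), special_vars), drop = FALSE]
  questions <- filter_survey(questions, max_missing_frac = max_missing, min_level_frac = min_level)
  strace <- attr(questions, "survey_trace")
  note("question_missingness", strace$n_subjects[2], ncol(counts) - 1L, strace$n_questions[1])
  note("question_sparseness", strace$n_subjects[3], ncol(counts) - 1L, strace$n_questions[3])

  specials <- specials[stats::complete.cases(specials), , drop = FALSE]
  for (nm in names(discretize)) {
    target <- if (nm %in% names(specials)) "specials" else if (nm %in% names(questions)) "questions" else NA
    if (is.na(target)) next
    if (target == "specials") {
      specials[[nm]] <- discretize_variable(discretize[[nm]], as.numeric(specials[[nm]]))
    } else {
      questions[[nm]] <- discretize_variable(discretize[[nm]], as.numeric(questions[[nm]]))
    }
  }

  dataset <- assemble_dataset(
    presence, questions, specials,
    roles = roles, categories = categories
  )
  note("assembled", nrow(dataset$data), ncol(counts) - 1L, ncol(questions) - 1L)

  trace <- dplyr::bind_rows(trace)
  list(dataset = dataset, trace = trace, norm_depth = norm_depth)
}
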