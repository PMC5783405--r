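# End-to-end orchestration: prepare -> alpha -> consensus -> fit -> metrics
# -> queries -> ordination, with every intermediate artifact written to a
# run directory together with a manifest of input hashes and seeds.

#' Validate a pipeline run configuration
#'
#' @param config Named list. Recognised entries: `counts`, `survey` (data
#'   frames or CSV paths), `out_dir`; prep parameters (`min_depth`,
#'   `rare_frac`, `max_missing`, `min_level`, `exclusions`, `collapse`,
#'   `drop_questions`, `discretize`, `special_vars`, `roles`,
#'   `categories`); learning parameters (`alpha` — a number or `"auto"`,
#'   `n_seeds`, `n_boot`, `threshold`, `master_seed`); analysis parameters
#'   (`resolution`, `queries`, `n_perm`, `n_starts`, `anosim_vars`).
#' @return The config with defaults filled in; errors on unknown or invalid
#'   entries.
#' @export
validate_run_config <- function(config) {
  defaults <- list(
    counts = NULL, survey = NULL, out_dir = NULL,
    min_depth = 1000, rare_frac = 0.001, max_missing = 0.05, min_level = 0.05,
    exclusions = list(), collapse = list(), drop_questions = character(),
    discretize = c(age = "age", nugent = "nugent"),
    special_vars = NULL, roles = NULL, categories = NULL,
    alpha = "auto", n_seeds = 10, n_boot = 10, threshold = 0.30,
    master_seed = 1, resolution = 1.0, queries = list(),
    n_perm = 999, n_starts = 20, anosim_vars = character()
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) abort(sprintf("unknown config entry '%s'", unknown[1]))
  # plain overwrite (modifyList would merge nested lists element-wise and
  # drop unnamed entries such as exclusion rules or query specs)
  merged <- defaults
  for (nm in names(config)) merged[[nm]] <- config[[nm]]
  config <- merged
  if (is.null(config$counts) || is.null(config$survey)) {
    abort("config needs 'counts' and 'survey'")
  }
  if (is.null(config$out_dir)) abort("config needs 'out_dir'")
  if (!(identical(config$alpha, "auto") || (is.numeric(config$alpha) && config$alpha > 0))) {
    abort("alpha must be 'auto' or a positive number")
  }
  stopifnot(
    config$threshold > 0, config$threshold <= 1,
    config$n_seeds >= 1, config$n_boot >= 1, config$n_perm >= 1
  )
  config
}

read_table_arg <- function(x, what) {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(sprintf("%s file not found: %s", what, x))
    out <- tryCatch(
      utils::read.csv(x, check.names = FALSE),
      error = function(e) abort(sprintf("failed to read %s file '%s': %s", what, x, conditionMessage(e)))
    )
    tibble::as_tibble(out)
  } else {
    tibble::as_tibble(x)
  }
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data preparation, imaginary-sample-size estimation
#' (unless a fixed `alpha` is given), the bootstrap ensemble and consensus
#' network, CPT fitting, network metrics and communities, any configured
#' conditional-probability queries, and the ordination/PERMANOVA companion
#' analyses. Every stage's output is written under `out_dir` as CSV, plus a
#' JSON manifest with input hashes, seeds and session versions. Re-running
#' with an identical config and inputs reproduces identical artifacts.
#'
#' @param config A list accepted by [validate_run_config()].
#' @return Invisibly, a list with the in-memory stage results (`prepared`,
#'   `alpha`, `strengths`, `consensus`, `fit`, `metrics`, `report`,
#'   `queries`, `ordination`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  counts <- stage("prepare", read_table_arg(config$counts, "counts"))
  survey <- stage("prepare", read_table_arg(config$survey, "survey"))
  input_hash <- list(
    counts = digest_table(counts),
    survey = digest_table(survey)
  )

  prepared <- stage("prepare", prepare_data(
    counts, survey,
    special_vars = config$special_vars %||%
      intersect(c("age", "ethnicity", "ph", "nugent"), names(survey)),
    min_depth = config$min_depth, rare_frac = config$rare_frac,
    max_missing = config$max_missing, min_level = config$min_level,
    exclusions = config$exclusions, collapse = config$collapse,
    drop_questions = config$drop_questions, discretize = config$discretize,
    roles = config$roles, categories = config$categories
  ))
  dataset <- prepared$dataset
  write_bn_dataset(dataset, out("dataset.csv"), out("dataset_meta.csv"))
  utils::write.csv(prepared$trace, out("filter_trace.csv"), row.names = FALSE)

  alpha_info <- stage("alpha", {
    if (identical(config$alpha, "auto")) {
      estimate_alpha_star(dataset, seed = derive_seeds(config$master_seed, 2)[2])
    } else {
      list(alpha = config$alpha, converged = NA)
    }
  })

  strengths <- stage("consensus", bootstrap_ensemble(
    dataset,
    alpha = alpha_info$alpha,
    n_seeds = config$n_seeds, n_boot = config$n_boot,
    master_seed = config$master_seed
  ))
  write_arc_strength(strengths, out("arc_strengths.csv"))
  consensus <- stage("consensus", averaged_network(strengths, threshold = config$threshold))
  write_arcs(consensus, out("consensus_arcs.csv"))

  fit <- stage("fit", suppressWarnings(fit_mle(consensus, dataset)))
  utils::write.csv(tidy(fit), out("cpts.csv"), row.names = FALSE)

  metrics <- stage("metrics", metrics_report(
    consensus,
    categories = variable_categories(dataset),
    resolution = config$resolution,
    seed = derive_seeds(config$master_seed, 3)[3]
  ))
  utils::write.csv(tidy(metrics), out("metrics.csv"), row.names = FALSE)
  utils::write.csv(glance(metrics), out("graph_summary.csv"), row.names = FALSE)

  report <- stage("report", descriptive_report(dataset, prepared$trace))
  utils::write.csv(report, out("descriptive_report.csv"), row.names = FALSE)

  query_results <- stage("queries", {
    if (length(config$queries)) conditional_probability_report(fit, config$queries) else NULL
  })
  if (!is.null(query_results)) {
    utils::write.csv(query_results, out("queries.csv"), row.names = FALSE)
  }

  ordination <- stage("ordination", {
    seeds <- derive_seeds(config$master_seed, 6)
    prepared_counts <- normalize_to_min_depth(filter_samples(counts, config$min_depth))
    prepared_counts <- filter_rare_taxa(prepared_counts, config$rare_frac)
    keep <- as.character(prepared_counts[[1]]) %in% dataset$subject_ids
    prepared_counts <- prepared_counts[keep, , drop = FALSE]
    hel <- hellinger_transform(prepared_counts)
    d <- community_distances(hel)
    ord <- nmds(d, k = 2, n_starts = config$n_starts, seed = seeds[4])
    meta <- as_tibble(dataset)[match(as.character(hel[[1]]), dataset$subject_ids), , drop = FALSE]
    non_taxa <- setdiff(names(meta), c("subject_id", grep("present", names(meta), value = TRUE)))
    anosim_tabs <- purrr::map_dfr(config$anosim_vars, function(v) {
      res <- anosim_test(d, meta[[v]], n_perm = config$n_perm, seed = seeds[5])
      dplyr::mutate(tibble::as_tibble(res), term = v)
    })
    list(ordination = ord, anosim = anosim_tabs, transformed = hel, meta = meta)
  })
  utils::write.csv(tibble::as_tibble(ordination$ordination), out("nmds_coords.csv"), row.names = FALSE)
  if (nrow(ordination$anosim %||% tibble::tibble())) {
    utils::write.csv(ordination$anosim, out("anosim.csv"), row.names = FALSE)
  }

  manifest <- list(
    input_hash = input_hash,
    master_seed = config$master_seed,
    alpha = alpha_info$alpha,
    n_seeds = config$n_seeds,
    n_boot = config$n_boot,
    threshold = config$threshold,
    n_networks = attr(strengths, "n_networks"),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("bnconsensus"))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    prepared = prepared, alpha = alpha_info, strengths = strengths,
    consensus = consensus, fit = fit, metrics = metrics, report = report,
    queries = query_results, ordination = ordination, out_dir = config$out_dir
  ))
}

digest_table <- function(df) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' Descriptive statistics of a discrete dataset
#'
#' Tabulates every variable's level counts and percentages; the per-stage
#' retention trace (if given) is attached as attribute `"trace"`.
#'
#' @param dataset A [bn_dataset()].
#' @param filter_trace Optional retention trace from [prepare_data()].
#' @return Tibble with `variable`, `level`, `n`, `percent`.
#' @export
descriptive_report <- function(dataset, filter_trace = NULL) {
  stopifnot(inherits(dataset, "bn_dataset"))
  n_total <- nrow(dataset$data)
  out <- purrr::map_dfr(names(dataset$data), function(v) {
    tab <- table(dataset$data[[v]])
    tibble::tibble(
      variable = v,
      level = names(tab),
      n = as.integer(tab),
      percent = round(100 * as.integer(tab) / n_total, 1)
    )
  })
  attr(out, "trace") <- filter_trace
  out
}

#' Pearson chi-square test of independence between two discrete variables
#'
#' Computed on the contingency table without continuity correction, with
#' `df = (r - 1)(c - 1)` and an upper-tail p-value.
#'
#' @param dataset A [bn_dataset()] or data frame of factors.
#' @param var_a,var_b Variable names.
#' @return Tibble with `statistic`, `df`, `p`.
#' @export
chi_square_independence <- function(dataset, var_a, var_b) {
  df <- if (inherits(dataset, "bn_dataset")) dataset$data else tibble::as_tibble(dataset)
  for (v in c(var_a, var_b)) {
    if (!v %in% names(df)) abort(sprintf("unknown variable '%s'", v))
    if (length(unique(df[[v]])) < 2) abort(sprintf("'%s' has a single level", v))
  }
  tab <- table(df[[var_a]], df[[var_b]])
  fit <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p = fit$p.value
  )
}
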