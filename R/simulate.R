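# Layered synthetic-data generator. Emulates the joint structure the
# analysis assumes: two demographic roots (age, ethnicity), binary
# taxon-presence nodes and habit/symptom survey nodes in intermediate
# layers, a three-level diagnostic leaf (nugent), a zero-inflated
# overdispersed count layer with variable per-sample depth, and MCAR
# missingness in the survey block.

#' Configuration for the synthetic-study generator
#'
#' Defaults emulate the study conditions: 394 subjects of which a handful
#' have sequencing depth below 1000; 27 informative taxa plus 220 rare
#' nuisance taxa (247 total); 29 informative survey questions plus
#' high-missingness and sparse filler questions; log-normal depth around a
#' median of roughly 2150; health/toxic-shock screening questions; and MCAR
#' cell missingness near 0.5% (the rate implied by losing about a quarter of
#' subjects to complete-case filtering over ~56 retained questions).
#'
#' @param n_subjects Number of subjects.
#' @param n_taxa Informative (network) taxa.
#' @param n_habits,n_symptoms Binary habit and symptom survey nodes. Four of
#'   the habit slots are rendered as numeric variables (`menarche_age`,
#'   `partners_60d`, `vaginal_births`, `period_length`) so the fixed
#'   discretization schemes are exercised.
#' @param n_nuisance_taxa Rare taxa guaranteed below the 0.1% abundance
#'   filter.
#' @param n_filler_missing,n_filler_sparse Junk questions exceeding the
#'   missingness threshold / failing the 5% level-sparseness rule.
#' @param effect_strength In (0, 1]; larger means stronger parent effects
#'   (CPT rows are Dirichlet draws with concentration
#'   `(1 - effect_strength) / effect_strength + 0.02`, so values near 1 give
#'   near-deterministic tables).
#' @param level_floor In `[0, 1)`: CPT rows are mixed with the uniform
#'   distribution by this weight, bounding every level probability away from
#'   0 (keeps survey levels above the sparseness filter in the study
#'   emulation).
#' @param edge_density Probability of each admissible forward arc.
#' @param max_parents Cap on parents per node (keeps CPTs estimable).
#' @param mean_depth,depth_spread Log-normal depth: `meanlog =
#'   log(mean_depth)`, `sdlog = depth_spread`.
#' @param n_low_depth Subjects forced below the 1000-count depth filter.
#' @param count_dispersion Negative-binomial size parameter of present-taxon
#'   reads.
#' @param missing_rate MCAR cell missing probability in survey questions.
#' @param master_seed Integer seed; everything downstream derives from it.
#' @return A list of class `bn_sim_config`.
#' @export
sim_config <- function(n_subjects = 394,
                       n_taxa = 27,
                       n_habits = 21,
                       n_symptoms = 8,
                       n_nuisance_taxa = 220,
                       n_filler_missing = 207,
                       n_filler_sparse = 27,
                       effect_strength = 0.6,
                       level_floor = 0.2,
                       edge_density = 0.08,
                       max_parents = 3,
                       mean_depth = 2150,
                       depth_spread = 0.35,
                       n_low_depth = 5,
                       count_dispersion = 1.5,
                       missing_rate = 0.005,
                       master_seed = 1) {
  stopifnot(
    n_subjects >= 1, n_taxa >= 1, n_habits >= 4, n_symptoms >= 1,
    effect_strength > 0, effect_strength <= 1,
    level_floor >= 0, level_floor < 1,
    edge_density >= 0, edge_density <= 1,
    mean_depth > 0, depth_spread >= 0, count_dispersion > 0,
    missing_rate >= 0, missing_rate < 1
  )
  structure(as.list(environment()), class = "bn_sim_config")
}

sim_node_layout <- function(config) {
  taxa <- sprintf("taxon%02d", seq_len(config$n_taxa))
  numeric_habits <- c("menarche_age", "partners_60d", "vaginal_births", "period_length")
  habits <- c(numeric_habits, sprintf("habit%02d", seq_len(config$n_habits - 4)))
  symptoms <- sprintf("symptom%02d", seq_len(config$n_symptoms))
  nodes <- c("age", "ethnicity", habits, taxa, symptoms, "ph", "nugent")
  layer <- c(
    setNames(rep(1L, 2), c("age", "ethnicity")),
    setNames(rep(2L, length(habits)), habits),
    setNames(rep(2L, length(taxa)), taxa),
    setNames(rep(3L, length(symptoms) + 1L), c(symptoms, "ph")),
    nugent = 4L
  )
  category <- c(
    age = "demographic", ethnicity = "demographic",
    menarche_age = "demographic", vaginal_births = "demographic",
    setNames(rep("sexual/sanitary habit", length(habits) - 2),
             setdiff(habits, c("menarche_age", "vaginal_births"))),
    setNames(rep("microbiome", length(taxa)), taxa),
    setNames(rep("BV risk symptom", length(symptoms) + 1), c(symptoms, "ph")),
    nugent = "BV diagnostic criteria"
  )
  nlev <- c(
    age = 3L, ethnicity = 4L,
    menarche_age = 3L, partners_60d = 3L, vaginal_births = 4L, period_length = 4L,
    setNames(rep(2L, length(habits) - 4), setdiff(habits, numeric_habits)),
    setNames(rep(2L, length(taxa)), taxa),
    setNames(rep(2L, length(symptoms)), symptoms),
    ph = 2L, nugent = 3L
  )
  levels <- list(
    age = c("<=30", "31-40", ">40"),
    ethnicity = c("hispanic", "asian", "white", "black"),
    menarche_age = c("<11", "11-15", ">15"),
    partners_60d = c("0", "1", ">1"),
    vaginal_births = c("0", "1", "2", "3"),
    period_length = c("1", "2", "3", "4"),
    ph = c("<=4.5", ">4.5"),
    nugent = c("low", "medium", "high")
  )
  for (v in nodes) {
    if (is.null(levels[[v]])) {
      levels[[v]] <- if (v %in% taxa) c("absent", "present") else c("no", "yes")
    }
  }
  list(
    nodes = nodes, layer = layer[nodes], category = category[nodes],
    nlev = nlev[nodes], levels = levels[nodes],
    taxa = taxa, habits = habits, symptoms = symptoms,
    numeric_habits = numeric_habits
  )
}

# Root marginals matching the printed study demographics.
sim_root_marginals <- function() {
  list(
    age = c(0.495, 0.417, 0.088),
    ethnicity = c(0.204, 0.249, 0.274, 0.274)
  )
}

dirichlet_row <- function(r, conc) {
  g <- stats::rgamma(r, shape = conc)
  if (sum(g) <= 0) g <- rep(1, r)
  g / sum(g)
}

#' Sample a layered ground-truth network and its parameters
#'
#' Draws a DAG whose arcs only run forward across layers (roots: age and
#' ethnicity; habits and taxa; symptoms and pH; leaf: nugent), with each
#' admissible arc included with probability `edge_density` and parents
#' capped at `max_parents`. CPT rows are Dirichlet draws whose
#' concentration is set by `effect_strength`, mixed with the uniform by
#' `level_floor`; root marginals use the study demographics.
#'
#' @param config A [sim_config()].
#' @return An object of class `bn_ground_truth`: list with `dag`, `cpts`
#'   (arrays as in [fit_mle()]), `levels`, `layer`, `category`, and the
#'   `config`.
#' @export
make_ground_truth <- function(config) {
  layout <- sim_node_layout(config)
  conc <- (1 - config$effect_strength) / config$effect_strength + 0.02
  with_seed(derive_seeds(config$master_seed, 3)[1], {
    arcs <- list()
    pa_count <- setNames(integer(length(layout$nodes)), layout$nodes)
    for (child in layout$nodes) {
      lc <- layout$layer[child]
      if (lc == 1L) next
      cand <- layout$nodes[layout$layer < lc]
      pick <- cand[runif(length(cand)) < config$edge_density]
      if (length(pick) > config$max_parents) {
        pick <- sample(pick, config$max_parents)
      }
      if (length(pick)) {
        arcs[[child]] <- tibble::tibble(from = pick, to = child)
      }
    }
    dag <- bn_dag(layout$nodes, dplyr::bind_rows(arcs))

    roots <- sim_root_marginals()
    cpts <- lapply(layout$nodes, function(v) {
      r <- layout$nlev[[v]]
      pa <- parents(dag, v)
      if (v %in% names(roots)) {
        return(array(roots[[v]], dim = r, dimnames = setNames(list(layout$levels[[v]]), v)))
      }
      q_dims <- layout$nlev[pa]
      q <- prod(q_dims)
      rows <- vapply(seq_len(max(q, 1)), function(j) {
        p <- dirichlet_row(r, conc)
        (1 - config$level_floor) * p + config$level_floor / r
      }, numeric(r))
      dn <- c(setNames(list(layout$levels[[v]]), v), layout$levels[pa])
      array(rows, dim = c(r, q_dims), dimnames = dn)
    })
    names(cpts) <- layout$nodes
  })
  structure(
    list(
      dag = dag, cpts = cpts, levels = layout$levels,
      layer = layout$layer, category = layout$category,
      layout = layout, config = config
    ),
    class = "bn_ground_truth"
  )
}

#' @export
print.bn_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<bn_ground_truth> %d nodes (%d taxa), %d true arcs\n",
    length(x$dag$nodes), length(x$layout$taxa), nrow(x$dag$arcs)
  ))
  invisible(x)
}

# Fitted-network view of a ground truth, so the sampling machinery and
# queries can run against the true parameters.
as_bn_fit <- function(gt) {
  structure(
    list(dag = gt$dag, levels = gt$levels, cpts = gt$cpts, smoothing = 0,
         unobserved_configs = list()),
    class = "bn_fit"
  )
}

#' Ancestral (forward) sampling from a ground truth
#'
#' @param gt A [make_ground_truth()] object.
#' @param n Number of subjects.
#' @param seed Integer seed.
#' @return A tibble of factors, one column per node, with a
#'   `subject_id` column prepended.
#' @export
forward_sample <- function(gt, n, seed = 1) {
  stopifnot(n >= 1)
  tab <- forward_sample_fit(as_bn_fit(gt), n, seed)
  tab <- dplyr::mutate(tab, dplyr::across(
    dplyr::everything(),
    ~ factor(.x, levels = gt$levels[[dplyr::cur_column()]])
  ))
  dplyr::bind_cols(tibble::tibble(subject_id = sprintf("S%04d", seq_len(n))), tab)
}

#' Render presence/absence taxa into a raw count table
#'
#' Absent taxa get zero reads. Present taxa get negative-binomial reads
#' (taxon-specific mean abundance weights, dispersion from the config),
#' rescaled so each sample's total equals a depth drawn log-normally around
#' `mean_depth`; `n_low_depth` samples are forced below 1000 total counts.
#' Rare nuisance taxa with grand totals guaranteed below the 0.1% abundance
#' rule are appended so the rare-taxon filter is exercised.
#'
#' @param gt_table Output of [forward_sample()] (needs the taxon columns).
#' @param config The [sim_config()].
#' @param seed Integer seed.
#' @return A count table: `subject_id` plus integer taxa columns.
#' @export
render_counts <- function(gt_table, config, seed = 1) {
  layout <- sim_node_layout(config)
  taxa <- layout$taxa
  n <- nrow(gt_table)
  present <- vapply(taxa, function(t) gt_table[[t]] == "present", logical(n))
  if (is.null(dim(present))) present <- matrix(present, nrow = n)
  with_seed(seed, {
    depth <- round(rlnorm(n, meanlog = log(config$mean_depth), sdlog = config$depth_spread))
    depth <- pmax(depth, 1100)
    if (config$n_low_depth > 0 && n > config$n_low_depth) {
      low <- sample.int(n, config$n_low_depth)
      depth[low] <- round(runif(config$n_low_depth, 650, 980))
    }
    # taxon-specific mean abundance weights (right-skewed)
    w <- rlnorm(length(taxa), meanlog = 0, sdlog = 1)
    raw <- matrix(0, n, length(taxa))
    for (j in seq_along(taxa)) {
      k <- which(present[, j])
      if (length(k)) {
        raw[k, j] <- 1 + rnbinom(length(k), size = config$count_dispersion, mu = 50 * w[j])
      }
    }
    counts <- matrix(0L, n, length(taxa), dimnames = list(NULL, taxa))
    for (i in seq_len(n)) {
      pres <- which(raw[i, ] > 0)
      if (!length(pres)) {
        # degenerate all-absent subject: give one read to a random taxon so
        # the sample still has positive depth
        pres <- sample(seq_along(taxa), 1)
        raw[i, pres] <- 1
      }
      scaled <- raw[i, pres] / sum(raw[i, pres]) * depth[i]
      ci <- pmax(1L, as.integer(round(scaled)))
      # absorb rounding drift into the largest taxon
      drift <- depth[i] - sum(ci)
      ci[which.max(ci)] <- ci[which.max(ci)] + as.integer(drift)
      counts[i, pres] <- ci
    }
    out <- dplyr::bind_cols(
      tibble::tibble(subject_id = as.character(gt_table$subject_id)),
      tibble::as_tibble(counts)
    )
    if (config$n_nuisance_taxa > 0) {
      grand <- sum(counts)
      # per-nuisance-taxon budget safely below 0.1% of the grand total
      budget <- max(1, floor(0.0004 * grand))
      nuis <- matrix(0L, n, config$n_nuisance_taxa,
                     dimnames = list(NULL, sprintf("rare%03d", seq_len(config$n_nuisance_taxa))))
      for (j in seq_len(config$n_nuisance_taxa)) {
        total_j <- sample.int(budget, 1)
        hosts <- sample.int(n, min(n, max(1, rbinom(1, 5, 0.5) + 1)))
        alloc <- rmultinom(1, total_j, rep(1, length(hosts)))[, 1]
        nuis[hosts, j] <- as.integer(alloc)
      }
      out <- dplyr::bind_cols(out, tibble::as_tibble(nuis))
    }
  })
  out
}

#' Inject MCAR missingness into a survey table
#'
#' Masks cells completely at random at `rate`; columns listed in
#' `high_missing` are masked at `high_rate` instead (used to exercise the
#' question-missingness filter).
#'
#' @param survey Survey table (subject ID first column).
#' @param rate Cell missing probability in `[0, 1)`.
#' @param seed Integer seed.
#' @param high_missing Character vector of column names masked at
#'   `high_rate`.
#' @param high_rate Missing probability for `high_missing` columns.
#' @return The survey with `NA`s injected.
#' @export
inject_missingness <- function(survey, rate, seed = 1, high_missing = character(),
                               high_rate = 0.08) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0 && !length(high_missing)) return(survey)
  cols <- setdiff(names(survey), names(survey)[1])
  with_seed(seed, {
    for (v in cols) {
      r <- if (v %in% high_missing) high_rate else rate
      if (r <= 0) next
      mask <- runif(nrow(survey)) < r
      survey[[v]][mask] <- NA
    }
  })
  survey
}

# Render the sampled discrete table as a raw survey: numeric variables get
# bin-faithful numeric values (so the fixed discretization recovers the
# level exactly), everything else passes through as character.
render_survey <- function(gt_table, config, seed = 1) {
  layout <- sim_node_layout(config)
  qcols <- c(layout$habits, layout$symptoms)
  n <- nrow(gt_table)
  numeric_render <- list(
    age = list("<=30" = c(18, 30), "31-40" = c(31, 40), ">40" = c(41, 45)),
    menarche_age = list("<11" = c(8, 10), "11-15" = c(11, 15), ">15" = c(16, 18)),
    partners_60d = list("0" = c(0, 0), "1" = c(1, 1), ">1" = c(2, 5)),
    vaginal_births = list("0" = c(0, 0), "1" = c(1, 1), "2" = c(2, 2), "3" = c(3, 3)),
    period_length = list("1" = c(1, 1), "2" = c(2, 2), "3" = c(3, 3), "4" = c(4, 4)),
    nugent = list(low = c(0, 3), medium = c(4, 6), high = c(7, 10))
  )
  out <- tibble::tibble(subject_id = as.character(gt_table$subject_id))
  with_seed(seed, {
    for (v in c("age", "ethnicity", qcols, "ph", "nugent")) {
      val <- as.character(gt_table[[v]])
      if (v %in% names(numeric_render)) {
        rng <- numeric_render[[v]]
        out[[v]] <- vapply(val, function(l) {
          b <- rng[[l]]
          b[1] + sample.int(b[2] - b[1] + 1L, 1) - 1L
        }, numeric(1), USE.NAMES = FALSE)
      } else {
        out[[v]] <- val
      }
    }
    # screening questions: mostly benign answers, a few disqualifying/missing
    out$good_health <- ifelse(runif(n) < 0.012, "no", "yes")
    out$good_health[runif(n) < 0.004] <- NA
    out$ever_tss <- ifelse(runif(n) < 0.018, "yes", "no")
    out$ever_tss[runif(n) < 0.006] <- NA
    # filler questions destined for the missingness filter
    if (config$n_filler_missing > 0) {
      for (j in seq_len(config$n_filler_missing)) {
        out[[sprintf("filler_m%03d", j)]] <- sample(c("yes", "no"), n, replace = TRUE)
      }
    }
    # filler questions destined for the sparseness filter (<5% minority level)
    if (config$n_filler_sparse > 0) {
      for (j in seq_len(config$n_filler_sparse)) {
        p_min <- runif(1, 0.001, 0.03)
        out[[sprintf("filler_s%03d", j)]] <- ifelse(runif(n) < p_min, "yes", "no")
      }
    }
  })
  out
}

#' Simulate a full raw study: counts plus survey
#'
#' Samples the ground truth, forward-samples the subjects, renders raw
#' counts (with low-depth samples and rare nuisance taxa) and a raw survey
#' (numeric age/nugent/habit variables, screening questions, filler
#' questions), then injects MCAR missingness (filler missingness columns
#' above the 5% threshold).
#'
#' @param config A [sim_config()].
#' @return List with `counts`, `survey`, `truth` (the
#'   [make_ground_truth()] object), `discrete` (the sampled complete table)
#'   and `categories` (named vector for the network nodes).
#' @export
simulate_study <- function(config = sim_config()) {
  seeds <- derive_seeds(config$master_seed, 6)
  gt <- make_ground_truth(config)
  disc <- forward_sample(gt, config$n_subjects, seed = seeds[2])
  counts <- render_counts(disc, config, seed = seeds[3])
  survey <- render_survey(disc, config, seed = seeds[4])
  high <- grep("^filler_m", names(survey), value = TRUE)
  survey <- inject_missingness(
    survey, rate = config$missing_rate, seed = seeds[5],
    high_missing = high, high_rate = 0.08
  )
  # every survey question carries an a-priori category, including the
  # filler questions (they are survey items; a few can survive the filters)
  fillers <- grep("^filler_", names(survey), value = TRUE)
  categories <- c(
    gt$category,
    setNames(rep("sexual/sanitary habit", length(fillers)), fillers)
  )
  list(
    counts = counts,
    survey = survey,
    truth = gt,
    discrete = disc,
    categories = categories
  )
}

#' Skeleton precision/recall/F1 of a learned graph against a truth
#'
#' Compares undirected adjacencies (the skeleton), ignoring orientation.
#'
#' @param learned,truth `bn_dag` objects over the same nodes.
#' @return Tibble with `true_arcs`, `learned_arcs`, `tp`, `precision`,
#'   `recall`, `f1`.
#' @export
skeleton_f1 <- function(learned, truth) {
  und <- function(dag) {
    if (!nrow(dag$arcs)) return(character())
    unique(ifelse(
      dag$arcs$from < dag$arcs$to,
      paste(dag$arcs$from, dag$arcs$to),
      paste(dag$arcs$to, dag$arcs$from)
    ))
  }
  a <- und(learned)
  b <- und(truth)
  tp <- length(intersect(a, b))
  precision <- if (length(a)) tp / length(a) else NA_real_
  recall <- if (length(b)) tp / length(b) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    0
  }
  tibble::tibble(
    true_arcs = length(b), learned_arcs = length(a), tp = tp,
    precision = precision, recall = recall, f1 = f1
  )
}
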