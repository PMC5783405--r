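# Companion community-ecology analyses: Hellinger transform, NMDS, ANOSIM,
# PERMANOVA (as RDA on Hellinger-transformed counts) and forward stepwise
# AIC model selection.

#' Hellinger transform of a count table
#'
#' Per sample: square root of relative abundances, so each row's squared
#' values sum to one and Euclidean distance between rows is the Hellinger
#' distance.
#'
#' @param counts A count table (subject ID first column) with positive row
#'   totals.
#' @return A tibble: `subject_id` plus transformed taxa columns.
#' @export
hellinger_transform <- function(counts) {
  validate_count_table(counts)
  m <- as.matrix(counts[, -1, drop = FALSE])
  if (any(rowSums(m) <= 0)) abort("zero-total sample; cannot Hellinger-transform")
  h <- vegan::decostand(m, method = "hellinger")
  dplyr::bind_cols(
    tibble::tibble(subject_id = as.character(counts[[1]])),
    tibble::as_tibble(h)
  )
}

#' Euclidean distance matrix between transformed samples
#' @param transformed Output of [hellinger_transform()] (or any subject-by-
#'   variable table with an ID first column).
#' @return A `dist` object labelled by subject IDs.
#' @export
community_distances <- function(transformed) {
  m <- as.matrix(transformed[, -1, drop = FALSE])
  rownames(m) <- as.character(transformed[[1]])
  stats::dist(m)
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 NMDS with multiple random starts, keeping the best
#' solution.
#'
#' @param dist A `dist` object (e.g. from [community_distances()]).
#' @param k Number of dimensions. Default 2.
#' @param n_starts Random starts. Default 50.
#' @param seed Integer seed.
#' @return An object of class `bn_ordination`: tibble of coordinates
#'   (`subject_id`, `NMDS1`, ...), with `stress` (in `[0, 1]`), `converged`
#'   and `n_starts` attributes.
#' @export
nmds <- function(dist, k = 2, n_starts = 50, seed = 1) {
  stopifnot(k >= 1, n_starts >= 1)
  fit <- with_seed(seed, vegan::metaMDS(
    dist, k = k, try = n_starts, trymax = n_starts,
    trace = 0, autotransform = FALSE, wascores = FALSE
  ))
  coords <- tibble::as_tibble(as.data.frame(fit$points), .name_repair = "minimal")
  names(coords) <- paste0("NMDS", seq_len(k))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = attr(dist, "Labels") %||% as.character(seq_len(nrow(coords)))),
    coords
  )
  structure(
    out,
    class = c("bn_ordination", class(out)),
    stress = fit$stress,
    converged = isTRUE(fit$converged > 0 || isTRUE(fit$converged)),
    n_starts = n_starts
  )
}

#' @export
print.bn_ordination <- function(x, ...) {
  cat(sprintf(
    "<bn_ordination> k = %d, stress = %.4f, converged = %s\n",
    ncol(x) - 1L, attr(x, "stress"), attr(x, "converged")
  ))
  NextMethod()
}

new_perm_test <- function(tbl, n_perm, full_r2 = NA_real_) {
  structure(
    tibble::as_tibble(tbl),
    class = c("bn_perm_test", class(tibble::tibble())),
    n_perm = n_perm, full_r2 = full_r2
  )
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based contrast of between- versus within-group pairwise distances,
#' with a free permutation test of the group labels.
#'
#' @param dist A `dist` object.
#' @param grouping Factor (or coercible) with at least two groups of two.
#' @param n_perm Number of permutations. Default 999.
#' @param seed Integer seed.
#' @return A `bn_perm_test` tibble: `term`, `statistic` (ANOSIM R), `R2`
#'   (`NA`), `p`, `n_perm`.
#' @export
anosim_test <- function(dist, grouping, n_perm = 999, seed = 1) {
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2 || any(table(grouping) < 2)) {
    abort("grouping needs >= 2 groups with >= 2 members each")
  }
  fit <- with_seed(seed, vegan::anosim(dist, grouping, permutations = n_perm))
  new_perm_test(
    tibble::tibble(
      term = "grouping",
      statistic = unname(fit$statistic),
      R2 = NA_real_,
      p = fit$signif,
      n_perm = n_perm
    ),
    n_perm
  )
}

one_hot <- function(predictors) {
  predictors <- as.data.frame(predictors)
  stats::model.matrix(~., data = predictors)
}

#' PERMANOVA via redundancy analysis on transformed counts
#'
#' Fits an RDA of the (Hellinger-transformed) community matrix on the
#' predictors and tests each term sequentially with a permutation pseudo-F
#' (permutation of residuals under the reduced model). Because Euclidean
#' distance on Hellinger-transformed counts is the Hellinger distance, this
#' is the distance-based PERMANOVA in variance-partition form.
#'
#' @param transformed Subject-by-taxon table (ID first column), typically
#'   from [hellinger_transform()].
#' @param predictors Data frame of categorical predictors, rows aligned with
#'   `transformed`.
#' @param n_perm Number of permutations. Default 999.
#' @param seed Integer seed.
#' @param by Term testing mode for `vegan::anova.cca` (`"terms"`
#'   sequential, default).
#' @return A `bn_perm_test` tibble with one row per term: `term`, `df`,
#'   `statistic` (pseudo-F), `R2` (share of total variance), `p`,
#'   `n_perm`; attribute `full_r2` holds the full-model R-squared (also in
#'   the `"Model"` row of the table when `by = NULL`).
#' @export
permanova <- function(transformed, predictors, n_perm = 999, seed = 1, by = "terms") {
  y <- as.matrix(transformed[, -1, drop = FALSE])
  predictors <- as.data.frame(predictors)
  stopifnot(nrow(predictors) == nrow(y))
  constant <- vapply(predictors, function(x) length(unique(x)) < 2, logical(1))
  if (any(constant)) {
    warn(sprintf(
      "dropping constant predictor(s): %s",
      paste(names(predictors)[constant], collapse = ", ")
    ))
    predictors <- predictors[, !constant, drop = FALSE]
  }
  if (ncol(predictors) == 0L) {
    return(new_perm_test(
      tibble::tibble(term = character(), df = numeric(), statistic = numeric(),
                     R2 = numeric(), p = numeric(), n_perm = integer()),
      n_perm, full_r2 = 0
    ))
  }
  fit <- vegan::rda(y ~ ., data = predictors)
  full_r2 <- fit$CCA$tot.chi / fit$tot.chi
  an <- with_seed(seed, vegan::anova.cca(fit, by = by, permutations = n_perm))
  tab <- as.data.frame(an)
  terms <- rownames(tab)
  keep <- !terms %in% c("Residual", "Residuals")
  new_perm_test(
    tibble::tibble(
      term = terms[keep],
      df = tab$Df[keep],
      statistic = tab$F[keep],
      R2 = tab$Variance[keep] / sum(tab$Variance),
      p = tab$`Pr(>F)`[keep],
      n_perm = n_perm
    ),
    n_perm, full_r2 = full_r2
  )
}

#' @export
print.bn_perm_test <- function(x, ...) {
  cat(sprintf("<bn_perm_test> %d permutations", attr(x, "n_perm")))
  if (!is.na(attr(x, "full_r2"))) cat(sprintf(", full-model R2 = %.3f", attr(x, "full_r2")))
  cat("\n")
  NextMethod()
}

#' @export
glance.bn_perm_test <- function(x, ...) {
  tibble::tibble(
    n_terms = nrow(x),
    full_r2 = attr(x, "full_r2"),
    n_perm = attr(x, "n_perm")
  )
}

# Deviance-style AIC analog for a multivariate linear fit of Y on a one-hot
# model matrix: n * log(RSS / n) + 2 * rank.
rda_aic <- function(y, predictors) {
  n <- nrow(y)
  yc <- scale(y, center = TRUE, scale = FALSE)
  if (is.null(predictors) || ncol(as.data.frame(predictors)) == 0L) {
    rss <- sum(yc^2)
    return(list(aic = n * log(rss / n) + 2 * 1, rss = rss, rank = 1L))
  }
  x <- one_hot(predictors)
  qr_x <- qr(x)
  fitted <- qr.fitted(qr_x, yc)
  rss <- sum((yc - fitted)^2)
  list(aic = n * log(rss / n) + 2 * qr_x$rank, rss = rss, rank = qr_x$rank)
}

#' Forward stepwise predictor selection by a multivariate AIC analog
#'
#' Greedy forward selection on the transformed community matrix: at each
#' step the candidate predictor whose addition most lowers
#' `n * log(RSS / n) + 2 * rank` joins the model; selection stops when no
#' candidate lowers it. Deterministic.
#'
#' @param transformed Subject-by-taxon table (ID first column).
#' @param candidates Data frame of candidate categorical predictors.
#' @return Tibble with the selection path: `step`, `term`, `aic`; the
#'   selected predictor names in order as attribute `"selected"`.
#' @export
stepwise_select <- function(transformed, candidates) {
  y <- as.matrix(transformed[, -1, drop = FALSE])
  candidates <- as.data.frame(candidates)
  stopifnot(ncol(candidates) >= 1, nrow(candidates) == nrow(y))
  selected <- character()
  current_aic <- rda_aic(y, NULL)$aic
  path <- list(tibble::tibble(step = 0L, term = "(none)", aic = current_aic))
  repeat {
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    trial_aic <- vapply(remaining, function(v) {
      rda_aic(y, candidates[, c(selected, v), drop = FALSE])$aic
    }, numeric(1))
    best <- which.min(trial_aic)
    if (trial_aic[best] >= current_aic) break
    selected <- c(selected, remaining[best])
    current_aic <- trial_aic[best]
    path[[length(path) + 1]] <- tibble::tibble(
      step = length(selected), term = remaining[best], aic = current_aic
    )
  }
  out <- dplyr::bind_rows(path)
  attr(out, "selected") <- selected
  out
}
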