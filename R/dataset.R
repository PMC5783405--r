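#' Discrete dataset for Bayesian-network learning
#'
#' A complete-case table of categorical variables plus per-variable metadata:
#' the five-level a-priori category scheme (`demographic`, `microbiome`,
#' `sexual/sanitary habit`, `BV risk symptom`, `BV diagnostic criteria`) and a
#' structural role (`root`, `leaf` or `free`). Roots are variables no arc may
#' point into; a leaf is a variable no arc may leave.
#'
#' @param data A data frame of categorical columns (factors or characters),
#'   one row per subject, no missing values.
#' @param subject_ids Optional character vector of subject identifiers
#'   (defaults to row numbers).
#' @param categories Named character vector mapping variable names to the
#'   five-level category scheme. Unnamed variables get `NA`.
#' @param roles Named character vector mapping variable names to
#'   `"root"`/`"leaf"` (everything else is `"free"`).
#' @return An object of class `bn_dataset`: a list with elements `data`
#'   (tibble of factors), `subject_ids`, and `meta` (tibble with columns
#'   `variable`, `category`, `role`, `levels` list-column).
#' @export
bn_dataset <- function(data, subject_ids = NULL, categories = NULL, roles = NULL) {
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0L || ncol(data) == 0L) {
    abort("bn_dataset needs at least one subject and one variable")
  }
  if (anyNA(data)) {
    abort("bn_dataset must be complete-case; missing values found")
  }
  if (anyDuplicated(names(data))) abort("duplicate variable names")
  data <- dplyr::mutate(data, dplyr::across(dplyr::everything(), ~ {
    f <- factor(.x)
    droplevels(f)
  }))
  n_lev <- vapply(data, nlevels, integer(1))
  if (any(n_lev < 2L)) {
    abort(sprintf(
      "every variable needs >= 2 observed levels; constant: %s",
      paste(names(data)[n_lev < 2L], collapse = ", ")
    ))
  }
  subject_ids <- as.character(subject_ids %||% seq_len(nrow(data)))
  if (length(subject_ids) != nrow(data) || anyDuplicated(subject_ids)) {
    abort("subject_ids must be unique and match the number of rows")
  }
  roles_full <- rep("free", ncol(data))
  names(roles_full) <- names(data)
  if (!is.null(roles)) {
    bad <- setdiff(names(roles), names(data))
    if (length(bad)) abort(sprintf("role given for unknown variable: %s", bad[1]))
    if (!all(roles %in% c("root", "leaf", "free"))) abort("roles must be root/leaf/free")
    roles_full[names(roles)] <- roles
  }
  cats_full <- rep(NA_character_, ncol(data))
  names(cats_full) <- names(data)
  if (!is.null(categories)) {
    bad <- setdiff(names(categories), names(data))
    if (length(bad)) abort(sprintf("category given for unknown variable: %s", bad[1]))
    ok <- categories %in% node_category_levels()
    if (!all(ok)) {
      abort(sprintf("unknown category '%s'", categories[!ok][1]))
    }
    cats_full[names(categories)] <- categories
  }
  if (sum(roles_full == "leaf" & cats_full %in% "BV diagnostic criteria", na.rm = TRUE) > 1) {
    abort("at most one diagnostic leaf")
  }
  meta <- tibble::tibble(
    variable = names(data),
    category = unname(cats_full),
    role = unname(roles_full),
    levels = lapply(data, levels)
  )
  structure(
    list(data = data, subject_ids = subject_ids, meta = meta),
    class = "bn_dataset"
  )
}

#' The five a-priori node categories
#' @return Character vector of the category scheme.
#' @export
node_category_levels <- function() {
  c(
    "demographic", "microbiome", "sexual/sanitary habit",
    "BV risk symptom", "BV diagnostic criteria"
  )
}

#' @export
print.bn_dataset <- function(x, ...) {
  cat(sprintf(
    "<bn_dataset> %d subjects x %d variables (%d root, %d leaf)\n",
    nrow(x$data), ncol(x$data),
    sum(x$meta$role == "root"), sum(x$meta$role == "leaf")
  ))
  print(dplyr::count(x$meta, .data$category))
  invisible(x)
}

#' @export
dim.bn_dataset <- function(x) dim(x$data)

#' @export
as.data.frame.bn_dataset <- function(x, ...) as.data.frame(x$data, ...)

#' Coerce a bn_dataset to a tibble of factors
#' @param x A `bn_dataset`.
#' @param ... Unused.
#' @return The underlying tibble, with a `subject_id` column prepended.
#' @export
as_tibble.bn_dataset <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(subject_id = x$subject_ids), x$data)
}

#' Variable names of a dataset or graph
#' @param x A `bn_dataset` or `bn_dag`.
#' @return Character vector of variable names.
#' @export
variables <- function(x) UseMethod("variables")

#' @export
variables.bn_dataset <- function(x) names(x$data)

#' Structural roles declared on a dataset
#' @param x A `bn_dataset`.
#' @return Named character vector (`root`/`leaf`/`free`) per variable.
#' @export
variable_roles <- function(x) {
  setNames(x$meta$role, x$meta$variable)
}

#' A-priori categories declared on a dataset
#' @param x A `bn_dataset`.
#' @return Named character vector per variable (may contain `NA`).
#' @export
variable_categories <- function(x) {
  setNames(x$meta$category, x$meta$variable)
}

# Integer-coded view used by the scoring machinery: matrix of level indices
# plus level counts. Kept internal; all scoring is count-based so row order
# never matters.
dataset_codes <- function(dataset) {
  mat <- vapply(dataset$data, function(f) as.integer(f), integer(nrow(dataset$data)))
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = ncol(dataset$data))
  colnames(mat) <- names(dataset$data)
  list(
    mat = mat,
    nlev = vapply(dataset$data, nlevels, integer(1)),
    levels = lapply(dataset$data, levels)
  )
}

#' Write / read a discrete dataset as CSV plus a metadata sidecar
#'
#' The data file holds `subject_id` plus one column per variable; the sidecar
#' holds `variable,category,role,levels` with levels joined by `|`.
#'
#' @param dataset A `bn_dataset`.
#' @param data_file,meta_file Paths for the two CSV files.
#' @return `write_bn_dataset()` returns the paths invisibly;
#'   `read_bn_dataset()` returns a `bn_dataset`.
#' @export
write_bn_dataset <- function(dataset, data_file, meta_file) {
  utils::write.csv(as_tibble.bn_dataset(dataset), data_file, row.names = FALSE)
  meta <- dataset$meta
  meta_out <- data.frame(
    variable = meta$variable,
    category = meta$category,
    role = meta$role,
    levels = vapply(meta$levels, paste, character(1), collapse = "|")
  )
  utils::write.csv(meta_out, meta_file, row.names = FALSE)
  invisible(c(data_file, meta_file))
}

#' @rdname write_bn_dataset
#' @export
read_bn_dataset <- function(data_file, meta_file) {
  dat <- utils::read.csv(data_file, check.names = FALSE, colClasses = "character")
  meta <- utils::read.csv(meta_file, check.names = FALSE, colClasses = "character")
  ids <- dat$subject_id
  dat$subject_id <- NULL
  lev <- strsplit(meta$levels, "|", fixed = TRUE)
  for (i in seq_len(nrow(meta))) {
    v <- meta$variable[i]
    dat[[v]] <- factor(dat[[v]], levels = lev[[i]])
  }
  cats <- setNames(meta$category, meta$variable)
  cats <- cats[!is.na(cats) & cats != "" & cats != "NA"]
  roles <- setNames(meta$role, meta$variable)
  bn_dataset(dat, subject_ids = ids, categories = cats, roles = roles[roles != "free"])
}
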