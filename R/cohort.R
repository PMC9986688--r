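#' Case-control cohort tables
#'
#' A cohort table holds one row per individual: case/control status
#' (1/0), age (at diagnosis for cases, at last observation for
#' controls), the raw and standardized PRS, a country label and any
#' principal-component covariates (`pc1`, `pc2`, ...).  Ages must lie in
#' the model range and below 80.
#'
#' @param df A data frame with at least columns `status`, `age` and one
#'   of `prs_std` / `prs_raw`.  If `prs_std` is absent it is copied from
#'   `prs_raw`.  A `sample_id` column is added if missing.
#' @param params A [variance_params()] giving the admissible age range.
#' @return The validated data frame with class `cohort_table`.
#' @export
cohort_table <- function(df, params = variance_params()) {
  df <- as.data.frame(df)
  if (!all(c("status", "age") %in% names(df)))
    stop("cohort requires `status` and `age` columns", call. = FALSE)
  if (!("prs_std" %in% names(df))) {
    if (!("prs_raw" %in% names(df)))
      stop("cohort requires a `prs_std` or `prs_raw` column", call. = FALSE)
    df$prs_std <- df$prs_raw
  }
  if (!("sample_id" %in% names(df)))
    df$sample_id <- sprintf("S%06d", seq_len(nrow(df)))
  if (!("country" %in% names(df))) df$country <- "ALL"
  if (anyNA(df$age) || anyNA(df$status))
    stop("cohort ages and statuses must be complete", call. = FALSE)
  df$status <- as.integer(df$status)
  if (!all(df$status %in% c(0L, 1L)))
    stop("`status` must be binary 0/1", call. = FALSE)
  df$age <- as.integer(df$age)
  if (any(df$age < params$age_min | df$age > params$age_max | df$age >= 80L))
    stop(sprintf("cohort ages must lie in [%d, %d] and below 80",
                 params$age_min, params$age_max), call. = FALSE)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read or write a cohort CSV
#'
#' Columns: `sample_id, status, age, prs_raw, country, pc1..pcK`
#' (optionally `prs_std`).
#'
#' @param path CSV path.
#' @param cohort A `cohort_table`.
#' @param params A [variance_params()] for validation.
#' @return `read_cohort` returns a `cohort_table`; `write_cohort`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path, params = variance_params()) {
  if (!file.exists(path))
    stop(sprintf("cohort file not found: %s", path), call. = FALSE)
  cohort_table(utils::read.csv(path, comment.char = "#",
                               stringsAsFactors = FALSE), params)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

pc_columns <- function(cohort) grep("^pc[0-9]+$", names(cohort), value = TRUE)

covariate_matrix <- function(cohort, covariates) {
  if (length(covariates) == 0L)
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0L))
  missing <- setdiff(covariates, names(cohort))
  if (length(missing))
    stop(sprintf("covariate columns absent from cohort: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df <- as.data.frame(cohort)[covariates]
  for (v in covariates)
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
  constant <- vapply(df, function(x) length(unique(x)) < 2L, logical(1))
  df <- df[!constant]
  if (ncol(df) == 0L)
    return(matrix(numeric(0), nrow = nrow(cohort), ncol = 0L))
  mm <- stats::model.matrix(~ ., data = df)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}
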