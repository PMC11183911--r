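cohort_columns <- c("subject_id", "arm", "pre_area_cm2", "post_area_cm2",
                    "n_applications", "treatment_days")
cohort_optional <- c("age", "sex")

#' Validate a cohort table
#'
#' Checks the schema invariants of a per-subject wound cohort: required
#' columns present, unique subject ids, arm coded 0/1, strictly positive
#' baseline areas, non-negative endpoint areas (0 = closed) and positive
#' integer application / treatment-day counts. Errors name the offending row
#' and column.
#'
#' @param cohort A data.frame.
#' @return The cohort, invisibly, with class `cohort_table` attached.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort))
    stop("cohort must be a data.frame", call. = FALSE)
  missing_cols <- setdiff(cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort: missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(cohort) == 0L) stop("cohort: no rows", call. = FALSE)

  fail_row <- function(col, bad, what) {
    stop(sprintf("cohort: column '%s', row %d: %s", col, which(bad)[1], what),
         call. = FALSE)
  }
  dup <- duplicated(cohort$subject_id)
  if (any(dup)) fail_row("subject_id", dup, "duplicate subject_id")

  num_col <- function(col) {
    v <- cohort[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn)) fail_row(col, is.na(vn), "non-numeric value")
      v <- vn
    }
    if (anyNA(v)) fail_row(col, is.na(v), "missing value")
    v
  }
  arm <- num_col("arm")
  if (!all(arm %in% c(0, 1))) fail_row("arm", !arm %in% c(0, 1), "arm must be 0 or 1")
  pre <- num_col("pre_area_cm2")
  if (any(pre <= 0)) fail_row("pre_area_cm2", pre <= 0, "baseline area must be > 0")
  post <- num_col("post_area_cm2")
  if (any(post < 0)) fail_row("post_area_cm2", post < 0, "endpoint area must be >= 0")
  for (col in c("n_applications", "treatment_days")) {
    v <- num_col(col)
    bad <- v < 1 | v != floor(v)
    if (any(bad)) fail_row(col, bad, "must be a positive integer")
  }
  if (!inherits(cohort, "cohort_table"))
    class(cohort) <- c("cohort_table", class(cohort))
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads and validates a per-subject cohort file with mandatory header
#' `subject_id, arm, pre_area_cm2, post_area_cm2, n_applications,
#' treatment_days` (optional passthrough columns `age`, `sex`). Any schema
#' violation raises an error naming the row and column; missing endpoint
#' areas are an error, never imputed.
#'
#' @param path CSV file path.
#' @return A `cohort_table` data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop("read_cohort_csv: no such file: ", path, call. = FALSE)
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  cohort <- validate_cohort(cohort)
  cohort$arm <- as.integer(cohort$arm)
  cohort$n_applications <- as.integer(cohort$n_applications)
  cohort$treatment_days <- as.integer(cohort$treatment_days)
  cohort
}

#' Write a cohort CSV
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' Read a fit configuration from YAML
#'
#' Recognized keys: `chains`, `draws`, `warmup`, `seed`, `target_accept`,
#' `thin`; missing keys fall back to the [fit_config()] defaults.
#'
#' @param path YAML file path.
#' @return A [fit_config()].
#' @export
read_fit_config <- function(path) {
  if (!file.exists(path)) stop("read_fit_config: no such file: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  dflt <- fit_config()
  fit_config(
    n_chains = y$chains %||% dflt$n_chains,
    n_draws_per_chain = y$draws %||% dflt$n_draws_per_chain,
    n_warmup = y$warmup %||% dflt$n_warmup,
    seed = y$seed %||% dflt$seed,
    target_accept = y$target_accept %||% dflt$target_accept,
    thin = y$thin %||% dflt$thin
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
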