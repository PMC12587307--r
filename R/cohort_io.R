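# Cohort and configuration I/O: CSV for subject-level tables, YAML for
# generator/pipeline configuration.

REQUIRED_COLUMNS <- c("subject_id", "age", "sex", "ses", "ever_smoker",
                      "disease_duration", "nurse_visits", "pcp_visits",
                      "sick_leave_days", "sick_leave_eligible", "dispensations")

#' Write a cohort table to CSV
#'
#' @param cohort a `cohort_table`.
#' @param path output file.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read and validate a cohort table from CSV
#'
#' Expects the documented header: `subject_id`, 26 binary comorbidity
#' columns (see [comorbidity_names()]), demographics (`age`, `sex`, `ses`,
#' `ever_smoker`, `disease_duration`) and outcomes (`nurse_visits`,
#' `pcp_visits`, `sick_leave_days`, `sick_leave_eligible`,
#' `dispensations`); an optional `true_class` column is kept when present.
#' Non-binary comorbidity entries are reported with their row and column.
#'
#' @param path CSV file path.
#' @param comorbidities names of the indicator columns (default: the
#'   packaged 26-item list).
#' @return a validated `cohort_table`.
#' @export
read_cohort <- function(path, comorbidities = comorbidity_names()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) stop(sprintf("empty input file: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop(sprintf("no subjects in input file: %s", path))
  missing_cols <- setdiff(c(REQUIRED_COLUMNS, comorbidities), names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing required column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  for (cc in comorbidities) {
    v <- df[[cc]]
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("non-binary comorbidity value in column `%s`, row(s) %s",
                   cc, paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  if (anyDuplicated(df$subject_id)) stop("duplicate subject_id values")
  if (any(df$age < 18, na.rm = TRUE)) stop("ages below 18 are outside the adult cohort definition")
  for (v in c("disease_duration", "nurse_visits", "pcp_visits", "sick_leave_days", "dispensations")) {
    if (any(df[[v]] < 0, na.rm = TRUE)) stop(sprintf("negative values in `%s`", v))
  }
  df$sex <- factor(df$sex, levels = c("male", "female"))
  df$ses <- factor(df$ses, levels = paste0("Q", 1:5))
  if ("true_class" %in% names(df)) {
    ks <- sort(unique(setdiff(df$true_class, "none")))
    df$true_class <- factor(df$true_class, levels = c("none", ks))
  }
  attr(df, "comorbidities") <- comorbidities
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write / read generator configuration as YAML
#'
#' Matrix-valued fields are stored as named per-class lists so the files
#' stay human-editable.
#'
#' @param config a `cohort_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(config, path) {
  obj <- unclass(config)
  obj$item_profiles <- apply(config$item_profiles, 1L, as.list, simplify = FALSE)
  obj$class_weights <- as.list(config$class_weights)
  obj$missingness <- as.list(config$missingness)
  yaml::write_yaml(obj, path, precision = 15L)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  obj$class_weights <- unlist(obj$class_weights)
  prof <- do.call(rbind, lapply(obj$item_profiles, unlist))
  obj$item_profiles <- prof
  obj$missingness <- unlist(obj$missingness)
  obj$n_subjects <- as.integer(obj$n_subjects)
  obj$seed <- as.integer(obj$seed)
  for (g in names(obj$demo_model)) {
    obj$demo_model[[g]] <- lapply(obj$demo_model[[g]], unlist)
  }
  config <- structure(obj, class = "cohort_config")
  validate_config(config)
  config
}
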