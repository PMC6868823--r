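scoff_columns <- function() paste0("scoff_", scoff_items())

patient_columns <- function() {
  c("id", "sex", "age", "bmi", scoff_columns())
}

#' Validate a patient cohort data frame
#'
#' Checks the Patient CSV contract: required columns present, ids unique,
#' sex in {female, male}, age at least 18 (the study inclusion criterion),
#' BMI finite in (0, 100], SCOFF answers binary, and the optional
#' `dsm5_diagnosis` column restricted to [dsm5_vocabulary()]. SCOFF answers
#' are normalised to integer 0/1.
#'
#' @param records Data frame in the Patient CSV layout.
#' @param permissive If `TRUE`, allow age under 18 and missing sex (for
#'   reuse outside the original inclusion criteria). Default `FALSE`.
#' @return The validated data frame, SCOFF columns normalised to 0/1,
#'   extra columns untouched.
#' @export
validate_cohort <- function(records, permissive = FALSE) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop("records must be a non-empty data frame", call. = FALSE)
  }
  missing_cols <- setdiff(patient_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop(sprintf("missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  records$id <- as.character(records$id)
  if (anyDuplicated(records$id)) {
    dup <- unique(records$id[duplicated(records$id)])
    stop(sprintf("duplicate patient id(s): %s",
                 paste(utils::head(dup, 5), collapse = ", ")), call. = FALSE)
  }
  sex <- tolower(as.character(records$sex))
  if (!permissive) {
    bad_sex <- is.na(sex) | !sex %in% c("female", "male")
    if (any(bad_sex)) {
      stop(sprintf("invalid or missing sex for id(s): %s",
                   paste(utils::head(records$id[bad_sex], 5), collapse = ", ")),
           call. = FALSE)
    }
    under <- !is.finite(records$age) | records$age < 18
    if (any(under)) {
      stop(sprintf("age below 18 or missing for id(s): %s (use permissive = TRUE to allow)",
                   paste(utils::head(records$id[under], 5), collapse = ", ")),
           call. = FALSE)
    }
  }
  records$sex <- sex
  classify_bmi(records$bmi) # errors on invalid BMI
  for (col in scoff_columns()) {
    item <- sub("^scoff_", "", col)
    records[[col]] <- vapply(records[[col]], function(v) {
      as.integer(parse_binary_answer(v, item))
    }, integer(1))
  }
  if ("dsm5_diagnosis" %in% names(records)) {
    has_dx <- !is.na(records$dsm5_diagnosis) & records$dsm5_diagnosis != ""
    if (any(has_dx)) map_dsm5_to_broad(records$dsm5_diagnosis[has_dx])
  }
  records
}

#' Read a patient cohort CSV
#'
#' UTF-8 comma-separated with a header row; required columns `id, sex, age,
#' bmi, scoff_sick, scoff_control, scoff_one_stone, scoff_fat, scoff_food`,
#' optional `dsm5_diagnosis`. Unknown columns are preserved and passed
#' through.
#'
#' @param path Path to the CSV file.
#' @inheritParams validate_cohort
#' @return Validated data frame (see [validate_cohort()]).
#' @export
read_patient_csv <- function(path, permissive = FALSE) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  validate_cohort(records, permissive = permissive)
}

#' Write a patient cohort CSV
#'
#' Answers are written as 0/1; column order puts the required columns first.
#'
#' @param records Validated cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_patient_csv <- function(records, path) {
  known <- intersect(c(patient_columns(), "dsm5_diagnosis"), names(records))
  extra <- setdiff(names(records), known)
  utils::write.csv(records[, c(known, extra), drop = FALSE], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
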