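#' Patient-level cohort tables
#'
#' A cohort is a plain data frame with one row per patient and the
#' canonical columns below.  Times are whole days on the clock-forward
#' scale whose origin (day 0) is disease onset, defined as the date
#' erythema first developed.
#'
#' \describe{
#'   \item{patient_id}{opaque identifier (character).}
#'   \item{age_years}{non-negative integer.}
#'   \item{sex}{`"male"` or `"female"`.}
#'   \item{diagnosis}{`"SJS"` or `"TEN"`.}
#'   \item{drug_nsaids, drug_cold_remedies, drug_antibiotics,
#'     drug_anticonvulsants, drug_gout}{logical causative-drug exposure
#'     flags.}
#'   \item{severity_subscore}{systemic severity index subscore, 0--11.}
#'   \item{days_onset_to_initial}{days from onset to the first
#'     ophthalmological examination; may be negative when the eye exam
#'     preceded the erythema.}
#'   \item{days_initial_to_worst}{non-negative days from initial
#'     presentation to the worst-condition follow-up visit (0 when the
#'     grade never changed).}
#'   \item{grade_initial, grade_worst}{acute ocular severity grades 0--3 at
#'     initial presentation and at the worst-condition visit;
#'     `grade_worst >= grade_initial` always (no recovery transitions).}
#'   \item{days_onset_to_last_followup}{day of the final follow-up
#'     examination (censoring day for non-progressors).}
#'   \item{died}{logical.}
#'   \item{sequelae}{`"none"`/`"present"`, `NA` when the chronic-stage
#'     outcome is missing.}
#'   \item{visual_disturbance}{`"none"`, `"20/20-20/200"`,
#'     `"worse than 20/200"`, or `NA`.}
#'   \item{dry_eye}{`"none"`, `"mild"`, `"moderate"`, `"severe"`, or `NA`.}
#' }
#'
#' @name cohort-format
NULL

.cohort_columns <- c(
  "patient_id", "age_years", "sex", "diagnosis",
  "drug_nsaids", "drug_cold_remedies", "drug_antibiotics",
  "drug_anticonvulsants", "drug_gout", "severity_subscore",
  "days_onset_to_initial", "days_initial_to_worst",
  "grade_initial", "grade_worst", "days_onset_to_last_followup",
  "died", "sequelae", "visual_disturbance", "dry_eye")

#' Validate a patient cohort table
#'
#' Checks the canonical columns and the structural invariants: grades in
#' 0--3, no regression (`grade_worst >= grade_initial`), non-negative
#' progression interval, and final follow-up no earlier than the
#' worst-condition day.
#'
#' @param cohort a cohort data frame (see [cohort-format]).
#' @return The cohort, invisibly; errors describe the first violation.
#' @export
validate_cohort <- function(cohort) {
  if (!is.data.frame(cohort))
    stop("cohort must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols))
    stop("cohort is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(cohort) == 0L) return(invisible(cohort))
  if (anyDuplicated(cohort$patient_id))
    stop("duplicated patient_id in cohort", call. = FALSE)
  check_grade(cohort$grade_initial)
  check_grade(cohort$grade_worst)
  bad <- cohort$grade_worst < cohort$grade_initial
  if (any(bad))
    stop("grade_worst < grade_initial (severity regression) for: ",
         paste(cohort$patient_id[bad], collapse = ", "), call. = FALSE)
  if (any(cohort$days_initial_to_worst < 0))
    stop("days_initial_to_worst must be non-negative", call. = FALSE)
  bad <- cohort$days_onset_to_last_followup <
    cohort$days_onset_to_initial + cohort$days_initial_to_worst
  if (any(bad))
    stop("final follow-up precedes the worst-condition day for: ",
         paste(cohort$patient_id[bad], collapse = ", "), call. = FALSE)
  if (!all(cohort$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (!all(cohort$diagnosis %in% c("SJS", "TEN")))
    stop("diagnosis must be 'SJS' or 'TEN'", call. = FALSE)
  invisible(cohort)
}

#' Read / write a cohort CSV
#'
#' Round-trip safe plain-text serialization of a cohort table.  Missing
#' chronic-stage outcome fields are written as empty cells.
#'
#' @param path file path.
#' @param cohort a cohort data frame.
#' @return `read_cohort()` returns the cohort data frame; `write_cohort()`
#'   returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            colClasses = c(patient_id = "character"))
  for (col in grep("^drug_|^died$", names(cohort), value = TRUE))
    cohort[[col]] <- as.logical(cohort[[col]])
  for (col in c("sequelae", "visual_disturbance", "dry_eye"))
    if (col %in% names(cohort))
      cohort[[col]][!is.na(cohort[[col]]) & cohort[[col]] == ""] <- NA
  validate_cohort(cohort)
  cohort
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Apply the 30-day eligibility filters
#'
#' Excludes patients in whom the elapsed time from disease onset to the
#' initial ophthalmological examination, or from initial presentation to
#' the worst-condition follow-up visit, exceeds `max_days` (strictly more
#' than `max_days` days; boundary values are retained).
#'
#' @param cohort a cohort data frame.
#' @param max_days maximum admissible elapsed time in days (default 30).
#' @return A list with elements `eligible` (the retained cohort) and
#'   `exclusions` (a data frame naming each excluded `patient_id` and the
#'   `rule` that fired).
#' @examples
#' fx <- make_study_fixture()
#' flt <- apply_eligibility_filters(fx$cohort)
#' nrow(flt$eligible)    # 230
#' nrow(flt$exclusions)  # 17
#' @export
apply_eligibility_filters <- function(cohort, max_days = 30) {
  validate_cohort(cohort)
  stopifnot(length(max_days) == 1L, max_days >= 0)
  if (nrow(cohort) == 0L)
    return(list(eligible = cohort,
                exclusions = data.frame(patient_id = character(),
                                        rule = character())))
  r1 <- cohort$days_onset_to_initial > max_days
  r2 <- cohort$days_initial_to_worst > max_days
  rule <- character(nrow(cohort))
  rule[r2] <- sprintf("days_initial_to_worst > %s", max_days)
  rule[r1] <- sprintf("days_onset_to_initial > %s", max_days)
  rule[r1 & r2] <- sprintf("both elapsed times > %s", max_days)
  out <- r1 | r2
  list(eligible = cohort[!out, , drop = FALSE],
       exclusions = data.frame(patient_id = cohort$patient_id[out],
                               rule = rule[out],
                               stringsAsFactors = FALSE))
}

#' Cross-tabulate initial against worst-condition grade
#'
#' The 4 x 4 transition count matrix of acute ocular severity: cell (i, j)
#' counts patients with grade i at initial presentation and grade j at the
#' worst-condition follow-up visit.  Because severity never regresses, the
#' lower triangle is structurally zero.
#'
#' @param cohort an eligible cohort data frame.
#' @return Integer matrix with grade labels as dimnames
#'   (rows = initial, columns = worst).
#' @examples
#' fx <- make_study_fixture()
#' elig <- apply_eligibility_filters(fx$cohort)$eligible
#' build_transition_table(elig)["mild", ]   # 0 74 19 4
#' @export
build_transition_table <- function(cohort) {
  validate_cohort(cohort)
  tab <- table(factor(cohort$grade_initial, levels = 0:3),
               factor(cohort$grade_worst, levels = 0:3))
  m <- matrix(as.integer(tab), 4, 4,
              dimnames = list(initial = .grade_labels,
                              worst = .grade_labels))
  m
}

# Numeric design matrix of the nine model covariates, rows aligned
# with the cohort.
covariate_matrix <- function(cohort) {
  cbind(
    age_years = as.numeric(cohort$age_years),
    sex_female = as.numeric(cohort$sex == "female"),
    diagnosis_ten = as.numeric(cohort$diagnosis == "TEN"),
    drug_nsaids = as.numeric(cohort$drug_nsaids),
    drug_cold_remedies = as.numeric(cohort$drug_cold_remedies),
    drug_antibiotics = as.numeric(cohort$drug_antibiotics),
    drug_anticonvulsants = as.numeric(cohort$drug_anticonvulsants),
    drug_gout = as.numeric(cohort$drug_gout),
    severity_subscore = as.numeric(cohort$severity_subscore)
  )
}
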