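#' Acute ocular severity grades and the three-state model
#'
#' Acute-stage ocular surface findings in SJS/TEN are graded 0--3:
#' Grade 0 "none", Grade 1 "mild" (conjunctival hyperemia), Grade 2 "severe"
#' (pseudomembrane formation or an ocular surface epithelial defect) and
#' Grade 3 "very severe" (both).  For event-history modelling Grades 2 and 3
#' are handled as one category, giving a progressive three-state model:
#' state 0 (none), state 1 (mild) and the absorbing state 2
#' (severe/very severe), with allowed transitions 0->1, 0->2 and 1->2.
#'
#' @param value integer grade(s) in `0:3`.
#' @return `grade_label()` returns the character label(s);
#'   `grade_to_state()` returns the model state(s) in `0:2`.
#' @examples
#' grade_to_state(0:3)   # 0 1 2 2
#' grade_label(2)        # "severe"
#' @name grades
NULL

.grade_labels <- c("none", "mild", "severe", "very severe")
.state_labels <- c("none", "mild", "severe/very severe")

#' @rdname grades
#' @export
grade_label <- function(value) {
  check_grade(value)
  .grade_labels[value + 1L]
}

#' @rdname grades
#' @export
grade_to_state <- function(value) {
  check_grade(value)
  as.integer(pmin(value, 2L))
}

check_grade <- function(value) {
  if (length(value) == 0L || anyNA(value) || !all(value %in% 0:3))
    stop("acute ocular severity grades must be integers in 0..3", call. = FALSE)
  invisible(value)
}

#' Transition structure of the progressive three-state model
#'
#' The allowed state graph: 0->1 (none to mild), 0->2 (none to
#' severe/very severe) and 1->2 (mild to severe/very severe).  State 2 is
#' absorbing and no edges enter state 0 (the published cross-tabulation of
#' initial against worst-condition grade has an all-zero lower triangle, so
#' recovery transitions are not modelled and a record implying one is
#' treated as a data error).
#'
#' @return A data frame with one row per allowed transition and columns
#'   `trans` (1--3), `from`, `to` (states) and `label`.
#' @examples
#' transition_structure()
#' @export
transition_structure <- function() {
  data.frame(
    trans = 1:3,
    from = c(0L, 0L, 1L),
    to = c(1L, 2L, 2L),
    label = c("none -> mild",
              "none -> severe/very severe",
              "mild -> severe/very severe"),
    stringsAsFactors = FALSE
  )
}

#' Covariate vector of the transition-specific hazard model
#'
#' The nine covariates entering every transition-specific Cox model, in
#' fixed order: age at onset in years (untransformed), female sex (1 vs
#' male 0), TEN diagnosis (1 vs SJS 0), five causative-drug exposure flags
#' (NSAIDs, cold remedies, antibiotics, anticonvulsants, gout treatment;
#' 1 = exposed) and the systemic severity index subscore (0--11,
#' untransformed).
#'
#' @return Character vector of the nine covariate column names, with a
#'   `labels` attribute carrying display names.
#' @export
ocular_covariates <- function() {
  x <- c("age_years", "sex_female", "diagnosis_ten",
         "drug_nsaids", "drug_cold_remedies", "drug_antibiotics",
         "drug_anticonvulsants", "drug_gout", "severity_subscore")
  attr(x, "labels") <- c(
    "Age at onset", "Sex female (vs. male)", "Diagnosis TEN (vs. SJS)",
    "NSAIDs yes (vs. no)", "Cold remedies yes (vs. no)",
    "Antibiotics yes (vs. no)", "Anticonvulsants yes (vs. no)",
    "Treatment for gout yes (vs. no)", "Systemic severity index subscore")
  x
}

# Worst-grade analysis grouping: "0", "1", "2/3"
grade_group <- function(grade) {
  check_grade(grade)
  ifelse(grade >= 2L, "2/3", as.character(grade))
}
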