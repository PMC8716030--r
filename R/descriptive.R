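#' Fisher's exact test (2 x 2 and Freeman-Halton r x c)
#'
#' Two-sided exact test for independence in an r x c contingency table
#' with both margins fixed.  The p-value is the total (multivariate)
#' hypergeometric probability of all margin-compatible tables whose
#' probability does not exceed that of the observed table
#' (probability-mass ordering, the standard two-sided convention; mid-p
#' and doubling conventions differ and are not used).  The general r x c
#' case is handled by exhaustive enumeration over the free
#' `(r-1) x (c-1)` cells, subject to a configurable table-count budget.
#'
#' @param counts non-negative integer matrix (at least 2 x 2).
#' @param max_tables enumeration budget; exceeding it aborts with
#'   guidance (default 1e7; every table arising in a cohort of a few
#'   hundred patients falls far below it).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' # NSAID exposure by worst-grade group (grade 0/1 vs grade 2/3)
#' fisher_exact(matrix(c(31, 106, 39, 54), 2, 2, byrow = TRUE))  # ~0.0022
#' @export
fisher_exact <- function(counts, max_tables = 1e7) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(counts) < 2L || ncol(counts) < 2L)
    stop("table must be at least 2 x 2", call. = FALSE)
  rs <- rowSums(counts); cs <- colSums(counts)
  keep_r <- rs > 0; keep_c <- cs > 0
  counts <- counts[keep_r, keep_c, drop = FALSE]
  if (nrow(counts) < 2L || ncol(counts) < 2L) return(1)
  rs <- rowSums(counts); cs <- colSums(counts)
  n <- sum(counts)
  if (n < 1L) stop("empty table", call. = FALSE)
  logconst <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp_obs <- logconst - sum(lgamma(counts + 1))
  tol <- 1e-7
  budget <- new.env(parent = emptyenv())
  budget$count <- 0
  psum <- fh_enumerate(rs, cs, logconst, logp_obs + tol, budget, max_tables)
  min(1, psum)
}

# Depth-first enumeration of all tables with the given margins, row by
# row; accumulates the probability of tables with log-probability <=
# threshold.  Row patterns are enumerated recursively cell by cell.
fh_enumerate <- function(rs, cs, logconst, logp_thresh, budget,
                         max_tables) {
  r <- length(rs)
  acc <- 0
  recurse_row <- function(row_idx, rem_cols, lg_acc) {
    if (row_idx == r) {
      # last row fully determined by the remaining column margins
      budget$count <- budget$count + 1
      if (budget$count > max_tables)
        stop("Fisher exact enumeration exceeds the table budget (",
             format(max_tables, scientific = FALSE),
             "); collapse sparse categories or raise max_tables",
             call. = FALSE)
      logp <- logconst - lg_acc - sum(lgamma(rem_cols + 1))
      if (logp <= logp_thresh) acc <<- acc + exp(logp)
      return(invisible())
    }
    target <- rs[row_idx]
    c_ <- length(rem_cols)
    cell <- integer(c_)
    fill_cell <- function(j, left) {
      if (j == c_) {
        if (left > rem_cols[c_]) return(invisible())
        cell[c_] <<- left
        recurse_row(row_idx + 1L, rem_cols - cell,
                    lg_acc + sum(lgamma(cell + 1)))
        return(invisible())
      }
      lo <- max(0L, left - sum(rem_cols[(j + 1L):c_]))
      hi <- min(rem_cols[j], left)
      if (lo > hi) return(invisible())
      for (v in lo:hi) {
        cell[j] <<- v
        fill_cell(j + 1L, left - v)
      }
      invisible()
    }
    fill_cell(1L, target)
    invisible()
  }
  recurse_row(1L, cs, 0)
  acc
}

#' Wilcoxon rank-sum test
#'
#' Two-sided test comparing two independent samples via the rank sum of
#' the first sample (midranks for ties).  With combined sample size at
#' most `exact_limit` (default 20) the exact permutation distribution of
#' the rank sum over all subset assignments is enumerated and the
#' two-sided p-value is twice the smaller tail (capped at 1); otherwise a
#' normal approximation with tie correction and a 0.5 continuity
#' correction is used.
#'
#' @param x,y numeric samples (both non-empty).
#' @param exact_limit combined-size threshold for exact enumeration.
#' @return Two-sided p-value in (0, 1].
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)   # 0.1 (exact)
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 20L) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  z <- c(x, y)
  if (length(unique(z)) == 1L) {
    warning("all values identical across both samples; p = 1",
            call. = FALSE)
    return(1)
  }
  rk <- rank(z)
  nx <- length(x); ny <- length(y); n <- nx + ny
  W <- sum(rk[seq_len(nx)])
  if (n <= exact_limit) {
    sums <- colSums(matrix(rk[utils::combn(n, nx)], nrow = nx))
    eps <- 1e-9
    p_lo <- mean(sums <= W + eps)
    p_hi <- mean(sums >= W - eps)
    return(min(1, 2 * min(p_lo, p_hi)))
  }
  EW <- nx * (n + 1) / 2
  tie_t <- table(rk)
  VW <- nx * ny / 12 * ((n + 1) - sum(tie_t^3 - tie_t) / (n * (n - 1)))
  num <- W - EW
  zstat <- (num - sign(num) * 0.5) / sqrt(VW)
  min(1, 2 * stats::pnorm(-abs(zstat)))
}

#' Grouped summaries by worst-condition severity grade
#'
#' Reproduces the descriptive layer of the study tables: patient
#' characteristics and chronic-stage outcomes by worst-condition severity
#' group (Grade 0, Grade 1, Grade 2/3).  Characteristics use all patients
#' in the group as denominator; chronic-stage outcome percentages use the
#' non-missing denominator (patients with missing ocular-sequelae data
#' are excluded from the denominator of sequelae, visual-disturbance and
#' dry-eye rows).
#'
#' @param cohort an eligible cohort data frame.
#' @return An object of class `"grade_summary"`: list with `n` (group
#'   sizes), `characteristics` and `outcomes` (data frames of count /
#'   percentage or median / range per group) and `outcome_denominator`
#'   (non-missing group sizes).
#' @examples
#' fx <- make_study_fixture()
#' elig <- apply_eligibility_filters(fx$cohort)$eligible
#' s <- summarize_by_grade(elig)
#' s$outcomes[s$outcomes$variable == "ocular_sequelae", ]
#' @export
summarize_by_grade <- function(cohort) {
  validate_cohort(cohort)
  grp <- factor(grade_group(cohort$grade_worst), levels = c("0", "1", "2/3"))
  n <- as.integer(table(grp))
  names(n) <- levels(grp)

  count_row <- function(variable, flag, denom) {
    cnt <- as.integer(tapply(flag, grp, sum, na.rm = TRUE))
    cnt[is.na(cnt)] <- 0L
    pct <- ifelse(denom > 0, 100 * cnt / denom, NA_real_)
    data.frame(variable = variable,
               g0_n = cnt[1], g0_pct = pct[1],
               g1_n = cnt[2], g1_pct = pct[2],
               g23_n = cnt[3], g23_pct = pct[3],
               stringsAsFactors = FALSE)
  }
  median_row <- function(variable, x) {
    med <- tapply(x, grp, stats::median)
    lo <- tapply(x, grp, min)
    hi <- tapply(x, grp, max)
    data.frame(variable = variable,
               g0_n = med[1], g0_pct = NA, g1_n = med[2], g1_pct = NA,
               g23_n = med[3], g23_pct = NA,
               stringsAsFactors = FALSE,
               row.names = NULL)
  }

  chars <- rbind(
    median_row("age_years_median", cohort$age_years),
    count_row("sex_male", cohort$sex == "male", n),
    count_row("diagnosis_ten", cohort$diagnosis == "TEN", n),
    count_row("drug_nsaids", cohort$drug_nsaids, n),
    count_row("drug_cold_remedies", cohort$drug_cold_remedies, n),
    count_row("drug_antibiotics", cohort$drug_antibiotics, n),
    count_row("drug_anticonvulsants", cohort$drug_anticonvulsants, n),
    count_row("drug_gout", cohort$drug_gout, n),
    median_row("days_onset_to_initial_median", cohort$days_onset_to_initial),
    median_row("severity_subscore_median", cohort$severity_subscore)
  )

  miss <- is.na(cohort$sequelae)
  denom <- as.integer(tapply(!miss, grp, sum))
  denom[is.na(denom)] <- 0L
  outc <- rbind(
    count_row("death", cohort$died, n),
    count_row("ocular_sequelae",
              !miss & cohort$sequelae == "present", denom),
    count_row("visual_disturbance_20_20_to_20_200",
              !is.na(cohort$visual_disturbance) &
                cohort$visual_disturbance == "20/20-20/200", denom),
    count_row("visual_disturbance_worse_than_20_200",
              !is.na(cohort$visual_disturbance) &
                cohort$visual_disturbance == "worse than 20/200", denom),
    count_row("any_visual_disturbance",
              !is.na(cohort$visual_disturbance) &
                cohort$visual_disturbance != "none", denom),
    count_row("dry_eye_mild",
              !is.na(cohort$dry_eye) & cohort$dry_eye == "mild", denom),
    count_row("dry_eye_moderate",
              !is.na(cohort$dry_eye) & cohort$dry_eye == "moderate", denom),
    count_row("dry_eye_severe",
              !is.na(cohort$dry_eye) & cohort$dry_eye == "severe", denom),
    count_row("any_dry_eye",
              !is.na(cohort$dry_eye) & cohort$dry_eye != "none", denom),
    count_row("missing_sequelae_data", miss, rep(NA_integer_, 3))
  )
  rownames(chars) <- rownames(outc) <- NULL
  structure(list(n = n, characteristics = chars, outcomes = outc,
                 outcome_denominator = stats::setNames(denom, levels(grp))),
            class = "grade_summary")
}

#' @export
print.grade_summary <- function(x, ...) {
  cat("Summary by worst-condition acute ocular severity group\n")
  cat(sprintf("  N: Grade 0 = %d, Grade 1 = %d, Grade 2/3 = %d\n",
              x$n[1], x$n[2], x$n[3]))
  cat("\nCharacteristics (count or median per group):\n")
  print(x$characteristics, digits = 3)
  cat(sprintf("\nOutcomes (non-missing denominators %d / %d / %d):\n",
              x$outcome_denominator[1], x$outcome_denominator[2],
              x$outcome_denominator[3]))
  print(x$outcomes, digits = 3)
  invisible(x)
}

.continuous_variables <- c("age_years", "days_onset_to_initial",
                           "days_initial_to_worst", "severity_subscore",
                           "days_onset_to_last_followup")
.categorical_variables <- c("sex", "diagnosis", "drug_nsaids",
                            "drug_cold_remedies", "drug_antibiotics",
                            "drug_anticonvulsants", "drug_gout", "died",
                            "sequelae", "visual_disturbance", "dry_eye")

#' Compare a variable between worst-grade groups 0/1 and 2/3
#'
#' Univariate comparison on the Grade 0/1 versus Grade 2/3 collapse of the
#' worst-condition severity score: continuous variables are dispatched to
#' the Wilcoxon rank-sum test, categorical variables to Fisher's exact
#' test on the cross-tabulation of the fully displayed category structure
#' (missing values dropped).
#'
#' @param cohort an eligible cohort data frame.
#' @param variable a cohort column name.
#' @return Two-sided p-value.
#' @examples
#' fx <- make_study_fixture()
#' elig <- apply_eligibility_filters(fx$cohort)$eligible
#' round(grade_group_compare(elig, "drug_nsaids"), 3)   # 0.002
#' @export
grade_group_compare <- function(cohort, variable) {
  validate_cohort(cohort)
  if (!variable %in% c(.continuous_variables, .categorical_variables))
    stop("unknown variable: ", variable, call. = FALSE)
  severe <- cohort$grade_worst >= 2L
  v <- cohort[[variable]]
  if (variable %in% .continuous_variables) {
    if (length(unique(v)) == 1L) {
      warning("constant variable; p = 1", call. = FALSE)
      return(1)
    }
    return(wilcoxon_rank_sum(v[!severe], v[severe]))
  }
  keep <- !is.na(v)
  tab <- table(v[keep], severe[keep])
  if (nrow(tab) < 2L) {
    warning("constant variable; p = 1", call. = FALSE)
    return(1)
  }
  fisher_exact(as.matrix(tab))
}
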