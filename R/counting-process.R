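#' Convert a cohort to transition-specific counting-process data
#'
#' Expands each patient into at-risk intervals `(entry, exit]` per allowed
#' transition under the clock-forward Markov convention (all times in days
#' since disease onset):
#'
#' * While in state 0 a patient contributes one interval for each of the
#'   competing transitions 0->1 and 0->2 over the same `(0, t]`; at most one
#'   of the two rows is an event.
#' * A patient whose initial-presentation grade maps to state 1 or 2 has
#'   that transition recorded as an event at `days_onset_to_initial`; a
#'   patient presenting in state 0 who later worsens has the event at
#'   `days_onset_to_initial + days_initial_to_worst`.
#' * A state-1 occupant enters the 1->2 risk set with delayed entry at the
#'   day state 1 was reached, with an event at the worst-condition day iff
#'   the worst grade maps to state 2, else censoring at the final
#'   follow-up examination.
#' * Non-progressors are censored at `days_onset_to_last_followup`.
#' * Zero-length intervals (an event or censoring falling on the entry
#'   day, e.g. day-0 presentation or worst = initial day) have their exit
#'   offset by +0.5 day so that `entry < exit` strictly.
#'
#' Patients evaluated ophthalmologically before the onset of erythema
#' (`days_onset_to_initial < 0`) are excluded from the multi-state
#' analysis, as are records with a missing model covariate
#' (complete-case); both exclusions are logged in the `dropped` attribute.
#'
#' @param cohort an eligible cohort data frame (see [cohort-format]).
#' @param offset half-day offset applied to zero-length intervals.
#' @return A data frame of class `"counting_process"` with columns
#'   `patient_id`, `trans` (1--3), `from`, `to`, `entry`, `exit`, `status`
#'   (1 = event, 0 = censored) and the nine covariate columns, plus
#'   attributes `dropped` (exclusion log) and `n_subjects`.
#' @examples
#' fx <- make_study_fixture()
#' elig <- apply_eligibility_filters(fx$cohort)$eligible
#' cp <- to_counting_process(elig)
#' attr(cp, "n_subjects")                      # 227
#' with(cp, tapply(status, trans, sum))        # 100 68 23
#' @export
to_counting_process <- function(cohort, offset = 0.5) {
  validate_cohort(cohort)
  dropped <- data.frame(patient_id = character(), rule = character(),
                        stringsAsFactors = FALSE)
  neg <- cohort$days_onset_to_initial < 0
  if (any(neg)) {
    dropped <- rbind(dropped, data.frame(
      patient_id = cohort$patient_id[neg],
      rule = "ocular evaluation before erythema onset (negative days)",
      stringsAsFactors = FALSE))
    cohort <- cohort[!neg, , drop = FALSE]
  }
  X <- covariate_matrix(cohort)
  inc <- stats::complete.cases(X)
  if (any(!inc)) {
    dropped <- rbind(dropped, data.frame(
      patient_id = cohort$patient_id[!inc],
      rule = "missing model covariate (complete-case analysis)",
      stringsAsFactors = FALSE))
    cohort <- cohort[inc, , drop = FALSE]
    X <- X[inc, , drop = FALSE]
  }

  n <- nrow(cohort)
  s_init <- grade_to_state(cohort$grade_initial)
  s_worst <- grade_to_state(cohort$grade_worst)
  t_init <- as.numeric(cohort$days_onset_to_initial)
  t_worst <- t_init + as.numeric(cohort$days_initial_to_worst)
  t_cens <- as.numeric(cohort$days_onset_to_last_followup)

  # state-0 interval, shared by the two competing transitions: exit at
  # the day the patient is first seen/known out of state 0, else at
  # censoring; the destination (0 = none) marks which row is the event
  exit0 <- ifelse(s_init > 0L, t_init,
                  ifelse(s_worst > 0L, t_worst, t_cens))
  exit0[exit0 <= 0] <- offset
  dest0 <- ifelse(s_init > 0L, s_init, s_worst)

  # state-1 occupancy: presented mild, or reached (and stayed) mild
  in1 <- s_init == 1L | (s_init == 0L & s_worst == 1L)
  e1 <- exit0[in1]
  ev1 <- s_init[in1] == 1L & s_worst[in1] == 2L
  exit1 <- ifelse(ev1,
                  pmax(t_worst[in1], e1 + offset),
                  pmax(t_cens[in1], e1 + offset))

  idx <- c(seq_len(n), seq_len(n), which(in1))
  out <- data.frame(
    patient_id = cohort$patient_id[idx],
    trans = rep(c(1L, 2L, 3L), c(n, n, sum(in1))),
    from = rep(c(0L, 0L, 1L), c(n, n, sum(in1))),
    to = rep(c(1L, 2L, 2L), c(n, n, sum(in1))),
    entry = c(rep(0, 2L * n), e1),
    exit = c(exit0, exit0, exit1),
    status = c(as.integer(dest0 == 1L), as.integer(dest0 == 2L),
               as.integer(ev1)),
    stringsAsFactors = FALSE)
  out <- cbind(out, X[idx, , drop = FALSE])
  ord <- order(match(out$patient_id, cohort$patient_id), out$trans)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  attr(out, "n_subjects") <- n
  class(out) <- c("counting_process", "data.frame")
  out
}

#' @export
print.counting_process <- function(x, ...) {
  cat(sprintf(
    "Counting-process data: %d subjects, %d rows\n",
    attr(x, "n_subjects"), nrow(x)))
  tr <- transition_structure()
  ev <- tapply(x$status, factor(x$trans, levels = 1:3), sum)
  at <- tapply(x$patient_id, factor(x$trans, levels = 1:3),
               function(z) length(unique(z)))
  for (k in 1:3)
    cat(sprintf("  %-28s at risk %3d, events %3d\n",
                tr$label[k],
                ifelse(is.na(at[k]), 0L, at[k]),
                ifelse(is.na(ev[k]), 0L, ev[k])))
  d <- attr(x, "dropped")
  if (!is.null(d) && nrow(d))
    cat(sprintf("  excluded from analysis: %d (see attr 'dropped')\n",
                nrow(d)))
  invisible(x)
}

#' Export counting-process data as CSV
#'
#' Long-format export (one at-risk interval per row) with columns
#' `patient_id`, `from_state`, `to_state`, `entry`, `exit`, `status` and
#' the nine covariates.
#'
#' @param cp a `"counting_process"` object.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_counting_process <- function(cp, path) {
  out <- data.frame(patient_id = cp$patient_id, from_state = cp$from,
                    to_state = cp$to, entry = cp$entry, exit = cp$exit,
                    status = cp$status, stringsAsFactors = FALSE)
  out <- cbind(out, cp[, ocular_covariates(), drop = FALSE])
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
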