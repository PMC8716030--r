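#' Fit the three-state ocular severity progression model
#'
#' The package's central fitting function.  Takes a patient cohort (or
#' ready-made counting-process data) and fits one multivariate Cox
#' proportional-hazards model per allowed transition (none->mild,
#' none->severe/very severe, mild->severe/very severe), each adjusted for
#' the nine-component covariate vector of [ocular_covariates()] (or a
#' user-supplied subset).  The three baseline hazards are left completely
#' unrelated (separate per-transition fits), which for transition-specific
#' covariate effects is equivalent to a single stratified fit.
#'
#' @param data an eligible cohort data frame (converted internally via
#'   [to_counting_process()]) or a `"counting_process"` object.
#' @param covariates covariate column names (default the nine-component
#'   model vector).
#' @param ties tie-handling method passed to [fit_cox()].
#' @param ... further arguments passed to [fit_cox()].
#' @return An object of class `"msm_cox"`: list with `fits` (three
#'   `"ocm_coxfit"` objects), `data` (the counting-process rows),
#'   `covariates`, `covariate_range`, `n_subjects`, `ties` and `call`.
#'   Methods: [print.msm_cox()], [summary.msm_cox()], `coef`, `vcov`,
#'   `confint`, [predict.msm_cox()], [plot.msm_cox()],
#'   [residuals.msm_cox()].
#' @examples
#' fx <- make_study_fixture()
#' elig <- apply_eligibility_filters(fx$cohort)$eligible
#' fit <- msm_cox(elig)
#' summary(fit)
#' @export
msm_cox <- function(data, covariates = ocular_covariates(),
                    ties = c("breslow", "efron"), ...) {
  ties <- match.arg(ties)
  cp <- if (inherits(data, "counting_process")) data
        else to_counting_process(data)
  fits <- lapply(1:3, function(k)
    fit_cox(cp, transition = k, ties = ties, covariates = covariates, ...))
  Xr <- apply(as.matrix(cp[, covariates, drop = FALSE]), 2L, range)
  structure(list(fits = fits, data = cp,
                 covariates = covariates,
                 covariate_range = Xr,
                 n_subjects = attr(cp, "n_subjects"),
                 ties = ties,
                 call = match.call()),
            class = "msm_cox")
}

#' @export
print.msm_cox <- function(x, ...) {
  cat("Three-state Markov model of acute ocular severity progression\n")
  cat(sprintf("  %d subjects; transition events: %s\n",
              x$n_subjects,
              paste(vapply(x$fits, function(f) f$n_events, integer(1)),
                    collapse = " / ")))
  cat("  transitions: ",
      paste(transition_structure()$label, collapse = "; "), "\n")
  cat("  (use summary() for per-transition hazard ratios)\n")
  invisible(x)
}

#' Summarize a fitted progression model
#'
#' Per-transition hazard ratios with 95% Wald confidence intervals and
#' two-sided p-values, laid out one block per transition.
#'
#' @param object an `"msm_cox"` fit.
#' @param ... unused.
#' @return An object of class `"summary.msm_cox"`: list of per-transition
#'   coefficient tables plus header counts.
#' @export
summary.msm_cox <- function(object, ...) {
  structure(list(
    tables = lapply(object$fits, coxfit_table),
    labels = transition_structure()$label,
    n_subjects = vapply(object$fits, function(f) f$n_subjects, integer(1)),
    n_events = vapply(object$fits, function(f) f$n_events, integer(1)),
    converged = vapply(object$fits, function(f) f$converged, logical(1)),
    ties = object$ties
  ), class = "summary.msm_cox")
}

#' @export
print.summary.msm_cox <- function(x, ...) {
  for (k in seq_along(x$tables)) {
    cat(sprintf("\nTransition %s  (N = %d, number of events: %d)%s\n",
                x$labels[k], x$n_subjects[k], x$n_events[k],
                if (x$converged[k]) "" else "  [NOT CONVERGED]"))
    print(format_hr_table(x$tables[[k]]), right = FALSE)
  }
  invisible(x)
}

#' @export
coef.msm_cox <- function(object, ...) {
  tr <- transition_structure()
  out <- matrix(NA_real_, 3, length(object$covariates),
                dimnames = list(tr$label, object$covariates))
  for (k in 1:3) {
    b <- object$fits[[k]]$coefficients
    out[k, names(b)] <- b
  }
  out
}

#' @export
vcov.msm_cox <- function(object, ...) lapply(object$fits, vcov)

#' @export
confint.msm_cox <- function(object, parm, level = 0.95, ...) {
  lapply(object$fits, confint, level = level)
}

#' Predicted transition probabilities from a fitted model
#'
#' Aalen-Johansen product integral with each transition's Breslow baseline
#' hazard scaled by `exp(beta' x)` for the supplied covariate profile; the
#' semi-parametric counterpart of the nonparametric [aalen_johansen()]
#' estimate.
#'
#' @param object an `"msm_cox"` fit.
#' @param profile named numeric vector of covariate values; defaults to
#'   the reference profile (all zero).  A profile outside the observed
#'   covariate range triggers a warning, not a rejection.
#' @param s start time (default 0, disease onset).
#' @param times evaluation grid (default days 0--30).
#' @param ... unused.
#' @return A `"transprob"` object (`flavor = "cox_predicted"`).
#' @export
predict.msm_cox <- function(object, profile = NULL, s = 0, times = 0:30,
                            ...) {
  if (is.null(profile))
    profile <- stats::setNames(numeric(length(object$covariates)),
                               object$covariates)
  predict_from_cox(object$fits, profile = profile, s = s, times = times,
                   covariate_range = object$covariate_range)
}

#' Plot predicted stacked probability curves
#'
#' @param x an `"msm_cox"` fit.
#' @param profile,s,times passed to [predict.msm_cox()].
#' @param from start state for the stacked bands (default 0).
#' @param ... passed to [plot.transprob()].
#' @return The `"transprob"` object, invisibly.
#' @export
plot.msm_cox <- function(x, profile = NULL, s = 0, times = 0:30,
                         from = 0, ...) {
  est <- predict(x, profile = profile, s = s, times = times)
  plot(est, from = from, ...)
  invisible(est)
}

#' Martingale residuals of a fitted progression model
#'
#' Per counting-process row: observed event indicator minus the estimated
#' cumulative transition intensity accumulated over the row's at-risk
#' interval, `status - exp(beta' x) * (A0(exit) - A0(entry))`.  Within
#' each transition the residuals sum to numerical zero.
#'
#' @param object an `"msm_cox"` fit.
#' @param ... unused.
#' @return Numeric vector aligned with the rows of `object$data`.
#' @export
residuals.msm_cox <- function(object, ...) {
  cp <- object$data
  res <- numeric(nrow(cp))
  for (k in 1:3) {
    f <- object$fits[[k]]
    idx <- which(cp$trans == k)
    X <- as.matrix(cp[idx, names(f$coefficients), drop = FALSE])
    X <- sweep(X, 2L, f$baseline_center)
    lp <- drop(X %*% f$coefficients)
    ch <- f$baseline_cumhaz
    res[idx] <- cp$status[idx] -
      exp(lp) * (cumhaz_at(ch, cp$exit[idx]) - cumhaz_at(ch, cp$entry[idx]))
  }
  res
}

#' Export per-transition fit results as JSON
#'
#' One array per transition mirroring the published hazard-ratio table
#' layout: covariate, HR, 95% CI bounds and p-value.
#'
#' @param object an `"msm_cox"` fit.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_msm_json <- function(object, path) {
  tr <- transition_structure()
  out <- lapply(1:3, function(k) {
    f <- object$fits[[k]]
    tab <- coxfit_table(f)
    list(transition = tr$label[k],
         n_subjects = f$n_subjects,
         n_events = f$n_events,
         converged = f$converged,
         estimates = tab)
  })
  names(out) <- sprintf("transition_%d", 1:3)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
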