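#' Aalen-Johansen transition probability estimates
#'
#' Nonparametric estimate of the transition probability matrix
#' `P(s, t)` of the multi-state process: the product integral over the
#' distinct event times `u` in `(s, t]` of `(I + dA(u))`, where the
#' off-diagonal entries of `dA(u)` are the Nelson-Aalen increments
#' (events at u over subjects at risk in the source state just before u)
#' and each diagonal entry is the negative row sum.  Every factor is a
#' row-stochastic matrix, hence so is `P(s, t)`; `P(s, s)` is the
#' identity and the absorbing-state row stays `(0, 0, 1)`.
#'
#' Should a transition event ever coincide with an empty source-state
#' risk set (impossible for data built by [to_counting_process()], but
#' conceivable for hand-made rows), the increment is skipped with a
#' warning and the probability mass is frozen.
#'
#' @param rows counting-process rows (all transitions together), e.g.
#'   from [to_counting_process()].
#' @param s start time in days (default 0, disease onset).
#' @param times evaluation grid; default integer days 0--30, the window
#'   over which acute progression is described.
#' @param n_states number of states (default 3).
#' @return An object of class `"transprob"`: list with `s`, `times`,
#'   `P` (array `n_states x n_states x length(times)`), `flavor`
#'   (`"nonparametric"`) and optional `stratum` label.
#' @examples
#' fx <- make_study_fixture()
#' cp <- to_counting_process(apply_eligibility_filters(fx$cohort)$eligible)
#' aj <- aalen_johansen(cp)
#' round(aj$P[1, , length(aj$times)], 3)  # state occupation from state 0 at day 30
#' @export
aalen_johansen <- function(rows, s = 0, times = 0:30, n_states = 3L) {
  stopifnot(s >= 0, all(times >= s))
  times <- sort(unique(times))
  tr <- transition_structure()
  # distinct event times in (s, max(times)]
  ev <- rows$status == 1
  ut <- sort(unique(rows$exit[ev]))
  ut <- ut[ut > s & ut <= max(times)]
  # unique per-patient source-state intervals (the two competing state-0
  # rows duplicate one occupancy interval)
  occ <- rows[!duplicated(paste(rows$patient_id, rows$from)),
              c("from", "entry", "exit"), drop = FALSE]
  P <- diag(n_states)
  out <- array(0, dim = c(n_states, n_states, length(times)),
               dimnames = list(from = .state_labels[seq_len(n_states)],
                               to = .state_labels[seq_len(n_states)],
                               t = times))
  gi <- 1L
  record_until <- function(gi, tmax, P) {
    while (gi <= length(times) && times[gi] <= tmax) {
      out[, , gi] <<- P
      gi <- gi + 1L
    }
    gi
  }
  for (u in ut) {
    gi <- record_until(gi, u - 1e-12, P)
    dA <- matrix(0, n_states, n_states)
    for (k in seq_len(nrow(tr))) {
      q <- tr$from[k]; r <- tr$to[k]
      if (q + 1L > n_states || r + 1L > n_states) next
      dk <- sum(ev & rows$trans == k & rows$exit == u)
      if (dk == 0L) next
      Y <- sum(occ$from == q & occ$entry < u & occ$exit >= u)
      if (Y == 0L) {
        warning(sprintf(
          "empty state-%d risk set at t = %g; increment skipped", q, u),
          call. = FALSE)
        next
      }
      dA[q + 1L, r + 1L] <- dA[q + 1L, r + 1L] + dk / Y
    }
    diag(dA) <- -rowSums(dA)
    P <- P %*% (diag(n_states) + dA)
    gi <- record_until(gi, u, P)
  }
  record_until(gi, Inf, P)
  structure(list(s = s, times = times, P = out,
                 flavor = "nonparametric", stratum = NULL),
            class = "transprob")
}

#' Stratified Aalen-Johansen estimates (age x NSAID exposure)
#'
#' Splits the cohort into the four strata defined by an age cut-off
#' (default 45 years, set on clinical impression in the source study) and
#' NSAID exposure, and estimates nonparametric transition probabilities
#' within each stratum by subsetting.  Panels are ordered (a) age >= cutoff
#' without NSAIDs, (b) age >= cutoff with NSAIDs, (c) age < cutoff without
#' NSAIDs, (d) age < cutoff with NSAIDs.
#'
#' @param cohort an eligible cohort data frame.
#' @param age_cutoff age threshold in years (default 45).
#' @param s,times,... passed to [aalen_johansen()].
#' @return Named list of `"transprob"` objects (empty strata are omitted
#'   with a warning).
#' @export
stratified_aj <- function(cohort, age_cutoff = 45, s = 0, times = 0:30,
                          ...) {
  validate_cohort(cohort)
  older <- cohort$age_years >= age_cutoff
  strata <- list(older & !cohort$drug_nsaids,
                 older & cohort$drug_nsaids,
                 !older & !cohort$drug_nsaids,
                 !older & cohort$drug_nsaids)
  names(strata) <- c(
    sprintf("age>=%s, NSAIDs no", age_cutoff),
    sprintf("age>=%s, NSAIDs yes", age_cutoff),
    sprintf("age<%s, NSAIDs no", age_cutoff),
    sprintf("age<%s, NSAIDs yes", age_cutoff))
  out <- list()
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    if (!any(idx)) {
      warning("empty stratum omitted: ", nm, call. = FALSE)
      next
    }
    cp <- to_counting_process(cohort[idx, , drop = FALSE])
    est <- aalen_johansen(cp, s = s, times = times, ...)
    est$stratum <- nm
    out[[nm]] <- est
  }
  out
}

#' Cox-predicted transition probabilities for a covariate profile
#'
#' Semi-parametric analogue of [aalen_johansen()]: the product integral is
#' evaluated with each transition's Breslow baseline increments scaled by
#' `exp(beta' x)` for the supplied covariate profile.  With all
#' coefficients zero and the reference (all-zero) profile this reduces to
#' the nonparametric estimate.
#'
#' @param fits list of three `"ocm_coxfit"` objects (transitions 1--3).
#' @param profile named numeric vector of raw covariate values (names as
#'   in [ocular_covariates()]; only the covariates present in each fit are
#'   used).
#' @param s start time (default 0).
#' @param times evaluation grid (default days 0--30).
#' @param covariate_range optional 2-row matrix (min/max per covariate)
#'   used to warn when the profile lies outside the observed range.
#' @return A `"transprob"` object with `flavor = "cox_predicted"`.
#' @export
predict_from_cox <- function(fits, profile, s = 0, times = 0:30,
                             covariate_range = NULL) {
  stopifnot(length(fits) == 3L)
  if (!all(vapply(fits, function(f) isTRUE(f$converged), logical(1))))
    stop("all three transition fits must have converged", call. = FALSE)
  if (!is.null(covariate_range)) {
    nm <- intersect(colnames(covariate_range), names(profile))
    low <- profile[nm] < covariate_range[1, nm]
    high <- profile[nm] > covariate_range[2, nm]
    if (any(low | high))
      warning("profile outside the observed covariate range: ",
              paste(nm[low | high], collapse = ", "), call. = FALSE)
  }
  times <- sort(unique(times))
  scaled <- lapply(fits, function(f) {
    b <- f$coefficients
    missing_cov <- setdiff(names(b), names(profile))
    if (length(missing_cov))
      stop("profile lacks covariate(s): ",
           paste(missing_cov, collapse = ", "), call. = FALSE)
    x <- profile[names(b)]
    if (!is.null(f$baseline_center)) x <- x - f$baseline_center
    lp <- sum(b * x)
    ch <- f$baseline_cumhaz
    list(time = ch$time, inc = ch$inc * exp(lp))
  })
  tr <- transition_structure()
  ut <- sort(unique(unlist(lapply(scaled, `[[`, "time"))))
  ut <- ut[ut > s & ut <= max(times)]
  P <- diag(3)
  out <- array(0, dim = c(3, 3, length(times)),
               dimnames = list(from = .state_labels, to = .state_labels,
                               t = times))
  gi <- 1L
  record_until <- function(gi, tmax, P) {
    while (gi <= length(times) && times[gi] <= tmax) {
      out[, , gi] <<- P
      gi <- gi + 1L
    }
    gi
  }
  for (u in ut) {
    gi <- record_until(gi, u - 1e-12, P)
    dA <- matrix(0, 3, 3)
    for (k in 1:3) {
      i <- match(u, scaled[[k]]$time)
      if (!is.na(i))
        dA[tr$from[k] + 1L, tr$to[k] + 1L] <- scaled[[k]]$inc[i]
    }
    # a predicted increment may exceed 1 for extreme profiles; cap so the
    # factor stays a stochastic matrix
    rs <- rowSums(dA)
    over <- rs > 1
    if (any(over)) {
      dA[over, ] <- dA[over, , drop = FALSE] / rs[over]
      warning("hazard increment(s) capped at total mass 1", call. = FALSE)
    }
    diag(dA) <- diag(dA) - rowSums(dA)
    P <- P %*% (diag(3) + dA)
    gi <- record_until(gi, u, P)
  }
  record_until(gi, Inf, P)
  structure(list(s = s, times = times, P = out,
                 flavor = "cox_predicted", stratum = NULL,
                 profile = profile),
            class = "transprob")
}

#' Stacked cumulative probability bands
#'
#' Converts a transition-probability estimate into plot-ready stacked
#' bands for a given start state: the cumulative boundaries
#' `P(state 0)`, `P(state 0) + P(state 1)` and exactly 1 at every grid
#' point.
#'
#' @param est a `"transprob"` object.
#' @param from start state (default 0).
#' @return Data frame with columns `time`, `band_none`, `band_mild`,
#'   `band_severe` (the three cumulative boundaries).
#' @examples
#' # a probability row (0.5, 0.3, 0.2) stacks to boundaries 0.5, 0.8, 1.0
#' @export
stacked_curves <- function(est, from = 0) {
  stopifnot(inherits(est, "transprob"))
  p <- t(est$P[from + 1L, , , drop = TRUE])
  if (is.null(dim(p))) p <- matrix(p, nrow = 1L)
  b1 <- p[, 1]
  b2 <- p[, 1] + p[, 2]
  data.frame(time = est$times, band_none = b1, band_mild = b2,
             band_severe = rep(1, length(est$times)))
}

#' @export
print.transprob <- function(x, ...) {
  cat(sprintf("Aalen-Johansen transition probabilities (%s)\n", x$flavor))
  if (!is.null(x$stratum)) cat("  stratum:", x$stratum, "\n")
  cat(sprintf("  P(%g, t) on %d grid points, t in [%g, %g]\n",
              x$s, length(x$times), min(x$times), max(x$times)))
  tmax <- length(x$times)
  cat(sprintf("  P(%g, %g) =\n", x$s, x$times[tmax]))
  print(round(x$P[, , tmax], 4))
  invisible(x)
}

#' Plot stacked transition-probability bands
#'
#' Stacked-area rendering of the probability of occupying each severity
#' state over time, for subjects in `from` at the start time.
#'
#' @param x a `"transprob"` object.
#' @param from start state (default 0).
#' @param main plot title; defaults to the stratum label.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.transprob <- function(x, from = 0, main = NULL, ...) {
  b <- stacked_curves(x, from = from)
  if (is.null(main))
    main <- if (is.null(x$stratum)) sprintf("%s estimate", x$flavor)
            else x$stratum
  graphics::plot(range(b$time), c(0, 1), type = "n", xlab = "Days from onset",
                 ylab = "Probability", main = main, ...)
  tt <- c(b$time, rev(b$time))
  graphics::polygon(tt, c(b$band_mild, rev(b$band_severe)),
                    col = "#d62728", border = NA)
  graphics::polygon(tt, c(b$band_none, rev(b$band_mild)),
                    col = "#ff7f0e", border = NA)
  graphics::polygon(tt, c(rep(0, nrow(b)), rev(b$band_none)),
                    col = "#2ca02c", border = NA)
  graphics::legend("bottomleft",
                   legend = c("none", "mild", "severe/very severe"),
                   fill = c("#2ca02c", "#ff7f0e", "#d62728"), bg = "white")
  invisible(x)
}

#' Export transition probabilities as long-format CSV
#'
#' @param estimates a `"transprob"` object or a (possibly named) list of
#'   them, e.g. from [stratified_aj()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_transprob <- function(estimates, path) {
  if (inherits(estimates, "transprob")) estimates <- list(estimates)
  rows <- lapply(seq_along(estimates), function(i) {
    est <- estimates[[i]]
    lab <- if (!is.null(est$stratum)) est$stratum
           else if (!is.null(names(estimates))) names(estimates)[i]
           else est$flavor
    grid <- expand.grid(from_state = 0:2, to_state = 0:2,
                        t = est$times, KEEP.OUT.ATTRS = FALSE)
    grid$probability <- as.vector(est$P)
    cbind(stratum = lab, s = est$s, grid)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
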