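#' Fit a transition-specific Cox proportional-hazards model
#'
#' Maximizes the delayed-entry Cox partial likelihood for one transition of
#' the three-state model by Newton-Raphson with step-halving, using the
#' Breslow (default) or Efron approximation for tied event times.  The risk
#' set at an event time u comprises all at-risk intervals with
#' `entry < u <= exit` for the same transition.  Wald 95% confidence
#' intervals and two-sided p-values are reported per covariate, together
#' with the Breslow estimate of the cumulative baseline hazard.
#'
#' Covariate columns that are constant over the transition's rows carry no
#' information and are dropped with a warning.  A fit whose likelihood is
#' monotone in some coefficient (no finite maximizer, e.g. a covariate that
#' perfectly separates events) is flagged `converged = FALSE` with the
#' direction of divergence.
#'
#' @param rows a `"counting_process"` data frame (see
#'   [to_counting_process()]).
#' @param transition transition index 1--3, or a length-2 vector
#'   `c(from, to)`.
#' @param ties `"breslow"` (default, matching the SAS default used in the
#'   source analyses) or `"efron"`.
#' @param covariates covariate column names; default the nine-component
#'   model vector [ocular_covariates()].
#' @param max_iter,tol_loglik,tol_score Newton-Raphson controls:
#'   iteration cap, relative log-likelihood change and score max-norm
#'   convergence tolerances.
#' @return An object of class `"ocm_coxfit"`: a list with elements
#'   `coefficients`, `var` (inverse observed information), `hr`,
#'   `ci_lower`, `ci_upper`, `se`, `z`, `p_values`, `loglik` (null and
#'   maximized), `score_norm`, `n_subjects`, `n_events`, `baseline_cumhaz`
#'   (a `"cumhaz"` step function), `ties`, `converged`, `n_iter`,
#'   `dropped_covariates` and `transition`.
#' @examples
#' fx <- make_study_fixture()
#' cp <- to_counting_process(apply_eligibility_filters(fx$cohort)$eligible)
#' fit <- fit_cox(cp, transition = 3)
#' fit$n_events   # 23
#' @export
fit_cox <- function(rows, transition, ties = c("breslow", "efron"),
                    covariates = ocular_covariates(),
                    max_iter = 50L, tol_loglik = 1e-9, tol_score = 1e-6) {
  ties <- match.arg(ties)
  k <- resolve_transition(transition)
  d <- rows[rows$trans == k, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no counting-process rows for transition ", k, call. = FALSE)
  if (sum(d$status) == 0L)
    stop("zero events on transition ", k,
         "; the partial likelihood is undefined", call. = FALSE)
  X <- as.matrix(d[, covariates, drop = FALSE])
  storage.mode(X) <- "double"
  keep <- apply(X, 2L, function(col) diff(range(col)) > 0)
  if (!all(keep)) {
    warning("dropping constant covariate(s): ",
            paste(covariates[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  if (ncol(X) == 0L)
    stop("no non-constant covariates to fit", call. = FALSE)

  entry <- d$entry; exit <- d$exit; status <- d$status
  p <- ncol(X)
  beta <- numeric(p)
  ll0 <- cox_partial(beta, X, entry, exit, status, ties)$loglik
  ll_old <- ll0
  converged <- FALSE
  divergent <- FALSE
  iter <- 0L
  pl <- cox_partial(beta, X, entry, exit, status, ties)
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(pl$info, pl$score),
                     error = function(e) NULL)
    if (is.null(step)) { divergent <- TRUE; break }
    halve <- 0L
    repeat {
      beta_new <- beta + step
      pl_new <- cox_partial(beta_new, X, entry, exit, status, ties)
      if (is.finite(pl_new$loglik) && pl_new$loglik >= pl$loglik - 1e-12)
        break
      step <- step / 2
      halve <- halve + 1L
      if (halve > 30L) break
    }
    if (halve > 30L) break
    rel <- abs(pl_new$loglik - pl$loglik) /
      (abs(pl$loglik) + .Machine$double.eps)
    beta <- beta_new
    pl <- pl_new
    if (max(abs(pl$score)) < tol_score || rel < tol_loglik) {
      converged <- TRUE
      break
    }
    if (max(abs(beta)) > 20) { divergent <- TRUE; break }
  }
  # monotone partial likelihood: the maximizer drifts without bound
  # (|log HR| > 10 is far outside any plausible clinical effect)
  if (divergent || max(abs(beta)) > 10) {
    converged <- FALSE
    divergent <- TRUE
  }

  var <- tryCatch(solve(pl$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(var), 0))
  zq <- stats::qnorm(0.975)
  z <- beta / se
  fit <- structure(list(
    transition = k,
    transition_label = transition_structure()$label[k],
    coefficients = stats::setNames(beta, colnames(X)),
    var = var,
    se = stats::setNames(se, colnames(X)),
    hr = stats::setNames(exp(beta), colnames(X)),
    ci_lower = stats::setNames(exp(beta - zq * se), colnames(X)),
    ci_upper = stats::setNames(exp(beta + zq * se), colnames(X)),
    z = z,
    p_values = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
    loglik = c(null = ll0, maximized = pl$loglik),
    score_norm = max(abs(pl$score)),
    n_subjects = length(unique(d$patient_id)),
    n_events = sum(status),
    ties = ties,
    converged = converged,
    n_iter = iter,
    divergence_direction = if (divergent)
      stats::setNames(sign(beta), colnames(X)) else NULL,
    dropped_covariates = covariates[!keep]
  ), class = "ocm_coxfit")
  # baseline referenced to the covariate mean for numerical stability
  # (predictions rescale by exp(beta' (x - xbar)))
  fit$baseline_center <- colMeans(X)
  fit$baseline_cumhaz <- breslow_baseline(fit, rows,
                                          covariates = colnames(X),
                                          center = fit$baseline_center)
  fit
}

resolve_transition <- function(transition) {
  tr <- transition_structure()
  if (length(transition) == 2L) {
    k <- which(tr$from == transition[1] & tr$to == transition[2])
    if (length(k) != 1L)
      stop("no such transition: ", transition[1], " -> ", transition[2],
           call. = FALSE)
    return(k)
  }
  if (!transition %in% 1:3)
    stop("transition must be 1, 2, 3 or c(from, to)", call. = FALSE)
  as.integer(transition)
}

# Log partial likelihood, score and observed information for delayed-entry
# counting-process data, Breslow or Efron tie handling.  Direct loop over
# distinct event times: day-valued data keep that set small.
cox_partial <- function(beta, X, entry, exit, status, ties = "breslow") {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ev <- status == 1
  ut <- sort(unique(exit[ev]))
  p <- ncol(X)
  loglik <- 0
  score <- numeric(p)
  info <- matrix(0, p, p)
  for (u in ut) {
    at <- which(entry < u & exit >= u)
    du <- which(ev & exit == u)
    dn <- length(du)
    s0 <- sum(w[at])
    s1 <- colSums(w[at] * X[at, , drop = FALSE])
    s2 <- crossprod(X[at, , drop = FALSE], w[at] * X[at, , drop = FALSE])
    loglik <- loglik + sum(eta[du])
    if (ties == "breslow" || dn == 1L) {
      loglik <- loglik - dn * log(s0)
      m1 <- s1 / s0
      score <- score + colSums(X[du, , drop = FALSE]) - dn * m1
      info <- info + dn * (s2 / s0 - tcrossprod(m1))
    } else {
      # Efron: within-tie averaged removal of the tied events' mass
      d0 <- sum(w[du])
      d1 <- colSums(w[du] * X[du, , drop = FALSE])
      d2 <- crossprod(X[du, , drop = FALSE], w[du] * X[du, , drop = FALSE])
      score <- score + colSums(X[du, , drop = FALSE])
      for (l in seq_len(dn) - 1L) {
        f <- l / dn
        s0l <- s0 - f * d0
        s1l <- s1 - f * d1
        s2l <- s2 - f * d2
        loglik <- loglik - log(s0l)
        m1 <- s1l / s0l
        score <- score - m1
        info <- info + s2l / s0l - tcrossprod(m1)
      }
    }
  }
  list(loglik = loglik, score = score, info = info)
}

#' Nelson-Aalen cumulative-hazard increments for one transition
#'
#' Nonparametric cumulative transition hazard: at each event time u the
#' increment is the number of observed transitions at u divided by the
#' number of subjects at risk in the source state just before u.  These
#' increments are the `dA` entries feeding the Aalen-Johansen product
#' integral.
#'
#' @param rows a `"counting_process"` data frame.
#' @param transition transition index 1--3 or `c(from, to)`.
#' @return An object of class `"cumhaz"`: list with `time` (event times),
#'   `inc` (increments), `cumhaz` (their cumulative sum) and `transition`.
#' @export
nelson_aalen <- function(rows, transition) {
  k <- resolve_transition(transition)
  d <- rows[rows$trans == k, , drop = FALSE]
  if (nrow(d) == 0L)
    stop("no counting-process rows for transition ", k, call. = FALSE)
  ut <- sort(unique(d$exit[d$status == 1]))
  inc <- vapply(ut, function(u) {
    sum(d$status == 1 & d$exit == u) / sum(d$entry < u & d$exit >= u)
  }, numeric(1))
  new_cumhaz(k, ut, inc)
}

#' Breslow cumulative baseline hazard
#'
#' Semi-parametric baseline-hazard estimate at the fitted coefficients:
#' the increment at event time u is the number of events at u divided by
#' the sum of `exp(beta' x)` over the risk set.  With all coefficients
#' zero this reduces exactly to the Nelson-Aalen estimator.
#'
#' @param fit an `"ocm_coxfit"` (only `fit$coefficients` and
#'   `fit$transition` are used, so a zero-coefficient list works too).
#' @param rows the `"counting_process"` data the fit was built from.
#' @param covariates covariate columns matching `fit$coefficients`.
#' @param center optional covariate reference vector; when given, the
#'   baseline refers to a subject with `x = center` rather than `x = 0`.
#' @return A `"cumhaz"` object.
#' @export
breslow_baseline <- function(fit, rows,
                             covariates = names(fit$coefficients),
                             center = NULL) {
  k <- resolve_transition(fit$transition)
  d <- rows[rows$trans == k, , drop = FALSE]
  X <- as.matrix(d[, covariates, drop = FALSE])
  if (!is.null(center)) X <- sweep(X, 2L, center)
  w <- exp(drop(X %*% fit$coefficients))
  ut <- sort(unique(d$exit[d$status == 1]))
  inc <- vapply(ut, function(u) {
    at <- d$entry < u & d$exit >= u
    sum(d$status == 1 & d$exit == u) / sum(w[at])
  }, numeric(1))
  new_cumhaz(k, ut, inc)
}

new_cumhaz <- function(transition, time, inc) {
  structure(list(transition = transition, time = time, inc = inc,
                 cumhaz = cumsum(inc)),
            class = "cumhaz")
}

#' Evaluate a cumulative hazard step function
#'
#' @param ch a `"cumhaz"` object.
#' @param t times at which to evaluate `A(t)` (right-continuous step
#'   function, `A(0) = 0`).
#' @return Numeric vector of cumulative-hazard values.
#' @export
cumhaz_at <- function(ch, t) {
  idx <- findInterval(t, ch$time)
  c(0, ch$cumhaz)[idx + 1L]
}

#' @export
print.cumhaz <- function(x, ...) {
  cat(sprintf("Cumulative transition hazard (%s): %d event times, A(max) = %.4f\n",
              transition_structure()$label[x$transition],
              length(x$time),
              if (length(x$cumhaz)) max(x$cumhaz) else 0))
  invisible(x)
}

#' @export
print.ocm_coxfit <- function(x, digits = 3, ...) {
  cat(sprintf("Transition-specific Cox model: %s\n", x$transition_label))
  cat(sprintf("N = %d (number of events: %d), ties = %s%s\n",
              x$n_subjects, x$n_events, x$ties,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- coxfit_table(x)
  print(format_hr_table(tab, digits = digits), right = FALSE)
  invisible(x)
}

coxfit_table <- function(x) {
  data.frame(covariate = names(x$coefficients),
             hr = unname(x$hr),
             ci_lower = unname(x$ci_lower),
             ci_upper = unname(x$ci_upper),
             p = unname(x$p_values),
             stringsAsFactors = FALSE)
}

format_hr_table <- function(tab, digits = 3) {
  data.frame(covariate = tab$covariate,
             HR = sprintf("%.2f", tab$hr),
             `95% CI` = sprintf("%.2f-%.2f", tab$ci_lower, tab$ci_upper),
             `P-value` = sprintf("%.3f", tab$p),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' @export
coef.ocm_coxfit <- function(object, ...) object$coefficients

#' @export
vcov.ocm_coxfit <- function(object, ...) object$var

#' @export
confint.ocm_coxfit <- function(object, parm, level = 0.95, ...) {
  zq <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$coefficients - zq * object$se,
              object$coefficients + zq * object$se)
  colnames(ci) <- sprintf("%.1f %%", c((1 - level) / 2,
                                       1 - (1 - level) / 2) * 100)
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
logLik.ocm_coxfit <- function(object, ...) {
  structure(object$loglik[["maximized"]],
            df = length(object$coefficients), class = "logLik")
}
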