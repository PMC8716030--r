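make_transprob <- function(P_list, times, s = 0) {
  P <- array(unlist(P_list), dim = c(3, 3, length(times)))
  structure(list(s = s, times = times, P = P, flavor = "nonparametric",
                 stratum = NULL), class = "transprob")
}

test_that("no events in (s, t] gives the identity matrix", {
  rows <- make_cp_rows(entry = 0, exit = c(10, 12), status = c(0L, 0L),
                       x = 0, trans = 1L)
  est <- aalen_johansen(rows, s = 0, times = 0:5)
  for (i in seq_along(est$times))
    expect_equal(unname(est$P[, , i]), diag(3))
})

test_that("two-state reduction equals one minus Kaplan-Meier exactly", {
  # 6 subjects, events at 2, 4, 4 and censorings at 3, 5, 6
  exit <- c(2, 3, 4, 4, 5, 6)
  status <- c(1L, 0L, 1L, 1L, 0L, 0L)
  rows <- make_cp_rows(entry = 0, exit = exit, status = status, x = 0,
                       trans = 1L)
  est <- aalen_johansen(rows, s = 0, times = 0:6)
  # hand-computed Kaplan-Meier: S(2) = 5/6, S(4) = 5/6 * 2/4
  km_hand <- c(1, 1, 5 / 6, 5 / 6, 5 / 6 * 2 / 4, 5 / 6 * 2 / 4,
               5 / 6 * 2 / 4)
  expect_equal(unname(est$P[1, 1, ]), km_hand, tolerance = 1e-12)
  expect_equal(unname(est$P[1, 2, ]), 1 - km_hand, tolerance = 1e-12)
  # and against the reference survival implementation
  library(survival)
  km <- survfit(Surv(exit, status) ~ 1)
  S_ref <- summary(km, times = 0:6)$surv
  expect_equal(unname(est$P[1, 1, ]), S_ref, tolerance = 1e-12)
})

test_that("estimates match the matrix exponential on a fully observed Markov cohort", {
  p <- default_params(n = 2000, seed = 55)
  p$beta[] <- 0
  p$p_susceptible <- 1
  p$censoring_rate <- 0
  r01 <- 0.20; r02 <- 0.10; r12 <- 0.15
  p$baseline[[1]]$rate <- r01
  p$baseline[[2]]$rate <- r02
  p$baseline[[3]]$rate <- r12
  cohort <- simulate_cohort(p)
  cp <- latent_counting_process(cohort)
  est <- aalen_johansen(cp, s = 0, times = c(0, 2, 5, 10, 20))
  Q <- matrix(c(-(r01 + r02), r01, r02,
                0, -r12, r12,
                0, 0, 0), 3, 3, byrow = TRUE)
  # bound the state-0 row (the whole cohort starts there; multinomial
  # SE <= 0.011 at n = 2000) at 3 SE; the absorbing row is exact
  for (i in seq_along(est$times)) {
    Pt <- as.matrix(Matrix::expm(Q * est$times[i]))
    expect_lt(max(abs(est$P[1, , i] - Pt[1, ])), 0.035)
    expect_equal(unname(est$P[3, , i]), c(0, 0, 1))
  }
})

test_that("row-stochasticity, absorbing state and Chapman-Kolmogorov hold", {
  cp <- to_counting_process(fixture_eligible())
  est <- aalen_johansen(cp, s = 0, times = 0:30)
  for (i in seq_along(est$times)) {
    P <- est$P[, , i]
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
    expect_equal(unname(P[3, ]), c(0, 0, 1))
  }
  # entry into the absorbing state is non-decreasing in t
  expect_true(all(diff(est$P[1, 3, ]) >= -1e-12))
  expect_true(all(diff(est$P[2, 3, ]) >= -1e-12))
  # Chapman-Kolmogorov with shared risk sets: P(0,u) P(u,t) = P(0,t)
  u <- 10
  est_u <- aalen_johansen(cp, s = u, times = c(u, 30))
  lhs <- est$P[, , est$times == u] %*% est_u$P[, , 2]
  expect_lt(max(abs(lhs - est$P[, , est$times == 30])), 1e-10)
})

test_that("stratified estimates partition the cohort and order with NSAID exposure", {
  strata <- stratified_aj(fixture_eligible())
  expect_identical(length(strata), 4L)
  expect_identical(names(strata)[1], "age>=45, NSAIDs no")
  for (st in strata) {
    last <- st$P[, , length(st$times)]
    expect_lt(max(abs(rowSums(last) - 1)), 1e-10)
  }
  # simulated cohort with a strong NSAID effect on mild -> severe:
  # NSAID strata accumulate more severe probability by day 30
  p <- default_params(n = 4000, seed = 99)
  cohort <- simulate_cohort(p)
  strata <- stratified_aj(cohort)
  p_sev <- vapply(strata, function(s) s$P[1, 3, length(s$times)],
                  numeric(1))
  expect_gt(p_sev[["age>=45, NSAIDs yes"]], p_sev[["age>=45, NSAIDs no"]])
  expect_gt(p_sev[["age<45, NSAIDs yes"]], p_sev[["age<45, NSAIDs no"]])
})

test_that("a lone never-progressing patient keeps all mass in state 0", {
  one <- make_patient("a", d_init = 2, g_init = 0, g_worst = 0,
                      followup = 20)
  est <- aalen_johansen(to_counting_process(one), times = 0:20)
  expect_true(all(est$P[1, 1, ] == 1))
})

test_that("Cox-predicted probabilities reduce to the nonparametric estimate", {
  cp <- to_counting_process(fixture_eligible())
  # all coefficients forced to zero + reference profile = Aalen-Johansen
  zero_fits <- lapply(1:3, function(k) {
    list(transition = k,
         coefficients = setNames(numeric(9), ocular_covariates()),
         converged = TRUE,
         baseline_cumhaz = nelson_aalen(cp, k))
  })
  prof <- setNames(numeric(9), ocular_covariates())
  pred <- predict_from_cox(zero_fits, prof, s = 0, times = 0:30)
  np <- aalen_johansen(cp, s = 0, times = 0:30)
  expect_equal(pred$P, np$P, tolerance = 1e-12)
  # t = s gives the identity
  pred0 <- predict_from_cox(zero_fits, prof, s = 0, times = 0)
  expect_equal(unname(pred0$P[, , 1]), diag(3))
})

test_that("Cox-predicted probabilities track the generating model", {
  p <- default_params(n = 2000, seed = 14)
  p$beta[] <- 0
  p$beta[, "drug_nsaids"] <- log(c(1.5, 1.5, 2.5))
  p$p_susceptible <- 1
  p$censoring_rate <- 1 / 40
  r <- c(0.15, 0.08, 0.10)
  for (k in 1:3) p$baseline[[k]]$rate <- r[k]
  cohort <- simulate_cohort(p)
  cp <- latent_counting_process(cohort)
  fits <- lapply(1:3, function(k) fit_cox(cp, k))
  prof <- setNames(numeric(9), ocular_covariates())
  prof["drug_nsaids"] <- 1
  pred <- suppressWarnings(
    predict_from_cox(fits, prof, times = c(0, 5, 10),
                     covariate_range = apply(
                       as.matrix(cp[, ocular_covariates()]), 2, range)))
  Q <- matrix(c(-(1.5 * r[1] + 1.5 * r[2]), 1.5 * r[1], 1.5 * r[2],
                0, -2.5 * r[3], 2.5 * r[3],
                0, 0, 0), 3, 3, byrow = TRUE)
  # state-0 row (where the cohort starts): baseline noise amplified by
  # exp(lp) gives the semi-parametric curve a sup-error of a few
  # hundredths at n = 2000; bound loosely and, more tellingly, require
  # the profile-specific prediction to beat the population-mixture
  # nonparametric estimate for this exposed profile
  aj_mix <- aalen_johansen(cp, times = c(0, 5, 10))
  for (i in 2:3) {
    Pt <- as.matrix(Matrix::expm(Q * pred$times[i]))
    expect_lt(max(abs(pred$P[1, , i] - Pt[1, ])), 0.12)
    expect_lt(max(abs(pred$P[1, , i] - Pt[1, ])),
              max(abs(aj_mix$P[1, , i] - Pt[1, ])))
  }
  # a profile outside the observed range warns but is not rejected
  prof_out <- prof; prof_out["age_years"] <- 200
  expect_warning(predict_from_cox(fits, prof_out, times = 0:5,
                                  covariate_range = apply(
                                    as.matrix(cp[, ocular_covariates()]),
                                    2, range)),
                 "outside the observed covariate range")
})

test_that("stacked bands are cumulative probabilities topped at one", {
  est <- make_transprob(list(diag(3),
                             matrix(c(0.5, 0.3, 0.2,
                                      0, 0.6, 0.4,
                                      0, 0, 1), 3, 3, byrow = TRUE)),
                        times = c(0, 5))
  b <- stacked_curves(est, from = 0)
  expect_equal(unname(unlist(b[1, -1])), c(1, 1, 1))
  expect_equal(unname(unlist(b[2, -1])), c(0.5, 0.8, 1.0))
  # on the fixture, the state-0 band never increases (progressive model)
  strata <- stratified_aj(fixture_eligible())
  for (st in strata) {
    b <- stacked_curves(st, from = 0)
    expect_true(all(diff(b$band_none) <= 1e-12))
    expect_true(all(b$band_severe == 1))
  }
})

test_that("estimator error shrinks with the sample size", {
  sup_err <- vapply(c(200, 2000), function(n) {
    p <- default_params(n = n, seed = 7)
    p$beta[] <- 0
    p$p_susceptible <- 1
    p$censoring_rate <- 0
    r <- c(0.2, 0.1, 0.15)
    for (k in 1:3) p$baseline[[k]]$rate <- r[k]
    cp <- latent_counting_process(simulate_cohort(p))
    est <- aalen_johansen(cp, times = c(5, 10, 20))
    Q <- matrix(c(-0.3, 0.2, 0.1, 0, -0.15, 0.15, 0, 0, 0), 3, 3,
                byrow = TRUE)
    max(vapply(seq_along(est$times), function(i)
      max(abs(est$P[, , i] -
                as.matrix(Matrix::expm(Q * est$times[i])))), numeric(1)))
  }, numeric(1))
  expect_lt(sup_err[2], sup_err[1])
})
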