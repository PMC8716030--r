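# independent oracle: explicit one-covariate Breslow partial likelihood
# evaluated on a dense beta grid
grid_search_beta <- function(entry, exit, status, x,
                             grid = seq(-4, 4, by = 1e-4)) {
  ll <- vapply(grid, function(b) {
    w <- exp(b * x)
    ut <- sort(unique(exit[status == 1]))
    s <- 0
    for (u in ut) {
      at <- entry < u & exit >= u
      du <- status == 1 & exit == u
      s <- s + b * sum(x[du]) - sum(du) * log(sum(w[at]))
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

test_that("toy fit matches a dense grid search of the explicit partial likelihood", {
  rows <- make_cp_rows(entry = c(0, 0, 0, 0), exit = c(2, 4, 5, 7),
                       status = c(1L, 1L, 0L, 0L), x = c(1, 0, 1, 0))
  fit <- fit_cox(rows, 3, covariates = "x")
  oracle <- grid_search_beta(rows$entry, rows$exit, rows$status, rows$x)
  expect_lt(abs(unname(coef(fit)) - oracle), 2e-4)
  expect_lt(fit$score_norm, 1e-6)
  expect_true(fit$converged)
})

test_that("relabelling a binary covariate flips the sign of its coefficient", {
  set.seed(21)
  x <- rbinom(30, 1, 0.4)
  rows <- make_cp_rows(entry = 0, exit = rexp(30, 0.2 * exp(0.7 * x)),
                       status = rep(1L, 30), x = x)
  rows2 <- rows; rows2$x <- 1 - rows2$x
  f1 <- fit_cox(rows, 3, covariates = "x")
  f2 <- fit_cox(rows2, 3, covariates = "x")
  expect_equal(unname(coef(f1)), -unname(coef(f2)), tolerance = 1e-7)
})

test_that("Breslow and Efron agree exactly on tie-free data", {
  set.seed(5)
  x <- rnorm(40)
  rows <- make_cp_rows(entry = 0, exit = rexp(40, 0.1 * exp(0.5 * x)),
                       status = rbinom(40, 1, 0.8), x = x)
  fb <- fit_cox(rows, 3, ties = "breslow", covariates = "x")
  fe <- fit_cox(rows, 3, ties = "efron", covariates = "x")
  expect_equal(coef(fb), coef(fe), tolerance = 1e-9)
})

test_that("fits agree with an independent reference implementation", {
  library(survival)
  cohort <- simulate_cohort(default_params(n = 400, seed = 31))
  cp <- to_counting_process(cohort)
  fml <- Surv(entry, exit, status) ~ age_years + sex_female +
    diagnosis_ten + drug_nsaids + drug_cold_remedies + drug_antibiotics +
    drug_anticonvulsants + drug_gout + severity_subscore
  for (k in 1:3) {
    for (ties in c("breslow", "efron")) {
      fit <- fit_cox(cp, k, ties = ties)
      ref <- coxph(fml, data = cp[cp$trans == k, ], ties = ties)
      expect_lt(max(abs(coef(fit) - coef(ref))), 1e-6)
      expect_lt(max(abs(sqrt(diag(vcov(fit))) - sqrt(diag(vcov(ref))))),
                1e-6)
      expect_lt(fit$score_norm, 1e-6)
    }
  }
})

test_that("degenerate inputs are rejected or flagged", {
  rows <- make_cp_rows(entry = 0, exit = c(1, 2, 3), status = c(0L, 0L, 0L),
                       x = c(0, 1, 0))
  expect_error(fit_cox(rows, 3, covariates = "x"), "zero events")
  rows$status <- c(1L, 1L, 0L)
  rows$x <- c(1, 1, 1)
  expect_error(suppressWarnings(fit_cox(rows, 3, covariates = "x")),
               "non-constant")
  # perfectly separating covariate: monotone likelihood flagged
  set.seed(2)
  x <- rep(c(1, 0), each = 15)
  ex <- c(rexp(15, 2), 10 + rexp(15, 2))
  rows <- make_cp_rows(entry = 0, exit = ex, status = rep(1L, 30), x = x)
  fit <- fit_cox(rows, 3, covariates = "x")
  expect_false(fit$converged)
  expect_identical(unname(fit$divergence_direction["x"]), 1)
})

test_that("Wald inference pieces are mutually consistent", {
  cohort <- simulate_cohort(default_params(n = 300, seed = 8))
  fit <- fit_cox(to_counting_process(cohort), 1)
  expect_true(all(fit$ci_lower < fit$hr & fit$hr < fit$ci_upper))
  expect_equal(fit$hr, exp(coef(fit)), tolerance = 1e-12)
  expect_equal(unname(fit$p_values),
               unname(2 * pnorm(-abs(coef(fit) / fit$se))),
               tolerance = 1e-12)
  v <- vcov(fit)
  expect_equal(v, t(v), tolerance = 1e-10)
  expect_true(all(eigen(v, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
})

test_that("Nelson-Aalen increments are events over at-risk counts", {
  rows <- make_cp_rows(entry = 0, exit = c(2, 3, 5), status = c(1L, 0L, 0L),
                       x = 0, trans = 1L)
  na <- nelson_aalen(rows, 1)
  expect_equal(na$time, 2)
  expect_equal(na$inc, 1 / 3)
  expect_equal(cumhaz_at(na, c(0, 1.9, 2, 10)), c(0, 0, 1 / 3, 1 / 3))
  # no events: flat zero
  rows$status <- 0L
  expect_error(na0 <- nelson_aalen(rows, 1), NA)
  expect_identical(length(na0$time), 0L)
  expect_equal(cumhaz_at(na0, c(0, 5)), c(0, 0))
})

test_that("Nelson-Aalen recovers an exponential cumulative hazard at large n", {
  set.seed(77)
  n <- 1500
  tt <- rexp(n, 0.2)
  cc <- rexp(n, 0.05)
  rows <- make_cp_rows(entry = 0, exit = pmin(tt, cc),
                       status = as.integer(tt <= cc), x = 0, trans = 1L)
  na <- nelson_aalen(rows, 1)
  for (t0 in c(2, 5, 10))
    expect_lt(abs(cumhaz_at(na, t0) - 0.2 * t0), 0.12 * 0.2 * t0 + 0.02)
})

test_that("Breslow baseline reduces to Nelson-Aalen at zero coefficients", {
  cohort <- simulate_cohort(default_params(n = 120, seed = 13))
  cp <- to_counting_process(cohort)
  zero_fit <- list(transition = 1L,
                   coefficients = setNames(0, "age_years"))
  bb <- breslow_baseline(zero_fit, cp, covariates = "age_years")
  na <- nelson_aalen(cp, 1)
  expect_equal(bb$time, na$time)
  expect_equal(bb$inc, na$inc, tolerance = 1e-12)
  # single at-risk subject, zero linear predictor: increment exactly 1
  one <- make_cp_rows(entry = 0, exit = 4, status = 1L, x = 0, trans = 1L)
  bb1 <- breslow_baseline(list(transition = 1L,
                               coefficients = setNames(0, "x")),
                          one, covariates = "x")
  expect_equal(bb1$inc, 1)
  # hand-computed increments d / sum(exp(beta x)) on 4 subjects
  rows <- make_cp_rows(entry = 0, exit = c(1, 2, 3, 4),
                       status = c(1L, 1L, 0L, 1L), x = c(1, 0, 1, 0),
                       trans = 1L)
  b <- 0.5
  bb <- breslow_baseline(list(transition = 1L,
                              coefficients = setNames(b, "x")),
                         rows, covariates = "x")
  w <- exp(b * rows$x)
  expect_equal(bb$inc,
               c(1 / sum(w), 1 / sum(w[2:4]), 1 / sum(w[4])),
               tolerance = 1e-12)
})

test_that("estimates recover generating coefficients on exactly observed data", {
  # fully susceptible cohort: under the mixture default the state-0
  # hazards are deliberately non-proportional, so recovery is checked
  # under the estimator's own model
  p <- default_params(n = 2000, seed = 123)
  p$p_susceptible <- 1
  cohort <- simulate_cohort(p)
  cp <- latent_counting_process(cohort)
  for (k in 1:3) {
    fit <- fit_cox(cp, k)
    expect_true(fit$converged)
    dev <- abs(coef(fit) - p$beta[k, names(coef(fit))]) / fit$se
    expect_true(all(dev < 3), info = sprintf("transition %d", k))
  }
})

test_that("Wald confidence intervals attain nominal coverage", {
  # well-conditioned two-covariate design, 200 replicates
  set.seed(4242)
  hit <- logical(200)
  b1 <- log(2)
  for (r in seq_len(200)) {
    n <- 250
    x1 <- rbinom(n, 1, 0.3)
    x2 <- rnorm(n)
    tt <- rexp(n, 0.05 * exp(b1 * x1 - 0.3 * x2))
    cc <- rexp(n, 0.03)
    rows <- make_cp_rows(entry = 0, exit = pmin(tt, cc),
                         status = as.integer(tt <= cc), x = x1)
    rows$x2 <- x2
    fit <- fit_cox(rows, 3, covariates = c("x", "x2"))
    ci <- confint(fit)["x", ]
    hit[r] <- ci[1] <= b1 && b1 <= ci[2]
  }
  expect_gte(mean(hit), 0.92)
  expect_lte(mean(hit), 0.98)
})
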