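test_that("severity grades map onto the three model states", {
  expect_identical(grade_to_state(0:3), c(0L, 1L, 2L, 2L))
  expect_identical(grade_label(0:3),
                   c("none", "mild", "severe", "very severe"))
  expect_error(grade_to_state(4), "0..3")
  expect_error(grade_to_state(NA), "0..3")
  tr <- transition_structure()
  expect_identical(nrow(tr), 3L)
  expect_true(all(tr$from < tr$to))       # progressive: no recovery edges
  expect_false(any(tr$to == 0L))          # nothing enters state 0
})

test_that("30-day eligibility filters exclude strictly-more-than-30-day intervals", {
  cohort <- make_cohort(
    make_patient("a", d_init = 31),
    make_patient("b", d_init = 30, d_worst = 30, g_init = 1, g_worst = 2,
                 followup = 80),
    make_patient("c", d_init = 2, d_worst = 31, g_init = 1, g_worst = 2,
                 followup = 60),
    make_patient("d", d_init = 0))
  flt <- apply_eligibility_filters(cohort)
  expect_identical(flt$eligible$patient_id, c("b", "d"))
  expect_identical(flt$exclusions$patient_id, c("a", "c"))
  expect_match(flt$exclusions$rule[1], "days_onset_to_initial")
  expect_match(flt$exclusions$rule[2], "days_initial_to_worst")
  # empty cohort passes through
  empty <- apply_eligibility_filters(cohort[0, ])
  expect_identical(nrow(empty$eligible), 0L)
  expect_identical(nrow(empty$exclusions), 0L)
})

test_that("transition cross-tabulation counts initial-by-worst grades", {
  one <- make_patient("a", g_init = 0, g_worst = 1, d_worst = 4)
  m <- build_transition_table(one)
  expect_identical(sum(m), 1L)
  expect_identical(m["none", "mild"], 1L)
  expect_true(all(build_transition_table(one[0, ]) == 0L))
  # lower triangle structurally zero on the study fixture
  m <- build_transition_table(fixture_eligible())
  expect_true(all(m[lower.tri(m)] == 0L))
  expect_identical(unname(m["mild", ]), c(0L, 74L, 19L, 4L))
})

test_that("counting-process conversion follows the competing-risk conventions", {
  # severe at presentation day 3: (0,1) censored and (0,2) event on (0,3]
  cp <- to_counting_process(make_patient("a", d_init = 3, g_init = 2,
                                         g_worst = 2))
  expect_identical(nrow(cp), 2L)
  expect_identical(cp$status, c(0L, 1L))
  expect_identical(cp$exit, c(3, 3))
  expect_false(any(cp$trans == 3L))

  # mild at day 2, worst severe at day 6: (0,1) event at 2, (0,2)
  # censored at 2, delayed-entry (1,2) event on (2,6]
  cp <- to_counting_process(make_patient("a", d_init = 2, d_worst = 4,
                                         g_init = 1, g_worst = 2,
                                         followup = 30))
  expect_identical(cp$status[cp$trans == 1L], 1L)
  expect_identical(cp$status[cp$trans == 2L], 0L)
  r3 <- cp[cp$trans == 3L, ]
  expect_identical(c(r3$entry, r3$exit, r3$status), c(2, 6, 1L))

  # day-0 presentation: zero-length interval offset to (0, 0.5]
  cp <- to_counting_process(make_patient("a", d_init = 0, g_init = 1,
                                         g_worst = 1, followup = 10))
  expect_identical(cp$exit[cp$trans == 1L], 0.5)
  expect_identical(cp$entry[cp$trans == 3L], 0.5)
  expect_true(all(cp$exit > cp$entry))

  # same-day worsening: worst = initial day still yields entry < exit
  cp <- to_counting_process(make_patient("a", d_init = 5, d_worst = 0,
                                         g_init = 1, g_worst = 3,
                                         followup = 10))
  r3 <- cp[cp$trans == 3L, ]
  expect_identical(c(r3$entry, r3$exit, r3$status), c(5, 5.5, 1L))
})

test_that("negative-day patients are excluded from the multi-state data with a log", {
  cohort <- make_cohort(
    make_patient("neg", d_init = -2, g_init = 1, g_worst = 1),
    make_patient("ok", d_init = 4))
  cp <- to_counting_process(cohort)
  expect_identical(attr(cp, "n_subjects"), 1L)
  d <- attr(cp, "dropped")
  expect_identical(d$patient_id, "neg")
  expect_match(d$rule, "before erythema")
})

test_that("severity regression and missing covariates are rejected", {
  bad <- make_patient("a", g_init = 2, g_worst = 1)
  expect_error(validate_cohort(bad), "regression")
  mc <- make_patient("a"); mc$age_years <- NA
  cp <- to_counting_process(rbind(mc, make_patient("b")))
  expect_identical(attr(cp, "n_subjects"), 1L)
  expect_match(attr(cp, "dropped")$rule, "complete-case")
})

test_that("counting-process invariants hold on simulated cohorts", {
  for (seed in c(2, 17, 301)) {
    cohort <- simulate_cohort(default_params(n = 150, seed = seed))
    cp <- to_counting_process(cohort)
    n <- attr(cp, "n_subjects")
    # competing risks exclusive: at most one event out of each state
    ev0 <- tapply(cp$status[cp$trans %in% 1:2],
                  cp$patient_id[cp$trans %in% 1:2], sum)
    expect_true(all(ev0 <= 1L))
    # accounting: state-0 exits (events) + state-0 censorings = subjects
    e01 <- sum(cp$status[cp$trans == 1L])
    e02 <- sum(cp$status[cp$trans == 2L])
    expect_identical(e01 + e02 + sum(ev0 == 0L), n)
    # every state-1 entrant is at risk of progression
    expect_identical(length(unique(cp$patient_id[cp$trans == 3L])), e01)
    expect_true(all(cp$exit > cp$entry))
  }
})

test_that("cohort CSV round-trip reproduces identical counting-process data", {
  cohort <- simulate_cohort(default_params(n = 80, seed = 9))
  path <- tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  back <- read_cohort(path)
  attr(cohort, "paths") <- NULL
  expect_identical(back, cohort)
  expect_identical(
    as.data.frame(to_counting_process(back)),
    as.data.frame(to_counting_process(cohort)))
  unlink(path)
})
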