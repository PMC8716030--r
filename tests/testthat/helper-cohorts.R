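# small cohort construction helpers used across the suite

make_patient <- function(id = "p1", age = 50, sex = "male",
                         diagnosis = "SJS", nsaids = FALSE, cold = FALSE,
                         abx = FALSE, anticonv = FALSE, gout = FALSE,
                         subscore = 5, d_init = 3, d_worst = 0,
                         g_init = 0, g_worst = g_init,
                         followup = max(d_init, 0) + d_worst + 30,
                         died = FALSE, sequelae = "none",
                         visual = "none", dry = "none") {
  data.frame(patient_id = id, age_years = age, sex = sex,
             diagnosis = diagnosis, drug_nsaids = nsaids,
             drug_cold_remedies = cold, drug_antibiotics = abx,
             drug_anticonvulsants = anticonv, drug_gout = gout,
             severity_subscore = subscore,
             days_onset_to_initial = d_init,
             days_initial_to_worst = d_worst,
             grade_initial = g_init, grade_worst = g_worst,
             days_onset_to_last_followup = followup,
             died = died, sequelae = sequelae,
             visual_disturbance = visual, dry_eye = dry,
             stringsAsFactors = FALSE)
}

make_cohort <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# bare counting-process rows for estimator tests (single covariate x)
make_cp_rows <- function(entry, exit, status, x, trans = 3L,
                         id = NULL) {
  n <- length(exit)
  if (is.null(id)) id <- sprintf("s%d", seq_len(n))
  tr <- transition_structure()
  out <- data.frame(patient_id = id, trans = trans,
                    from = tr$from[trans], to = tr$to[trans],
                    entry = entry, exit = exit, status = status,
                    x = x, stringsAsFactors = FALSE)
  attr(out, "n_subjects") <- length(unique(id))
  class(out) <- c("counting_process", "data.frame")
  out
}

fixture_eligible <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- apply_eligibility_filters(make_study_fixture()$cohort)$eligible
    cache
  }
})
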