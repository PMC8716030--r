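#' Run the full analysis pipeline
#'
#' Ties the stages together: obtain a cohort (deterministic study fixture,
#' simulated cohort, or CSV file), apply the 30-day eligibility filters,
#' cross-tabulate severity change, build the counting process, fit the
#' three transition-specific Cox models, estimate stratified
#' Aalen-Johansen probabilities, and write the report bundle.
#'
#' @param config a named list, or path to a YAML file, with any of:
#'   \describe{
#'     \item{generator}{`"fixture"` (default), `"simulate"`, or `"file"`.}
#'     \item{input}{cohort CSV path when `generator = "file"`.}
#'     \item{n_patients, seed}{simulated-cohort size and seed
#'       (`generator = "simulate"`).}
#'     \item{max_days}{eligibility threshold (default 30).}
#'     \item{ties}{`"breslow"` (default) or `"efron"`.}
#'     \item{age_cutoff}{stratification age threshold (default 45).}
#'     \item{output_dir}{where the bundle is written (required).}
#'     \item{figures}{write PNG stacked-probability figures
#'       (default TRUE).}
#'   }
#' @param ... individual settings overriding `config` values (mirrors a
#'   command line whose flags override the configuration file).
#' @return Invisibly, a list with the in-memory results: `cohort`,
#'   `eligible`, `exclusions`, `transition_table`, `cp`, `fit`
#'   (`"msm_cox"`), `summary`, `strata` and `files` (paths written).
#' @export
run_pipeline <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path",
                             call. = FALSE)
  overrides <- list(...)
  config[names(overrides)] <- overrides
  defaults <- list(generator = "fixture", input = NULL, n_patients = 500L,
                   seed = 1L, max_days = 30, ties = "breslow",
                   age_cutoff = 45, output_dir = NULL, figures = TRUE)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$output_dir))
    stop("config must name an output_dir", call. = FALSE)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$output_dir, "run.log")
  log_lines <- c(sprintf("ocmsm pipeline run, generator=%s, seed=%s",
                         cfg$generator, cfg$seed))

  cohort <- switch(
    cfg$generator,
    fixture = make_study_fixture()$cohort,
    simulate = {
      if (cfg$n_patients < 1L) stop("empty cohort requested (n < 1)", call. = FALSE)
      simulate_cohort(default_params(n = cfg$n_patients, seed = cfg$seed))
    },
    file = {
      if (is.null(cfg$input) || !file.exists(cfg$input))
        stop("generator 'file' needs a readable input path", call. = FALSE)
      read_cohort(cfg$input)
    },
    stop("unknown generator: ", cfg$generator, call. = FALSE)
  )

  flt <- apply_eligibility_filters(cohort, max_days = cfg$max_days)
  if (nrow(flt$exclusions))
    log_lines <- c(log_lines, sprintf("excluded %s: %s",
                                      flt$exclusions$patient_id,
                                      flt$exclusions$rule))
  tab1 <- build_transition_table(flt$eligible)
  cp <- to_counting_process(flt$eligible)
  dropped <- attr(cp, "dropped")
  if (nrow(dropped))
    log_lines <- c(log_lines, sprintf("multi-state drop %s: %s",
                                      dropped$patient_id, dropped$rule))
  fit <- msm_cox(cp, ties = cfg$ties)
  summ <- summarize_by_grade(flt$eligible)
  strata <- stratified_aj(flt$eligible, age_cutoff = cfg$age_cutoff)

  files <- c(
    counting_process = write_counting_process(
      cp, file.path(cfg$output_dir, "counting_process.csv")),
    fits = write_msm_json(fit, file.path(cfg$output_dir,
                                         "transition_fits.json")),
    transprob = write_transprob(strata, file.path(cfg$output_dir,
                                                  "transition_probabilities.csv"))
  )
  report <- render_tables(list(transition_table = tab1, summary = summ,
                               fit = fit, cohort_n = nrow(cohort),
                               eligible_n = nrow(flt$eligible)))
  report_path <- file.path(cfg$output_dir, "report.md")
  writeLines(report, report_path)
  files <- c(files, report = report_path)
  if (isTRUE(cfg$figures)) {
    for (i in seq_along(strata)) {
      fp <- file.path(cfg$output_dir,
                      sprintf("stacked_probabilities_panel_%s.png",
                              letters[i]))
      grDevices::png(fp, width = 720, height = 540)
      plot(strata[[i]])
      grDevices::dev.off()
      files <- c(files, fp)
    }
  }
  writeLines(log_lines, logf)
  files <- c(files, log = logf)
  invisible(list(cohort = cohort, eligible = flt$eligible,
                 exclusions = flt$exclusions, transition_table = tab1,
                 cp = cp, fit = fit, summary = summ, strata = strata,
                 files = files))
}

#' Render results as human-readable Markdown tables
#'
#' Formats the severity-change cross-tabulation, the grouped summaries
#' and the per-transition hazard-ratio tables as Markdown, with
#' percentages at one decimal.
#'
#' @param results a list with any of `transition_table` (4 x 4 matrix),
#'   `summary` (a `"grade_summary"`), `fit` (an `"msm_cox"`), and the
#'   counts `cohort_n`, `eligible_n`.
#' @return Character vector of report lines (empty results give an empty
#'   report with a warning).
#' @export
render_tables <- function(results) {
  if (!length(results) ||
      !any(c("transition_table", "summary", "fit") %in% names(results))) {
    warning("no results to render; empty report", call. = FALSE)
    return(character(0))
  }
  out <- c("# Acute ocular severity progression report", "")
  if (!is.null(results$cohort_n))
    out <- c(out, sprintf("Cohort: %d patients, %d eligible after the 30-day filters.",
                          results$cohort_n, results$eligible_n), "")
  if (!is.null(results$transition_table)) {
    m <- results$transition_table
    out <- c(out, "## Change of acute ocular severity", "",
             paste0("| initial \\ worst | ",
                    paste(colnames(m), collapse = " | "), " | Total |"),
             paste0("|", paste(rep("---", ncol(m) + 2), collapse = "|"),
                    "|"))
    for (i in seq_len(nrow(m))) {
      tot <- sum(m[i, ])
      cells <- vapply(seq_len(ncol(m)), function(j)
        sprintf("%d (%s)", m[i, j],
                format_pct(m[i, j], tot)), character(1))
      out <- c(out, paste0("| ", rownames(m)[i], " | ",
                           paste(cells, collapse = " | "),
                           sprintf(" | %d |", tot)))
    }
    out <- c(out, "")
  }
  if (!is.null(results$summary)) {
    s <- results$summary
    out <- c(out, "## Outcomes and ocular sequelae by severity group", "",
             sprintf("Group sizes: Grade 0 = %d, Grade 1 = %d, Grade 2/3 = %d; non-missing outcome denominators %d / %d / %d.",
                     s$n[1], s$n[2], s$n[3],
                     s$outcome_denominator[1], s$outcome_denominator[2],
                     s$outcome_denominator[3]), "",
             "| outcome | Grade 0 | Grade 1 | Grade 2/3 |",
             "|---|---|---|---|")
    for (i in seq_len(nrow(s$outcomes))) {
      r <- s$outcomes[i, ]
      fmt <- function(nn, pp)
        if (is.na(pp)) sprintf("%d", nn) else sprintf("%d (%s)", nn,
                                                      sprintf("%.1f", pp))
      out <- c(out, sprintf("| %s | %s | %s | %s |", r$variable,
                            fmt(r$g0_n, r$g0_pct), fmt(r$g1_n, r$g1_pct),
                            fmt(r$g23_n, r$g23_pct)))
    }
    out <- c(out, "")
  }
  if (!is.null(results$fit)) {
    sm <- summary(results$fit)
    for (k in seq_along(sm$tables)) {
      out <- c(out, sprintf("## Transition %s", sm$labels[k]),
               sprintf("N = %d (number of events: %d)", sm$n_subjects[k],
                       sm$n_events[k]), "",
               "| covariate | HR | 95% CI | P-value |",
               "|---|---|---|---|")
      tab <- format_hr_table(sm$tables[[k]])
      for (i in seq_len(nrow(tab)))
        out <- c(out, sprintf("| %s | %s | %s | %s |", tab$covariate[i],
                              tab$HR[i], tab$`95% CI`[i],
                              tab$`P-value`[i]))
      out <- c(out, "")
    }
  }
  out
}

# one-decimal percentage, e.g. 46/86 -> "53.5"
format_pct <- function(num, denom) {
  if (is.na(denom) || denom == 0) return("-")
  sprintf("%.1f", 100 * num / denom)
}
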