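#' Pipeline configuration
#'
#' Assembles every tunable of the simulate -> fit -> compare -> validate ->
#' stats pipeline into one serialisable list: design constants, generator
#' settings, fitting options, validation set counts and the master seed.
#' The configuration round-trips through YAML unchanged, so a run is fully
#' described by its config file plus the package version.
#'
#' @param participants Cohort size.
#' @param model_id Generating utility model.
#' @param kappa_range,eta_range,theta_range,lambda Agent population settings
#'   (see [agent_spec()]).
#' @param fit_models Model ids to fit and compare.
#' @param n_validation_sets Simulation sets for accuracy/recovery.
#' @param n_boot Bootstrap resamples for mediation.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(participants = 40,
                            model_id = "1.3",
                            kappa_range = c(0.5, 4),
                            eta_range = c(0, 3),
                            theta_range = c(0, 0.5),
                            lambda = 2,
                            fit_models = model_ids(),
                            n_validation_sets = 50,
                            n_boot = 5000,
                            seed = 1L) {
  structure(
    list(participants = as.integer(participants),
         model_id = model_id,
         kappa_range = as.numeric(kappa_range),
         eta_range = as.numeric(eta_range),
         theta_range = as.numeric(theta_range),
         lambda = as.numeric(lambda),
         fit_models = fit_models,
         n_validation_sets = as.integer(n_validation_sets),
         n_boot = as.integer(n_boot),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the stages end to end: simulate a dataset, fit the requested
#' utility models to every participant, compare them by summed BIC, validate
#' the winning model (predictive accuracy against chance, parameter
#' recovery, parameter independence), and run the behavioural statistics
#' stages (manipulation checks, emotion regressions, compensation
#' regression family, sensitivities, trait correlations). All CSV/JSON
#' artifacts are written under `outdir` together with a run log; rerunning
#' with the same config reproduces them.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  logfile <- file.path(outdir, "run.log")
  logline <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(msg)
    cat(msg, "\n", file = logfile, append = TRUE)
  }
  stage <- function(name, expr) {
    logline("stage %s: start", name)
    res <- tryCatch(expr, error = function(e) {
      logline("stage %s: FAILED: %s", name, conditionMessage(e))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    logline("stage %s: done", name)
    res
  }

  cat("", file = logfile)
  write_config(config, file.path(outdir, "config.yaml"))
  seeds <- derive_seeds(config$seed, 4)
  small_n <- config$participants < 3
  if (small_n) {
    warning("fewer than 3 participants: correlation-based stages are skipped",
            call. = FALSE)
  }

  dataset <- stage("simulate", {
    ds <- simulate_dataset(
      participants = config$participants,
      agents = agent_spec(config$model_id, config$kappa_range,
                          config$eta_range, config$theta_range,
                          config$lambda),
      seed = seeds[1]
    )
    write_dataset(ds, outdir)
    ds
  })

  fits <- stage("fit", {
    f <- fit_cohort(dataset$trials, models = config$fit_models)
    utils::write.csv(f, file.path(outdir, "fits.csv"), row.names = FALSE,
                     na = "")
    f
  })

  comparison <- stage("compare", {
    cmp <- compare_models(fits)
    utils::write.csv(cmp$table, file.path(outdir, "comparison.csv"),
                     row.names = FALSE)
    logline("winner: %s", cmp$winner)
    cmp
  })

  validation <- if (small_n) NULL else stage("validate", {
    wfits <- fits[fits$model == comparison$winner & !fits$excluded, ]
    rep <- validate_model(utility_model(comparison$winner), wfits,
                          dataset$trials,
                          n_sets = config$n_validation_sets, seed = seeds[2])
    jsonlite::write_json(
      list(accuracy = rep$accuracy[c("mean_accuracy", "ci", "chance",
                                     "t_test", "n_sets")],
           recovery = rep$recovery[setdiff(names(rep$recovery), "per_set")],
           independence = rep$independence,
           seed = rep$seed),
      file.path(outdir, "validation.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
    rep
  })

  stats_report <- stage("stats", {
    checks <- dataset$checks
    pain <- manipulation_check(checks[checks$measure == "pain", ])
    resp <- manipulation_check(checks[checks$measure == "responsibility", ])
    if (small_n) {
      st <- list(manipulation = list(pain = pain, responsibility = resp))
    } else {
      emo_h <- emotion_regression(dataset$emotions, "harm")
      emo_r <- emotion_regression(dataset$emotions, "responsibility")
      merged <- merge_emotions(dataset$trials, dataset$emotions)
      comp_reg <- compensation_regression(merged)
      sens <- extract_sensitivities(dataset$emotions, dataset$trials)
      tc <- trait_correlations(dataset$traits, mean_compensation(dataset$trials))
      st <- list(
        manipulation = list(pain = pain, responsibility = resp),
        emotion_harm = emo_h[c("coefficients", "interaction",
                               "simple_slopes", "random")],
        emotion_responsibility = emo_r[c("coefficients", "interaction",
                                         "simple_slopes", "random")],
        compensation = comp_reg[c("bic", "winner", "coefficients", "wald",
                                  "random")],
        sensitivities = sens,
        trait_correlations = tc
      )
    }
    jsonlite::write_json(st, file.path(outdir, "stats.json"),
                         dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, null = "null", force = TRUE)
    st
  })

  logline("pipeline complete")
  invisible(list(config = config, dataset = dataset, fits = fits,
                 comparison = comparison, validation = validation,
                 stats = stats_report))
}
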