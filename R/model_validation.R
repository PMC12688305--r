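#' Simulation-based predictive accuracy of a fitted model
#'
#' Simulates each participant's decisions from their fitted (or generating)
#' parameters `n_sets` times over the same trial schedule and scores, per
#' participant, the proportion of simulated decisions matching the observed
#' ones. The group mean accuracy is reported with a t-based 95% CI across
#' participants and tested against the chance level (1 over the number of
#' decision options) with a one-sample t test.
#'
#' @param model A [utility_model()].
#' @param params Per-participant parameter data frame (`participant_id`,
#'   `kappa`, `eta`, `theta`, `lambda`), e.g. the relevant columns of a
#'   [fit_cohort()] result.
#' @param trials Trial data frame holding the observed decisions.
#' @param n_sets Number of simulated datasets (must be >= 1).
#' @param seed Master seed; one child seed per simulation set.
#' @param chance Chance-level accuracy to test against.
#' @param options Decision option set.
#' @return A list: `per_participant` (id, accuracy), `mean_accuracy`,
#'   `ci` (95% t interval), `chance`, `t_test` (`statistic`, `df`,
#'   `p_value`), `n_sets`.
#' @export
predictive_accuracy <- function(model, params, trials, n_sets = 50, seed = 1L,
                                chance = 1 / length(options), options = 0:10) {
  assert_that(n_sets >= 1, "n_sets must be at least 1")
  obs <- self_error_trials(trials)
  obs <- obs[!is.na(obs$decision), , drop = FALSE]
  seeds <- derive_seeds(seed, n_sets)
  match_counts <- stats::setNames(numeric(nrow(params)), params$participant_id)
  trial_counts <- table(obs$participant_id)[params$participant_id]
  for (s in seq_len(n_sets)) {
    sim <- generate_decisions(obs, model, params, seed = seeds[s],
                              options = options)
    hit <- sim$decision == obs$decision
    agg <- tapply(hit, obs$participant_id, sum)
    match_counts <- match_counts + agg[names(match_counts)]
  }
  acc <- as.numeric(match_counts) / (as.numeric(trial_counts) * n_sets)
  if (stats::sd(acc) > 0) {
    tt <- stats::t.test(acc, mu = chance)
    ci <- as.numeric(tt$conf.int)
    t_test <- list(statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  } else {
    # degenerate (e.g. deterministic agents): accuracies identical
    ci <- rep(mean(acc), 2)
    t_test <- list(statistic = if (mean(acc) == chance) 0 else
                     Inf * sign(mean(acc) - chance),
                   df = length(acc) - 1,
                   p_value = as.numeric(mean(acc) == chance))
  }
  list(
    per_participant = data.frame(participant_id = params$participant_id,
                                 accuracy = acc, stringsAsFactors = FALSE),
    mean_accuracy = mean(acc),
    ci = ci,
    chance = chance,
    t_test = t_test,
    n_sets = n_sets
  )
}

#' Parameter recovery for a utility model
#'
#' For each of `n_sets` simulation sets, decisions are simulated over the
#' schedule from the generating parameters, the model is refit by maximum
#' likelihood, and the Pearson correlation between generating and recovered
#' values is computed across participants for each free utility parameter
#' (`kappa`, and `eta`/`theta` where present). Reported are the mean
#' correlation over sets and a 95% percentile interval over sets.
#'
#' @param model A [utility_model()].
#' @param params Generating per-participant parameters (the "real-data
#'   estimates" in an applied run; the true parameters in a synthetic run).
#' @param schedule Trial schedule (decisions ignored).
#' @param n_sets Number of simulate-refit cycles.
#' @param seed Master seed.
#' @param options Decision option set.
#' @return A list with, per recovered parameter, `mean_r` and `ci`
#'   (percentile over sets), plus `per_set` (data frame of per-set
#'   correlations), `n_failed` refits, and `n_sets`.
#' @export
parameter_recovery <- function(model, params, schedule, n_sets = 50,
                               seed = 1L, options = 0:10) {
  assert_that(nrow(params) >= 3, "parameter recovery needs at least 3 participants")
  which_pars <- intersect(c("kappa", "eta", "theta"), model$free_params)
  seeds <- derive_seeds(seed, n_sets)
  per_set <- matrix(NA_real_, n_sets, length(which_pars),
                    dimnames = list(NULL, which_pars))
  n_failed <- 0L
  for (s in seq_len(n_sets)) {
    sim <- generate_decisions(schedule, model, params, seed = seeds[s],
                              options = options)
    refit <- fit_cohort(sim, models = model$id, options = options)
    refit <- refit[!refit$excluded, , drop = FALSE]
    n_failed <- n_failed + (nrow(params) - nrow(refit))
    m <- match(refit$participant_id, params$participant_id)
    for (p in which_pars) {
      per_set[s, p] <- stats::cor(params[[p]][m], refit[[p]])
    }
  }
  out <- list(per_set = as.data.frame(per_set), n_failed = n_failed,
              n_sets = n_sets)
  for (p in which_pars) {
    r <- per_set[, p]
    out[[paste0("r_", p)]] <- list(
      mean_r = mean(r, na.rm = TRUE),
      ci = as.numeric(stats::quantile(r, c(0.025, 0.975), na.rm = TRUE))
    )
  }
  out
}

#' Correlation between fitted parameters across participants
#'
#' Pearson correlation (with two-sided test) between two fitted parameters,
#' by default compensatory sensitivity `kappa` and baseline `eta`; a
#' non-significant correlation indicates the two parameters capture separable
#' psychological quantities.
#'
#' @param params Per-participant parameter data frame.
#' @param pair Character vector of two parameter column names.
#' @return A list: `r`, `p_value`, `n`, `pair`.
#' @export
parameter_independence <- function(params, pair = c("kappa", "eta")) {
  x <- params[[pair[1]]]
  y <- params[[pair[2]]]
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  assert_that(length(x) >= 3, "need at least 3 participants")
  assert_that(stats::sd(x) > 0 && stats::sd(y) > 0,
              "correlation undefined for a constant parameter vector")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       pair = pair)
}

#' Run the full validation battery for a winning model
#'
#' Convenience wrapper combining [predictive_accuracy()],
#' [parameter_recovery()] and [parameter_independence()] into one report.
#'
#' @inheritParams predictive_accuracy
#' @param schedule Schedule used for the recovery simulations (defaults to
#'   `trials`).
#' @return A `validation_report` list with components `accuracy`, `recovery`,
#'   `independence`, `chance`, `n_sets`, `seed`.
#' @export
validate_model <- function(model, params, trials, schedule = trials,
                           n_sets = 50, seed = 1L,
                           chance = 1 / length(options), options = 0:10) {
  seeds <- derive_seeds(seed, 2)
  acc <- predictive_accuracy(model, params, trials, n_sets = n_sets,
                             seed = seeds[1], chance = chance,
                             options = options)
  rec <- parameter_recovery(model, params, schedule, n_sets = n_sets,
                            seed = seeds[2], options = options)
  ind <- tryCatch(parameter_independence(params), error = function(e) NULL)
  structure(list(accuracy = acc, recovery = rec, independence = ind,
                 chance = chance, n_sets = n_sets, seed = seed),
            class = "validation_report")
}
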