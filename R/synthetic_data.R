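#' Synthetic cohorts for the interpersonal compensation game
#'
#' `agent_spec()` describes a cohort of simulated deciders: either
#' utility-model agents (a generating [utility_model()] plus per-participant
#' parameters) or emotion-mediated agents whose decisions are a noisy linear
#' function of their own guilt and shame ratings. `draw_agents()` samples the
#' per-participant parameters.
#'
#' The default population is the package's documented study-condition cohort:
#' decisions generated from the winning diffusion model with baseline
#' (model 1.3), `kappa ~ Uniform(0.5, 4)`, `eta ~ Uniform(0, 3)`, `lambda`
#' fixed at 2 (`theta ~ Uniform(0, 0.5)` for the self-interest variants).
#' These ranges keep the ideal points `kappa * H/W + eta` inside the 0-10
#' token scale for most cells; the inverse temperature of 2 yields clearly
#' structured yet stochastic choices.
#'
#' @param model_id Generating model id (see [model_ids()]).
#' @param kappa_range,eta_range,theta_range Uniform sampling ranges for the
#'   participant-level parameters (ranges for components the model lacks are
#'   ignored).
#' @param lambda Inverse temperature, common to all participants.
#' @return An `agent_spec` object.
#' @export
agent_spec <- function(model_id = "1.3",
                       kappa_range = c(0.5, 4),
                       eta_range = c(0, 3),
                       theta_range = c(0, 0.5),
                       lambda = 2) {
  structure(
    list(model = utility_model(model_id), kappa_range = kappa_range,
         eta_range = eta_range, theta_range = theta_range, lambda = lambda),
    class = "agent_spec"
  )
}

#' @rdname agent_spec
#' @param spec An `agent_spec`.
#' @param n Number of participants.
#' @param seed Integer seed.
#' @return `draw_agents()`: a data frame with one row per participant and
#'   columns `participant_id`, `kappa`, `eta`, `theta`, `lambda` (`NA` for
#'   parameters the model does not use).
#' @export
draw_agents <- function(spec, n, seed = 1L) {
  set.seed(seed)
  m <- spec$model
  data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    kappa = stats::runif(n, spec$kappa_range[1], spec$kappa_range[2]),
    eta = if (m$baseline) stats::runif(n, spec$eta_range[1], spec$eta_range[2]) else NA_real_,
    theta = if (m$self_interest) stats::runif(n, spec$theta_range[1], spec$theta_range[2]) else NA_real_,
    lambda = spec$lambda,
    stringsAsFactors = FALSE
  )
}

#' Simulate compensation decisions on a schedule
#'
#' Fills the `decision` column of every self-error trial by sampling from the
#' softmax choice distribution of each participant's generating model at that
#' trial's harm level and wrongdoer count. With an infinite inverse
#' temperature the choice is the utility maximiser; an exact tie between two
#' adjacent options (a half-integer ideal point) resolves to the larger token
#' amount, the "half away from zero" convention used throughout the package.
#'
#' @param schedule Trial data frame from [build_schedule()]; self-error rows
#'   must carry `harm` and `wrongdoers`.
#' @param model A [utility_model()] shared by all participants.
#' @param agents Data frame of per-participant parameters as from
#'   [draw_agents()] (columns `participant_id`, `kappa`, `eta`, `theta`,
#'   `lambda`).
#' @param seed Integer seed; output is reproducible given the seed.
#' @param options Decision option set.
#' @return The schedule with `decision` filled on self-error trials.
#' @export
generate_decisions <- function(schedule, model, agents, seed = 1L,
                               options = 0:10) {
  validate_agent_params(model, agents)
  seeds <- derive_seeds(seed, nrow(agents))
  out <- schedule
  for (i in seq_len(nrow(agents))) {
    pid <- agents$participant_id[i]
    rows <- which(out$participant_id == pid & out$condition == "self_error")
    if (length(rows) == 0) next
    set.seed(seeds[i])
    pars <- as.list(agents[i, c("kappa", "eta", "theta", "lambda")])
    out$decision[rows] <- simulate_participant_decisions(
      model, pars, out$harm[rows], out$wrongdoers[rows], options)
  }
  out
}

validate_agent_params <- function(model, agents) {
  assert_that(all(c("participant_id", "kappa", "lambda") %in% names(agents)),
              "agents must have participant_id, kappa and lambda columns")
  assert_that(all(agents$kappa >= 0, na.rm = TRUE) &&
                all(agents$lambda >= 0, na.rm = TRUE),
              "kappa and lambda must be non-negative")
  if (model$baseline)
    assert_that(all(is.finite(agents$eta)), "model has a baseline: eta required")
  if (model$self_interest)
    assert_that(all(agents$theta >= 0 & agents$theta <= 1),
                "model has self-interest: theta in [0, 1] required")
  invisible(TRUE)
}

simulate_participant_decisions <- function(model, pars, H, W, options = 0:10) {
  n <- length(H)
  out <- integer(n)
  cell <- paste(H, W)
  for (uc in unique(cell)) {
    idx <- which(cell == uc)
    if (is.infinite(pars$lambda)) {
      u <- utility(model, pars, H[idx[1]], W[idx[1]], options,
                   endowment = max(options))
      out[idx] <- max(options[u == max(u)])  # ties -> larger amount
    } else {
      p <- choice_probabilities(model, pars, H[idx[1]], W[idx[1]], options)
      out[idx] <- sample(options, length(idx), replace = TRUE, prob = p)
    }
  }
  out
}

#' Generation model for guilt and shame ratings
#'
#' Ratings are produced per harm x responsibility cell (the post-game survey
#' collects one guilt and one shame rating per cell, 16 of each) as
#' `intercept + slope_H * H + slope_R * R + residual`, rounded half away from
#' zero and clipped to the 0-10 Likert scale. Participant heterogeneity
#' enters through Gaussian random intercepts and slopes. Default fixed slopes
#' are the package's reference values for the two emotions: harm acts more
#' strongly on guilt (0.74 vs. 0.23 rating units per level) while
#' responsibility acts more strongly on shame (0.57 vs. 0.93).
#'
#' @param guilt,shame Named numeric vectors with elements `intercept`,
#'   `slope_H`, `slope_R`.
#' @param intercept_sd Between-participant SD of the rating intercept.
#' @param slope_sd Between-participant SD of each slope.
#' @param residual_sd Within-participant residual SD.
#' @return An `emotion_gen_spec` object.
#' @export
emotion_gen_spec <- function(guilt = c(intercept = 0.5, slope_H = 0.74, slope_R = 0.57),
                             shame = c(intercept = 0.9, slope_H = 0.23, slope_R = 0.93),
                             intercept_sd = 0.8,
                             slope_sd = 0.3,
                             residual_sd = 0.8) {
  assert_that(residual_sd >= 0 && slope_sd >= 0 && intercept_sd >= 0,
              "SDs must be non-negative")
  structure(
    list(guilt = guilt, shame = shame, intercept_sd = intercept_sd,
         slope_sd = slope_sd, residual_sd = residual_sd,
         scale = c(0L, 10L)),
    class = "emotion_gen_spec"
  )
}

#' Simulate per-cell guilt and shame ratings
#'
#' @param design A [design_spec()].
#' @param spec An [emotion_gen_spec()].
#' @param participants Number of participants or character ids.
#' @param seed Integer seed.
#' @return A list with `emotions`, a long data frame (`participant_id`,
#'   `harm`, `responsibility`, `guilt`, `shame`) with one row per cell per
#'   participant, and `truth`, the per-participant generating slopes.
#' @export
generate_emotions <- function(design, spec, participants = 1, seed = 1L) {
  ids <- if (is.character(participants)) participants else {
    sprintf("P%02d", seq_len(participants))
  }
  set.seed(seed)
  cells <- expand.grid(harm = design$harm_levels,
                       responsibility = design$responsibility_levels)
  lo <- spec$scale[1]; hi <- spec$scale[2]
  rows <- vector("list", length(ids))
  truth <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    per <- list()
    for (emo in c("guilt", "shame")) {
      fx <- spec[[emo]]
      per[[emo]] <- c(
        intercept = fx[["intercept"]] + stats::rnorm(1, 0, spec$intercept_sd),
        slope_H = fx[["slope_H"]] + stats::rnorm(1, 0, spec$slope_sd),
        slope_R = fx[["slope_R"]] + stats::rnorm(1, 0, spec$slope_sd)
      )
    }
    rate <- function(p) {
      mu <- p[["intercept"]] + p[["slope_H"]] * cells$harm +
        p[["slope_R"]] * cells$responsibility
      clip(round_half_away(mu + stats::rnorm(nrow(cells), 0, spec$residual_sd)), lo, hi)
    }
    rows[[i]] <- data.frame(
      participant_id = ids[i], harm = cells$harm,
      responsibility = cells$responsibility,
      guilt = as.integer(rate(per$guilt)),
      shame = as.integer(rate(per$shame)),
      stringsAsFactors = FALSE
    )
    truth[[i]] <- data.frame(
      participant_id = ids[i],
      guilt_intercept = per$guilt[["intercept"]],
      guilt_slope_H = per$guilt[["slope_H"]],
      guilt_slope_R = per$guilt[["slope_R"]],
      shame_intercept = per$shame[["intercept"]],
      shame_slope_H = per$shame[["slope_H"]],
      shame_slope_R = per$shame[["slope_R"]],
      stringsAsFactors = FALSE
    )
  }
  list(emotions = do.call(rbind, rows), truth = do.call(rbind, truth))
}

#' Simulate emotion-mediated compensation decisions
#'
#' An alternative decision generator in which compensation is a noisy linear
#' function of the participant's own per-cell guilt and shame ratings,
#' `D = round(intercept + w_guilt * guilt + w_shame * shame + residual)`
#' clipped to the token range. Default weights are 0.22 tokens per guilt
#' rating unit and 0.10 per shame unit, the package's reference compensation
#' coefficients; this generator is what the compensation-regression stage is
#' tested against.
#'
#' @param schedule Trial schedule.
#' @param emotions Per-cell ratings from [generate_emotions()].
#' @param weights Named vector `c(intercept, guilt, shame)` in tokens.
#' @param residual_sd Decision noise SD in tokens.
#' @param seed Integer seed.
#' @param options Decision option set.
#' @return The schedule with decisions filled on self-error trials.
#' @export
generate_decisions_from_emotions <- function(schedule, emotions,
                                             weights = c(intercept = 1, guilt = 0.22, shame = 0.10),
                                             residual_sd = 1.0, seed = 1L,
                                             options = 0:10) {
  set.seed(seed)
  out <- schedule
  rows <- which(out$condition == "self_error")
  key <- paste(out$participant_id[rows], out$harm[rows], out$responsibility[rows])
  ekey <- paste(emotions$participant_id, emotions$harm, emotions$responsibility)
  idx <- match(key, ekey)
  assert_that(!anyNA(idx), "every self_error trial needs a matching emotion cell")
  mu <- weights[["intercept"]] + weights[["guilt"]] * emotions$guilt[idx] +
    weights[["shame"]] * emotions$shame[idx]
  d <- round_half_away(mu + stats::rnorm(length(rows), 0, residual_sd))
  out$decision[rows] <- as.integer(clip(d, min(options), max(options)))
  out
}

#' Simulate manipulation-check ratings
#'
#' Pain ratings (0-10) by harm level and perceived-responsibility ratings
#' (1-9) by responsibility level, plus a correct-estimate condition whose
#' mean sits below responsibility level 1. Cell means increase linearly
#' across levels; participants contribute Gaussian intercepts and residuals,
#' and ratings are rounded and clipped to their scales.
#'
#' @param design A [design_spec()].
#' @param participants Number of participants or character ids.
#' @param seed Integer seed.
#' @param pain_means Mean pain rating per harm level.
#' @param resp_means Mean responsibility rating per responsibility level.
#' @param correct_mean Mean responsibility rating after a correct estimate.
#' @param intercept_sd,residual_sd Participant and residual noise SDs.
#' @return A long data frame `participant_id`, `measure` (`"pain"` or
#'   `"responsibility"`), `level` (`"1"`..`"4"` or `"correct"`), `rating`.
#' @export
generate_manipulation_checks <- function(design, participants = 1, seed = 1L,
                                         pain_means = c(2, 4, 6, 8),
                                         resp_means = c(3, 4.5, 6, 7.5),
                                         correct_mean = 1.5,
                                         intercept_sd = 0.6,
                                         residual_sd = 0.8) {
  assert_that(correct_mean < resp_means[1],
              "correct-estimate mean must sit below responsibility level 1")
  ids <- if (is.character(participants)) participants else {
    sprintf("P%02d", seq_len(participants))
  }
  set.seed(seed)
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    b_pain <- stats::rnorm(1, 0, intercept_sd)
    b_resp <- stats::rnorm(1, 0, intercept_sd)
    pain <- clip(round_half_away(pain_means + b_pain +
                                   stats::rnorm(4, 0, residual_sd)), 0, 10)
    resp <- clip(round_half_away(c(resp_means, correct_mean) + b_resp +
                                   stats::rnorm(5, 0, residual_sd)), 1, 9)
    out[[i]] <- data.frame(
      participant_id = ids[i],
      measure = c(rep("pain", 4), rep("responsibility", 5)),
      level = c(as.character(1:4), as.character(1:4), "correct"),
      rating = as.integer(c(pain, resp)),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Simulate trait questionnaire scores
#'
#' Trait guilt (negative behaviour-evaluations, repair action tendencies),
#' trait shame (negative self-evaluations, withdrawal action tendencies),
#' trait gratitude and social value orientation are drawn as Gaussians.
#' Optionally a subset of traits is coupled to each participant's mean
#' compensation so that trait-correlation analyses have signal to detect.
#'
#' @param participants Number of participants or character ids.
#' @param seed Integer seed.
#' @param coupled_to Optional numeric vector (one value per participant,
#'   e.g. mean compensation) the coupled traits are linearly tied to.
#' @param coupling Named numeric vector of regression weights onto
#'   `coupled_to` for any subset of the trait columns.
#' @return A data frame of participant ids and six trait columns.
#' @export
generate_traits <- function(participants = 1, seed = 1L,
                            coupled_to = NULL,
                            coupling = c(repair_action = 0.6)) {
  ids <- if (is.character(participants)) participants else {
    sprintf("P%02d", seq_len(participants))
  }
  set.seed(seed)
  n <- length(ids)
  traits <- data.frame(
    participant_id = ids,
    negative_behavior_eval = stats::rnorm(n, 5.5, 1),
    repair_action = stats::rnorm(n, 5.5, 1),
    negative_self_eval = stats::rnorm(n, 4.5, 1),
    withdrawal_action = stats::rnorm(n, 4, 1),
    gratitude = stats::rnorm(n, 5.8, 0.8),
    svo = stats::rnorm(n, 25, 12),
    stringsAsFactors = FALSE
  )
  if (!is.null(coupled_to)) {
    assert_that(length(coupled_to) == n,
                "coupled_to must have one value per participant")
    z <- as.numeric(scale(coupled_to))
    for (nm in names(coupling)) {
      traits[[nm]] <- traits[[nm]] + coupling[[nm]] * z
    }
  }
  traits
}

#' Generate a complete synthetic study dataset
#'
#' Bundles the generators into one call: schedule, utility-model or
#' emotion-mediated decisions, per-cell emotion ratings, manipulation checks
#' and trait scores, together with the generating truth needed for recovery
#' tests.
#'
#' @param participants Number of participants.
#' @param design A [design_spec()].
#' @param agents An [agent_spec()], or `NULL` to generate decisions from the
#'   emotion-mediated model instead.
#' @param emotion_spec An [emotion_gen_spec()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param decision_weights Weights for the emotion-mediated decision
#'   generator (used when `agents` is `NULL`).
#' @return A list of class `synthetic_dataset`: `trials`, `emotions`,
#'   `checks`, `traits`, `truth` (generating parameters and slopes), `design`.
#' @export
simulate_dataset <- function(participants = 40,
                             design = design_spec(),
                             agents = agent_spec("1.3"),
                             emotion_spec = emotion_gen_spec(),
                             seed = 1L,
                             decision_weights = c(intercept = 1, guilt = 0.22, shame = 0.10)) {
  seeds <- derive_seeds(seed, 6)
  schedule <- build_schedule(design, participants, seed = seeds[1])
  emo <- generate_emotions(design, emotion_spec, participants, seed = seeds[2])
  if (is.null(agents)) {
    trials <- generate_decisions_from_emotions(schedule, emo$emotions,
                                               weights = decision_weights,
                                               seed = seeds[3])
    truth_params <- NULL
    gen_model <- "emotion_mediated"
  } else {
    truth_params <- draw_agents(agents, participants, seed = seeds[3])
    trials <- generate_decisions(schedule, agents$model, truth_params,
                                 seed = seeds[4])
    gen_model <- agents$model$id
  }
  checks <- generate_manipulation_checks(design, participants, seed = seeds[5])
  comp <- tapply(self_error_trials(trials)$decision,
                 self_error_trials(trials)$participant_id, mean)
  traits <- generate_traits(names(comp), seed = seeds[6],
                            coupled_to = as.numeric(comp))
  structure(
    list(trials = trials, emotions = emo$emotions, checks = checks,
         traits = traits,
         truth = list(model = gen_model, params = truth_params,
                      emotion_slopes = emo$truth,
                      decision_weights = if (is.null(agents)) decision_weights else NULL),
         design = design),
    class = "synthetic_dataset"
  )
}

#' Write a synthetic dataset bundle to disk
#'
#' Writes `trials.csv`, `emotions.csv`, `checks.csv`, `traits.csv` and
#' `truth.json` into `dir`.
#'
#' @param dataset A `synthetic_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_trials(dataset$trials, file.path(dir, "trials.csv"))
  utils::write.csv(dataset$emotions, file.path(dir, "emotions.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(dataset$checks, file.path(dir, "checks.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(dataset$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(dir)
}
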