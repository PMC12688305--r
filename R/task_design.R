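#' Design of the harm-by-responsibility interpersonal game
#'
#' `design_spec()` bundles the structural constants of the interpersonal
#' compensation game: a 4 (harm) x 4 (responsibility) within-subject factorial,
#' repeated 4 times, giving 64 experimental ("self-error") trials, interleaved
#' with 48 filler trials across 4 sessions of 16 + 12 trials. On every trial
#' the decider holds a 10-token endowment (1 token = 0.5 yuan) and allocates an
#' integer number of tokens, 0 to 10, to the receiver. Responsibility is
#' manipulated through the number of wrongdoers `W` (deciders who erred,
#' including the participant); the responsibility level is `R = 5 - W`.
#'
#' @param harm_levels Ordered integer harm levels.
#' @param responsibility_levels Ordered integer responsibility levels.
#' @param repeats_per_cell Repetitions of each harm x responsibility cell.
#' @param n_sessions Number of sessions the trials are split into.
#' @param exp_per_session Experimental trials per session.
#' @param filler_per_session Filler trials per session.
#' @param endowment_tokens Tokens endowed to the decider on each trial.
#' @param token_value Currency value of one token (yuan).
#' @param n_deciders Number of deciders in the game.
#' @param decision_options Integer token amounts available as decisions.
#'
#' @return An object of class `design_spec`.
#' @examples
#' spec <- design_spec()
#' n_experimental_trials(spec)  # 64
#' chance_accuracy(spec)        # 1/11
#' @export
design_spec <- function(harm_levels = 1:4,
                        responsibility_levels = 1:4,
                        repeats_per_cell = 4L,
                        n_sessions = 4L,
                        exp_per_session = 16L,
                        filler_per_session = 12L,
                        endowment_tokens = 10L,
                        token_value = 0.5,
                        n_deciders = 4L,
                        decision_options = 0:10) {
  spec <- structure(
    list(
      harm_levels = as.integer(harm_levels),
      responsibility_levels = as.integer(responsibility_levels),
      repeats_per_cell = as.integer(repeats_per_cell),
      n_sessions = as.integer(n_sessions),
      exp_per_session = as.integer(exp_per_session),
      filler_per_session = as.integer(filler_per_session),
      endowment_tokens = as.integer(endowment_tokens),
      token_value = token_value,
      n_deciders = as.integer(n_deciders),
      decision_options = as.integer(decision_options)
    ),
    class = "design_spec"
  )
  validate_design_spec(spec)
  spec
}

validate_design_spec <- function(spec) {
  n_exp <- n_experimental_trials(spec)
  assert_that(spec$exp_per_session * spec$n_sessions == n_exp,
              "exp_per_session * n_sessions must equal the number of experimental trials")
  assert_that(length(spec$decision_options) > 0,
              "decision_options must be non-empty")
  assert_that(identical(spec$decision_options, 0:spec$endowment_tokens),
              "decision_options must be the consecutive integers 0..endowment_tokens")
  assert_that(all(diff(spec$harm_levels) > 0) && all(diff(spec$responsibility_levels) > 0),
              "harm and responsibility levels must be strictly increasing")
  invisible(spec)
}

#' @rdname design_spec
#' @param spec A `design_spec`.
#' @export
n_experimental_trials <- function(spec) {
  length(spec$harm_levels) * length(spec$responsibility_levels) * spec$repeats_per_cell
}

#' @rdname design_spec
#' @export
n_filler_trials <- function(spec) {
  spec$filler_per_session * spec$n_sessions
}

#' @rdname design_spec
#' @export
n_total_trials <- function(spec) {
  n_experimental_trials(spec) + n_filler_trials(spec)
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Interpersonal game design:\n")
  cat(sprintf("  %d x %d factorial, %d repeats -> %d experimental trials\n",
              length(x$harm_levels), length(x$responsibility_levels),
              x$repeats_per_cell, n_experimental_trials(x)))
  cat(sprintf("  %d sessions of %d experimental + %d filler trials (%d total)\n",
              x$n_sessions, x$exp_per_session, x$filler_per_session,
              n_total_trials(x)))
  cat(sprintf("  endowment %d tokens (%.2f yuan/token), decisions %d..%d\n",
              x$endowment_tokens, x$token_value,
              min(x$decision_options), max(x$decision_options)))
  invisible(x)
}

#' Chance level of predicting a compensation decision
#'
#' With `m` available token amounts a random guesser matches the observed
#' decision with probability `1/m`; for the default 11-option set this is
#' 1/11, i.e. 9% to integer precision. Used as the null in the predictive
#' accuracy test.
#'
#' @param spec A [design_spec()].
#' @return A single proportion.
#' @export
chance_accuracy <- function(spec) {
  assert_that(length(spec$decision_options) > 0, "decision_options must be non-empty")
  1 / length(spec$decision_options)
}

#' Token-economy bounds of the game
#'
#' The receiver can collect at most one full endowment from each decider; the
#' decider can lose at most their own endowment, valued in yuan.
#'
#' @param spec A [design_spec()].
#' @return A list with `max_receiver_income_tokens` and `max_self_loss_yuan`.
#' @export
token_economy <- function(spec) {
  list(
    max_receiver_income_tokens = spec$n_deciders * spec$endowment_tokens,
    max_self_loss_yuan = spec$endowment_tokens * spec$token_value
  )
}

#' Build the pseudo-random trial schedule
#'
#' Constructs, for each participant, the full within-subject schedule: every
#' harm x responsibility cell exactly `repeats_per_cell` times, partitioned
#' into sessions of `exp_per_session` experimental plus `filler_per_session`
#' filler trials. Order within a session is a uniform shuffle constrained so
#' that the same cell never occupies two consecutive experimental trials; the
#' constraint is abandoned after 1000 failed shuffles (it is almost never
#' binding at the default design). Decisions are left missing.
#'
#' @param spec A [design_spec()].
#' @param participants Number of participants, or a character vector of ids.
#' @param seed Integer seed; the schedule is reproducible given the seed.
#' @return A data frame of trial records with columns `participant_id`,
#'   `trial_index`, `session`, `condition` (`"self_error"` or `"filler"`),
#'   `harm`, `wrongdoers`, `responsibility` (all `NA` on fillers), `decision`
#'   (`NA`, to be filled by [generate_decisions()] or observed data).
#' @examples
#' sched <- build_schedule(design_spec(), participants = 1, seed = 1)
#' table(sched$condition)
#' @export
build_schedule <- function(spec, participants = 1, seed = 1L) {
  validate_design_spec(spec)
  ids <- if (is.character(participants)) participants else {
    sprintf("P%02d", seq_len(participants))
  }
  seeds <- derive_seeds(seed, length(ids))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    out[[i]] <- schedule_one(spec, ids[i], seeds[i])
  }
  do.call(rbind, out)
}

schedule_one <- function(spec, id, seed) {
  set.seed(seed)
  cells <- expand.grid(harm = spec$harm_levels,
                       responsibility = spec$responsibility_levels)
  exp_trials <- cells[rep(seq_len(nrow(cells)), spec$repeats_per_cell), ]
  exp_trials <- exp_trials[sample.int(nrow(exp_trials)), ]
  exp_trials$session <- rep(seq_len(spec$n_sessions), each = spec$exp_per_session)

  sessions <- vector("list", spec$n_sessions)
  for (s in seq_len(spec$n_sessions)) {
    es <- exp_trials[exp_trials$session == s, c("harm", "responsibility")]
    n_exp <- nrow(es)
    n_fill <- spec$filler_per_session
    cell_id <- c(paste(es$harm, es$responsibility), rep(NA_character_, n_fill))
    ord <- shuffle_no_consecutive(cell_id, max_attempts = 1000L)
    is_exp <- ord <= n_exp
    sess <- data.frame(
      session = s,
      condition = ifelse(is_exp, "self_error", "filler"),
      harm = ifelse(is_exp, es$harm[ord], NA_integer_),
      responsibility = ifelse(is_exp, es$responsibility[ord], NA_integer_),
      stringsAsFactors = FALSE
    )
    sessions[[s]] <- sess
  }
  sched <- do.call(rbind, sessions)
  sched$wrongdoers <- ifelse(is.na(sched$responsibility), NA_integer_,
                             5L - sched$responsibility)
  data.frame(
    participant_id = id,
    trial_index = seq_len(nrow(sched)),
    session = sched$session,
    condition = sched$condition,
    harm = as.integer(sched$harm),
    wrongdoers = as.integer(sched$wrongdoers),
    responsibility = as.integer(sched$responsibility),
    decision = NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Permutation of seq_along(labels) such that no two consecutive non-NA labels
# are equal; falls back to an unconstrained shuffle after max_attempts.
shuffle_no_consecutive <- function(labels, max_attempts = 1000L) {
  n <- length(labels)
  for (attempt in seq_len(max_attempts)) {
    ord <- sample.int(n)
    lab <- labels[ord]
    adjacent <- !is.na(lab[-n]) & !is.na(lab[-1]) & lab[-n] == lab[-1]
    if (!any(adjacent)) return(ord)
  }
  sample.int(n)
}

#' Read and write trial schedules as CSV
#'
#' The interchange layout has one row per trial with columns `participant_id`,
#' `trial_index`, `session`, `condition`, `harm`, `wrongdoers`,
#' `responsibility`, `decision`; missing values are empty fields and indices
#' are 1-based.
#'
#' @param trials A trial data frame as produced by [build_schedule()].
#' @param path File path.
#' @return `read_trials()` returns the trial data frame; `write_trials()`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @param col_map Optional named character vector mapping the file's column
#'   names onto the canonical ones, e.g. `c(subject = "participant_id")`, so
#'   externally deposited spreadsheets can be ingested without editing.
#' @export
read_trials <- function(path, col_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(col_map)) {
    idx <- match(names(col_map), names(df))
    assert_that(!anyNA(idx), "col_map names missing from file columns")
    names(df)[idx] <- unname(col_map)
  }
  needed <- c("participant_id", "trial_index", "session", "condition",
              "harm", "wrongdoers", "responsibility", "decision")
  missing <- setdiff(needed, names(df))
  assert_that(length(missing) == 0,
              paste("missing trial columns:", paste(missing, collapse = ", ")))
  for (col in c("trial_index", "session", "harm", "wrongdoers",
                "responsibility", "decision")) {
    df[[col]] <- as.integer(df[[col]])
  }
  df[needed]
}

self_error_trials <- function(trials) {
  trials[trials$condition == "self_error", , drop = FALSE]
}
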