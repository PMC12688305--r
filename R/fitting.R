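#' Parameter bounds for maximum-likelihood fitting
#'
#' Box constraints used by the fitter, chosen so that ideal points stay near
#' the 0-10 token range: `kappa` in \[0, 10\] for the diffusion family (where
#' the attributed harm `H/W` is at most 4) but \[0, 2.5\] for the
#' amplification family (where `H*R` reaches 16); `eta` in \[0, 10\]; `theta`
#' in \[0, 1\]; `lambda` in \[0, 20\].
#'
#' @param model A [utility_model()].
#' @return Named list of `c(lower, upper)` pairs for the model's free
#'   parameters.
#' @export
default_bounds <- function(model) {
  kappa_hi <- if (model$family == "diffusion") 10 else 2.5
  all <- list(theta = c(0, 1), kappa = c(0, kappa_hi), eta = c(0, 10),
              lambda = c(0, 20))
  all[model$free_params]
}

# Coarse start grid: 5 evenly spaced points per free parameter within its
# bounds, except lambda which is log-spaced over [0.1, upper] plus 0 (choice
# stochasticity varies over orders of magnitude).
coarse_grid <- function(model, bounds = default_bounds(model), points = 5L) {
  axes <- lapply(model$free_params, function(p) {
    b <- bounds[[p]]
    if (p == "lambda") {
      c(0, exp(seq(log(max(b[1], 0.1)), log(b[2]), length.out = points)))
    } else {
      seq(b[1], b[2], length.out = points)
    }
  })
  names(axes) <- model$free_params
  as.matrix(expand.grid(axes))
}

full_params <- function(model, free) {
  pars <- list(kappa = 0, eta = 0, theta = 0, lambda = 1)
  pars[names(free)] <- as.list(free)
  pars
}

#' Fit one participant by maximum likelihood
#'
#' Maximises the softmax log-likelihood of one participant's decisions under
#' one utility model. A coarse grid over the free-parameter box picks the
#' best start location, from which a bounded quasi-Newton search (L-BFGS-B)
#' refines the estimate; if the local search fails the best grid point is
#' returned with `converged = FALSE`. The procedure is deterministic given
#' the data, grid and bounds.
#'
#' A participant whose decisions are all zero is flagged `excluded = TRUE`
#' and not fitted: with every choice at the boundary the parameters are not
#' reliably estimable (such a participant is dropped from modelling).
#'
#' @param model A [utility_model()].
#' @param trials Trial data frame for a single participant (self-error rows
#'   with decisions).
#' @param bounds Named list of `c(lower, upper)` per free parameter.
#' @param grid_points Grid resolution per free parameter.
#' @param options Decision option set.
#' @return A one-row data frame: `participant_id`, `model`, `kappa`, `eta`,
#'   `theta`, `lambda` (`NA` where unused), `loglik`, `n_trials`, `bic`,
#'   `converged`, `excluded`.
#' @export
fit_participant <- function(model, trials, bounds = default_bounds(model),
                            grid_points = 5L, options = 0:10) {
  tr <- self_error_trials(trials)
  tr <- tr[!is.na(tr$decision), , drop = FALSE]
  assert_that(nrow(tr) >= 1, "need at least one self_error trial with a decision")
  pid <- unique(tr$participant_id)
  assert_that(length(pid) == 1, "fit_participant expects a single participant")
  n <- nrow(tr)

  if (all(tr$decision == 0)) {
    return(fit_row(pid, model, rep(NA_real_, model$k), NA_real_, n,
                   converged = FALSE, excluded = TRUE))
  }

  H <- tr$harm; W <- tr$wrongdoers; D <- tr$decision
  negll <- function(x) {
    -ll_from_cells(model, full_params(model, stats::setNames(x, model$free_params)),
                   H, W, D, options)
  }

  grid <- coarse_grid(model, bounds, grid_points)
  gvals <- apply(grid, 1, negll)
  best <- which.min(gvals)
  start <- grid[best, ]
  lower <- vapply(bounds[model$free_params], `[`, numeric(1), 1)
  upper <- vapply(bounds[model$free_params], `[`, numeric(1), 2)

  opt <- tryCatch(
    stats::optim(start, negll, method = "L-BFGS-B", lower = lower,
                 upper = upper, control = list(factr = 1e7, maxit = 500)),
    error = function(e) NULL
  )
  if (is.null(opt) || opt$value > gvals[best] + 1e-9) {
    est <- grid[best, ]
    ll <- -gvals[best]
    converged <- FALSE
  } else {
    # guard against numerical dust just outside the box
    est <- pmin(pmax(opt$par, lower), upper)
    ll <- -opt$value
    converged <- opt$convergence == 0
  }
  fit_row(pid, model, est, ll, n, converged, excluded = FALSE)
}

fit_row <- function(pid, model, est, ll, n, converged, excluded) {
  pars <- c(kappa = NA_real_, eta = NA_real_, theta = NA_real_, lambda = NA_real_)
  if (!excluded) pars[model$free_params] <- est
  data.frame(
    participant_id = pid, model = model$id,
    kappa = pars[["kappa"]], eta = pars[["eta"]], theta = pars[["theta"]],
    lambda = pars[["lambda"]],
    loglik = ll, n_trials = n,
    bic = model$k * log(n) - 2 * ll,
    converged = converged, excluded = excluded,
    stringsAsFactors = FALSE
  )
}

#' Fit a cohort under one or several models
#'
#' Applies [fit_participant()] to every participant in `trials` for each
#' requested model id.
#'
#' @param trials Trial data frame for the cohort.
#' @param models Character vector of model ids (default: all eight).
#' @param ... Passed to [fit_participant()].
#' @return Row-bound data frame of fit results.
#' @export
fit_cohort <- function(trials, models = model_ids(), ...) {
  tr <- self_error_trials(trials)
  pids <- unique(tr$participant_id)
  out <- list()
  for (mid in models) {
    model <- utility_model(mid)
    for (pid in pids) {
      out[[length(out) + 1L]] <-
        fit_participant(model, tr[tr$participant_id == pid, ], ...)
    }
  }
  do.call(rbind, out)
}

#' Compare fitted models by summed BIC
#'
#' Aggregates per-participant BIC values across the cohort for each model
#' (fixed-effects model comparison) and declares the model with the lowest
#' summed BIC the winner; exact ties break toward the model with fewer free
#' parameters. Excluded participants are dropped from every model's sum so
#' the comparison stays balanced.
#'
#' @param fits Fit results from [fit_cohort()] covering every
#'   participant x model combination.
#' @return A `model_comparison` list: `table` (model, k, summed BIC,
#'   delta BIC, n participants), `bic_matrix` (participants x models),
#'   `winner`.
#' @export
compare_models <- function(fits) {
  fits <- fits[!fits$excluded, , drop = FALSE]
  models <- sort(unique(fits$model))
  pids <- sort(unique(fits$participant_id))
  bic <- matrix(NA_real_, length(pids), length(models),
                dimnames = list(pids, models))
  for (i in seq_len(nrow(fits))) {
    bic[fits$participant_id[i], fits$model[i]] <- fits$bic[i]
  }
  if (anyNA(bic)) {
    gaps <- which(is.na(bic), arr.ind = TRUE)
    stop("missing fits for: ",
         paste(sprintf("%s x %s", rownames(bic)[gaps[, 1]],
                       colnames(bic)[gaps[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  summed <- colSums(bic)
  k <- vapply(models, function(m) utility_model(m)$k, numeric(1))
  ord <- order(summed, k)
  winner <- models[ord[1]]
  tab <- data.frame(
    model = models, k = k, bic_sum = summed,
    delta_bic = summed - min(summed),
    n_participants = length(pids),
    stringsAsFactors = FALSE, row.names = NULL
  )
  tab <- tab[order(tab$bic_sum, tab$k), ]
  structure(list(table = tab, bic_matrix = bic, winner = winner),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison over %d participants; winner: %s\n",
              x$table$n_participants[1], x$winner))
  print(x$table, row.names = FALSE, digits = 6)
  invisible(x)
}
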