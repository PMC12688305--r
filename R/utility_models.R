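#' The eight-model utility family for compensatory decisions
#'
#' Two model families formalise how a decider integrates the harm level `H`
#' (1-4) with their share of responsibility when choosing how many tokens `D`
#' (0-10) to give the receiver:
#'
#' * **Diffusion family (1.x)** — responsibility is divided among the `W`
#'   wrongdoers, so the felt obligation scales with the average harm per
#'   wrongdoer, `H / W`.
#' * **Amplification family (2.x)** — responsibility multiplies harm, giving
#'   `H * R` with `R = 5 - W`.
#'
#' Within each family the four variants cross two components: whether
#' self-interest (the retained tokens, weighted by greed `theta`) enters the
#' utility, and whether a compensatory baseline `eta` exists. The full model
#' (x.1) is
#' `U(D) = theta * (10 - D) - (1 - theta) * |kappa * A + eta - D|`
#' where `A` is `H/W` (family 1) or `H*R` (family 2); x.2 drops `eta`, x.3
#' drops self-interest, x.4 drops both. `kappa` is the compensatory
#' sensitivity (tokens per unit of attributed harm), `eta` the compensatory
#' baseline (tokens given regardless of harm), and the absolute value encodes
#' aversion to both under- and over-compensation relative to the ideal amount
#' `kappa * A + eta`.
#'
#' @param id Model label, one of `"1.1"`, `"1.2"`, `"1.3"`, `"1.4"`, `"2.1"`,
#'   `"2.2"`, `"2.3"`, `"2.4"`.
#' @return A `utility_model` object with fields `id`, `family`
#'   (`"diffusion"` or `"amplification"`), `self_interest`, `baseline`,
#'   `free_params` (ordered subset of `theta`, `kappa`, `eta`, `lambda`) and
#'   `k`, the number of free parameters.
#' @examples
#' m <- utility_model("1.3")
#' utility(m, list(kappa = 2, eta = 1), H = 4, W = 2, D = 0:10)
#' @export
utility_model <- function(id) {
  id <- as.character(id)
  assert_that(id %in% model_ids(), paste("unknown model id:", id))
  fam <- if (startsWith(id, "1")) "diffusion" else "amplification"
  variant <- substring(id, 3)
  self_interest <- variant %in% c("1", "2")
  baseline <- variant %in% c("1", "3")
  free <- c(if (self_interest) "theta", "kappa", if (baseline) "eta", "lambda")
  structure(
    list(id = id, family = fam, self_interest = self_interest,
         baseline = baseline, free_params = free, k = length(free)),
    class = "utility_model"
  )
}

#' @rdname utility_model
#' @export
model_ids <- function() {
  c("1.1", "1.2", "1.3", "1.4", "2.1", "2.2", "2.3", "2.4")
}

#' @export
print.utility_model <- function(x, ...) {
  cat(sprintf("Utility model %s (%s family, %s, %s); free: %s\n",
              x$id, x$family,
              if (x$self_interest) "self-interest" else "no self-interest",
              if (x$baseline) "baseline" else "no baseline",
              paste(x$free_params, collapse = ", ")))
  invisible(x)
}

# Attributed harm A: the quantity kappa multiplies.
attributed_harm <- function(model, H, W) {
  if (model$family == "diffusion") H / W else H * (5 - W)
}

#' Utility of a compensation decision
#'
#' Evaluates `U(D)` for the given model at harm level `H`, wrongdoer count
#' `W`, and decision(s) `D`. Ideal points `kappa * A + eta` may be
#' non-integer; no rounding is applied — the absolute-value distance handles
#' fractional ideal points.
#'
#' @param model A [utility_model()].
#' @param params Named list or vector with elements among `kappa`, `eta`,
#'   `theta` (only those the model uses are read; missing `eta` is 0, missing
#'   `theta` is 0).
#' @param H Harm level in 1..4.
#' @param W Number of wrongdoers in 1..4.
#' @param D Decision(s), integer tokens within the option set.
#' @param endowment Endowment entering the self-interest term.
#' @return Numeric vector of utilities, one per element of `D`.
#' @export
utility <- function(model, params, H, W, D, endowment = 10) {
  params <- as.list(params)
  assert_that(all(H %in% 1:4) && all(W %in% 1:4), "H and W must lie in 1..4")
  assert_that(all(D >= 0 & D <= endowment & D == floor(D)),
              "D outside the decision option set")
  kappa <- params$kappa
  eta <- if (model$baseline) params$eta %||% 0 else 0
  theta <- if (model$self_interest) params$theta %||% 0 else 0
  ideal <- kappa * attributed_harm(model, H, W) + eta
  theta * (endowment - D) - (1 - theta) * abs(ideal - D)
}

#' Softmax choice probabilities over the decision set
#'
#' Maps utilities to choice probabilities with the softmax rule
#' `P(D) = exp(lambda * U(D)) / sum_j exp(lambda * U(D_j))`, where `lambda`
#' is the inverse temperature (0 gives uniform choice; large values approach
#' the utility maximiser). Exponents are stabilised by subtracting
#' `max(lambda * U)` so large `lambda * U` cannot overflow. `lambda = Inf` is
#' accepted and returns the uniform distribution over the argmax set.
#'
#' @inheritParams utility
#' @param params Named list including `lambda` in addition to the model's
#'   utility parameters.
#' @param options Integer vector of available decisions.
#' @return Named probability vector over `options`, summing to 1.
#' @export
choice_probabilities <- function(model, params, H, W, options = 0:10) {
  params <- as.list(params)
  lambda <- params$lambda
  assert_that(!is.null(lambda) && lambda >= 0, "lambda must be present and >= 0")
  u <- utility(model, params, H, W, options, endowment = max(options))
  p <- softmax_rows(matrix(u, nrow = 1), lambda)[1, ]
  names(p) <- options
  p
}

# Row-wise stabilised softmax of lambda * U. Handles lambda = Inf as the
# uniform distribution over each row's maximisers.
softmax_rows <- function(U, lambda) {
  if (is.infinite(lambda)) {
    best <- U == apply(U, 1, max)
    return(best / rowSums(best))
  }
  Z <- lambda * U
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Log-likelihood of observed decisions under a utility model
#'
#' Sums `log P(D_t)` over the experimental (self-error) trials of one
#' participant, with the softmax choice probabilities of the model evaluated
#' at each trial's harm level and wrongdoer count.
#'
#' @param model A [utility_model()].
#' @param params Named parameter list (`kappa`, `lambda`, and `eta`/`theta`
#'   when the model uses them).
#' @param trials Trial data frame; only `self_error` rows with non-missing
#'   decisions are used and must all carry `harm` and `wrongdoers`.
#' @param options Decision option set.
#' @return Total log-likelihood (finite for finite `lambda`).
#' @export
log_likelihood <- function(model, params, trials, options = 0:10) {
  tr <- self_error_trials(trials)
  tr <- tr[!is.na(tr$decision), , drop = FALSE]
  assert_that(nrow(tr) > 0, "no self_error trials with decisions")
  ll_from_cells(model, as.list(params), tr$harm, tr$wrongdoers, tr$decision,
                options)
}

# Core likelihood kernel: probabilities are computed once per unique (H, W)
# cell and indexed per trial.
ll_from_cells <- function(model, params, H, W, D, options = 0:10) {
  cell <- (H - 1L) * 4L + W
  uc <- sort(unique(cell))
  Hc <- (uc - 1L) %/% 4L + 1L
  Wc <- (uc - 1L) %% 4L + 1L
  A <- attributed_harm(model, Hc, Wc)
  eta <- if (model$baseline) params$eta %||% 0 else 0
  theta <- if (model$self_interest) params$theta %||% 0 else 0
  ideal <- params$kappa * A + eta
  endow <- max(options)
  U <- theta * outer(rep(1, length(uc)), endow - options) -
    (1 - theta) * abs(outer(ideal, options, `-`))
  P <- softmax_rows(U, params$lambda)
  row <- match(cell, uc)
  col <- match(D, options)
  sum(log(P[cbind(row, col)]))
}
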