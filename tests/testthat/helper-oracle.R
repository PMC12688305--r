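# Independent brute-force oracle for the utility family and softmax rule.
# Everything here is written directly from the model equations with plain
# loops and direct summation over the 11 options; it shares no code with the
# package internals it checks.

oracle_utility <- function(id, pars, H, W, D) {
  R <- 5 - W
  A <- if (substr(id, 1, 1) == "1") H / W else H * R
  eta <- if (id %in% c("1.1", "1.3", "2.1", "2.3")) pars$eta else 0
  ideal <- pars$kappa * A + eta
  if (id %in% c("1.1", "1.2", "2.1", "2.2")) {
    pars$theta * (10 - D) - (1 - pars$theta) * abs(ideal - D)
  } else {
    -abs(ideal - D)
  }
}

oracle_probs <- function(id, pars, H, W) {
  u <- numeric(11)
  for (d in 0:10) u[d + 1] <- oracle_utility(id, pars, H, W, d)
  w <- numeric(11)
  for (j in 1:11) w[j] <- exp(pars$lambda * u[j])
  w / sum(w)
}

oracle_loglik <- function(id, pars, H, W, D) {
  total <- 0
  for (t in seq_along(D)) {
    p <- oracle_probs(id, pars, H[t], W[t])
    total <- total + log(p[D[t] + 1])
  }
  total
}

# Minimal trial data frame for hand-built cases.
make_trials <- function(H, W, D = NA_integer_, pid = "P01") {
  n <- max(length(H), length(W))
  data.frame(
    participant_id = pid,
    trial_index = seq_len(n),
    session = 1L,
    condition = "self_error",
    harm = as.integer(rep_len(H, n)),
    wrongdoers = as.integer(rep_len(W, n)),
    responsibility = 5L - as.integer(rep_len(W, n)),
    decision = as.integer(rep_len(D, n)),
    stringsAsFactors = FALSE
  )
}

# Random valid parameter set for a model id, with lambda kept moderate so the
# oracle's unstabilised exponentials cannot overflow.
random_params <- function(id, lambda_max = 5) {
  m <- utility_model(id)
  list(
    kappa = runif(1, 0, if (m$family == "diffusion") 4 else 1.5),
    eta = if (m$baseline) runif(1, 0, 3) else 0,
    theta = if (m$self_interest) runif(1, 0, 1) else 0,
    lambda = runif(1, 0, lambda_max)
  )
}
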