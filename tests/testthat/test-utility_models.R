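test_that("model registry encodes the family / self-interest / baseline grid", {
  ks <- c("1.1" = 4, "1.2" = 3, "1.3" = 3, "1.4" = 2,
          "2.1" = 4, "2.2" = 3, "2.3" = 3, "2.4" = 2)
  for (id in model_ids()) {
    m <- utility_model(id)
    expect_equal(m$k, unname(ks[id]), info = id)
    expect_equal(m$k, length(m$free_params), info = id)
    expect_true("lambda" %in% m$free_params, info = id)
    expect_equal("theta" %in% m$free_params, m$self_interest, info = id)
    expect_equal("eta" %in% m$free_params, m$baseline, info = id)
    expect_equal(m$family,
                 if (startsWith(id, "1")) "diffusion" else "amplification")
  }
  expect_error(utility_model("3.1"), "unknown")
})

test_that("utilities match hand-computed ideal-point distances", {
  m13 <- utility_model("1.3")
  # ideal point kappa*H/W + eta = 2*2 + 1 = 5
  expect_equal(utility(m13, list(kappa = 2, eta = 1), H = 4, W = 2, D = 5), 0)
  expect_equal(utility(m13, list(kappa = 2, eta = 1), H = 4, W = 2, D = 3), -2)

  m23 <- utility_model("2.3")
  # amplification: ideal = kappa*H*R = 0.5*3*4 = 6
  expect_equal(utility(m23, list(kappa = 0.5, eta = 0), H = 3, W = 1, D = 6), 0)

  # pure greed limit of the full model: U(D) = 10 - D
  m11 <- utility_model("1.1")
  expect_equal(
    utility(m11, list(theta = 1, kappa = 3, eta = 2), H = 2, W = 2, D = 0:10),
    10 - 0:10
  )

  expect_error(utility(m13, list(kappa = 2, eta = 1), H = 4, W = 2, D = 11),
               "option set")
})

test_that("softmax probabilities behave at the temperature limits", {
  m <- utility_model("1.3")
  p0 <- choice_probabilities(m, list(kappa = 2, eta = 1, lambda = 0), 4, 2)
  expect_equal(unname(p0), rep(1 / 11, 11))

  p_cold <- choice_probabilities(m, list(kappa = 2, eta = 1, lambda = 50), 4, 2)
  expect_gt(p_cold[["5"]], 0.999)

  # softmax is invariant to adding a constant to every utility
  U <- matrix(runif(11, -5, 0), nrow = 1)
  expect_equal(moralcomp:::softmax_rows(U, 2),
               moralcomp:::softmax_rows(U + 7.3, 2))

  # large lambda*U does not overflow thanks to max-subtraction
  p_big <- choice_probabilities(m, list(kappa = 9, eta = 9, lambda = 20), 4, 1)
  expect_true(all(is.finite(p_big)))
  expect_equal(sum(p_big), 1, tolerance = 1e-12)
})

test_that("probabilities equal the direct-summation oracle", {
  # printed case: model 1.4, kappa = 1, lambda = 1, H = 2, W = 2 -> ideal 1
  m14 <- utility_model("1.4")
  pars <- list(kappa = 1, lambda = 1)
  p <- choice_probabilities(m14, pars, H = 2, W = 2)
  manual <- exp(-abs(1 - 0:10)) / sum(exp(-abs(1 - 0:10)))
  expect_equal(unname(p), manual, tolerance = 1e-12)

  set.seed(101)
  for (i in 1:50) {
    id <- sample(model_ids(), 1)
    pars <- random_params(id)
    H <- sample(1:4, 1); W <- sample(1:4, 1)
    p <- choice_probabilities(utility_model(id), pars, H, W)
    expect_equal(unname(p), oracle_probs(id, pars, H, W), tolerance = 1e-12)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})

test_that("the two families imply different ideal points when kappa > 0", {
  set.seed(5)
  for (i in 1:20) {
    kappa <- runif(1, 0.1, 3)
    cells <- expand.grid(H = 1:4, W = 1:4)
    diffusion <- kappa * cells$H / cells$W
    amplification <- kappa * cells$H * (5 - cells$W)
    expect_true(any(abs(diffusion - amplification) > 1e-8))
  }
})

test_that("log-likelihood sums per-trial log choice probabilities", {
  m <- utility_model("1.3")
  sched <- build_schedule(design_spec(), 1, seed = 2)
  trials <- sched[sched$condition == "self_error", ]
  trials$decision <- 5L

  # lambda = 0: every trial contributes log(1/11)
  expect_equal(log_likelihood(m, list(kappa = 2, eta = 1, lambda = 0), trials),
               64 * log(1 / 11))

  # near-deterministic probability at the ideal point gives ~0
  one <- make_trials(H = 4, W = 2, D = 5)
  expect_gt(log_likelihood(m, list(kappa = 2, eta = 1, lambda = 20), one),
            -1e-6)

  # three-trial toy set against the brute-force oracle
  toy <- make_trials(H = c(2, 4, 1), W = c(2, 1, 4), D = c(1, 4, 0))
  pars <- list(kappa = 1, lambda = 1)
  expect_equal(log_likelihood(utility_model("1.4"), pars, toy),
               oracle_loglik("1.4", c(pars, eta = 0, theta = 0),
                             toy$harm, toy$wrongdoers, toy$decision),
               tolerance = 1e-10)

  expect_error(log_likelihood(m, list(kappa = 1, eta = 0, lambda = 1),
                              trials[0, ]), "no self_error")
})
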