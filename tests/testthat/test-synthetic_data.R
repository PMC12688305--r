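test_that("deterministic and uniform choice limits generate as expected", {
  m <- utility_model("1.3")
  one <- make_trials(H = 4, W = 2)
  det <- data.frame(participant_id = "P01", kappa = 2, eta = 1, theta = NA,
                    lambda = Inf)
  out <- generate_decisions(one, m, det, seed = 1)
  expect_equal(out$decision, 5L)  # argmax of -|2*2 + 1 - D|

  # lambda = 0 gives uniform decisions over 0..10
  unif <- data.frame(participant_id = "P01", kappa = 2, eta = 1, theta = NA,
                     lambda = 0)
  many <- make_trials(H = rep(2, 10000), W = 2)
  draws <- generate_decisions(many, m, unif, seed = 2)$decision
  gof <- chisq.test(table(factor(draws, levels = 0:10)))
  expect_gt(gof$p.value, 0.01)

  # large lambda concentrates on the utility maximiser
  cold <- data.frame(participant_id = "P01", kappa = 2, eta = 1, theta = NA,
                     lambda = 20)
  draws_cold <- generate_decisions(many, m, cold, seed = 3)$decision
  expect_gte(mean(draws_cold == 3), 0.99)  # ideal point 2*(2/2) + 1 = 3
})

test_that("empirical decision frequencies match the softmax distribution", {
  m14 <- utility_model("1.4")
  pars <- data.frame(participant_id = "P01", kappa = 1, eta = NA, theta = NA,
                     lambda = 1)
  many <- make_trials(H = rep(2, 20000), W = 2)
  draws <- generate_decisions(many, m14, pars, seed = 4)$decision
  p1 <- exp(-abs(1 - 0:10)) / sum(exp(-abs(1 - 0:10)))
  expect_equal(mean(draws == 1), p1[2], tolerance = 0.01)
})

test_that("generated datasets stay in range and reproduce byte-identically", {
  ds <- simulate_dataset(participants = 6, seed = 9)
  se <- ds$trials[ds$trials$condition == "self_error", ]
  expect_true(all(se$decision %in% 0:10))
  expect_true(all(ds$emotions$guilt %in% 0:10))
  expect_true(all(ds$emotions$shame %in% 0:10))
  expect_true(all(ds$checks$rating[ds$checks$measure == "pain"] %in% 0:10))
  expect_true(all(ds$checks$rating[ds$checks$measure == "responsibility"] %in% 1:9))
  expect_equal(nrow(ds$emotions), 6 * 16)

  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(participants = 3, seed = 77), dir1)
  write_dataset(simulate_dataset(participants = 3, seed = 77), dir2)
  for (f in c("trials.csv", "emotions.csv", "checks.csv", "traits.csv")) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
})

test_that("emotion generator obeys its noise-free and clipping limits", {
  design <- design_spec()
  quiet <- emotion_gen_spec(
    guilt = c(intercept = 0, slope_H = 0.74, slope_R = 0.57),
    shame = c(intercept = 0, slope_H = 0.23, slope_R = 0.93),
    intercept_sd = 0, slope_sd = 0, residual_sd = 0
  )
  em <- generate_emotions(design, quiet, 1, seed = 1)$emotions
  cell <- em[em$harm == 4 & em$responsibility == 4, ]
  expect_equal(cell$guilt, round(0.74 * 4 + 0.57 * 4))  # 5

  ceiling_spec <- emotion_gen_spec(
    guilt = c(intercept = 20, slope_H = 0.74, slope_R = 0.57),
    shame = c(intercept = 20, slope_H = 0.23, slope_R = 0.93),
    intercept_sd = 0, slope_sd = 0, residual_sd = 0
  )
  em2 <- generate_emotions(design, ceiling_spec, 2, seed = 1)$emotions
  expect_true(all(em2$guilt == 10) && all(em2$shame == 10))
})

test_that("generated guilt ratings recover the harm slope by regression", {
  # the estimate is unbiased with SD ~0.06 per 40-participant cohort;
  # averaging three cohorts keeps Monte-Carlo error well inside the band
  slopes <- sapply(1:3, function(s) {
    ds <- generate_emotions(design_spec(), emotion_gen_spec(), 40, seed = 30 + s)
    reg <- emotion_regression(ds$emotions, "harm")
    reg$simple_slopes$estimate[reg$simple_slopes$emotion == "guilt"]
  })
  expect_equal(mean(slopes), 0.74, tolerance = 0.1)
})

test_that("manipulation-check generator orders conditions correctly", {
  noise_free <- generate_manipulation_checks(design_spec(), 5, seed = 1,
                                             intercept_sd = 0, residual_sd = 0)
  pain <- noise_free[noise_free$measure == "pain", ]
  means <- tapply(pain$rating, pain$level, mean)
  expect_true(all(diff(means[as.character(1:4)]) > 0))

  resp <- noise_free[noise_free$measure == "responsibility", ]
  rmeans <- tapply(resp$rating, resp$level, mean)
  expect_lt(rmeans[["correct"]], rmeans[["1"]])

  expect_error(
    generate_manipulation_checks(design_spec(), 2, correct_mean = 5),
    "below responsibility"
  )
})
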