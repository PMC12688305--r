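# Continuous noise-free emotion table: every participant shares the
# generating slopes exactly (no rounding), so regression stages must return
# the generating coefficients to solver tolerance.
noise_free_emotions <- function(n = 12, g = c(1, 0.74, 0.57),
                                s = c(1, 0.23, 0.93)) {
  cells <- expand.grid(harm = 1:4, responsibility = 1:4)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(participant_id = sprintf("P%02d", i),
               harm = cells$harm, responsibility = cells$responsibility,
               guilt = g[1] + g[2] * cells$harm + g[3] * cells$responsibility,
               shame = s[1] + s[2] * cells$harm + s[3] * cells$responsibility)
  }))
}

test_that("pairwise repeated-measures ANOVA reduces to the paired t-test", {
  set.seed(1)
  d <- data.frame(participant_id = rep(sprintf("P%02d", 1:20), 2),
                  level = rep(c("1", "2"), each = 20),
                  rating = c(rnorm(20, 5), rnorm(20, 6)))
  out <- manipulation_check(d)
  tt <- t.test(d$rating[d$level == "1"], d$rating[d$level == "2"],
               paired = TRUE)
  expect_equal(out$F, unname(tt$statistic)^2)
  expect_equal(out$p_value, tt$p.value)
  expect_equal(out$partial_eta_sq, out$F / (out$F + 19))

  # identical ratings across levels
  d$rating <- rep(rnorm(20, 5), 2)
  flat <- manipulation_check(d)
  expect_equal(flat$F, 0)
  expect_equal(flat$partial_eta_sq, 0)
})

test_that("manipulation checks separate adjacent levels on generated data", {
  checks <- generate_manipulation_checks(design_spec(), 42, seed = 5)
  pain <- manipulation_check(checks[checks$measure == "pain", ])
  expect_true(all(pain$p_value < 0.001))
  resp <- manipulation_check(
    checks[checks$measure == "responsibility", ],
    comparisons = list(c("1", "2"), c("2", "3"), c("3", "4"),
                       c("correct", "1"), c("correct", "4"))
  )
  expect_true(all(resp$p_value < 0.001))
  expect_true(all(resp$df2 == 41))

  incomplete <- checks[!(checks$participant_id == "P01" & checks$level == "2"), ]
  expect_error(manipulation_check(incomplete[incomplete$measure == "pain", ]),
               "P01")
})

test_that("emotion regression recovers generating slopes exactly in the noise-free limit", {
  em <- noise_free_emotions()
  reg_h <- emotion_regression(em, "harm")
  expect_equal(reg_h$interaction$estimate, 0.74 - 0.23, tolerance = 1e-8)
  slopes <- setNames(reg_h$simple_slopes$estimate, reg_h$simple_slopes$emotion)
  expect_equal(slopes[["guilt"]], 0.74, tolerance = 1e-8)
  expect_equal(slopes[["shame"]], 0.23, tolerance = 1e-8)

  reg_r <- emotion_regression(em, "responsibility")
  expect_equal(reg_r$interaction$estimate, 0.57 - 0.93, tolerance = 1e-8)

  # swapping the emotion coding flips the interaction sign
  swapped <- em
  names(swapped)[names(swapped) == "guilt"] <- "tmp"
  names(swapped)[names(swapped) == "shame"] <- "guilt"
  names(swapped)[names(swapped) == "tmp"] <- "shame"
  reg_s <- emotion_regression(swapped, "harm")
  expect_equal(reg_s$interaction$estimate, -(0.74 - 0.23), tolerance = 1e-8)

  # three-way model keeps both interactions estimable
  full <- emotion_regression(em, full = TRUE)
  expect_true(all(c("harm:type", "responsibility:type") %in%
                    full$coefficients$term))
})

test_that("emotion-type interaction is detected on generated cohorts", {
  em <- generate_emotions(design_spec(), emotion_gen_spec(), 40, seed = 8)
  reg <- emotion_regression(em$emotions, "harm")
  expect_gt(reg$interaction$estimate, 0)      # harm acts more on guilt
  expect_lt(reg$interaction$p_value, 0.01)
  reg_r <- emotion_regression(em$emotions, "responsibility")
  expect_lt(reg_r$interaction$estimate, 0)    # responsibility more on shame
  expect_lt(reg_r$interaction$p_value, 0.01)
})

test_that("null emotion-slope differences are covered by their confidence intervals", {
  # same generating slopes for guilt and shame: the interaction's 95% CI
  # should cover 0 at roughly the nominal rate
  same <- emotion_gen_spec(
    guilt = c(intercept = 1, slope_H = 0.5, slope_R = 0.5),
    shame = c(intercept = 1, slope_H = 0.5, slope_R = 0.5),
    slope_sd = 0.2, residual_sd = 1
  )
  covered <- logical(60)
  for (i in seq_along(covered)) {
    em <- generate_emotions(design_spec(), same, 20, seed = 300 + i)$emotions
    reg <- emotion_regression(em, "harm")
    half <- qt(0.975, reg$interaction$df) * reg$interaction$se
    covered[i] <- abs(reg$interaction$estimate) <= half
  }
  expect_gte(mean(covered), 0.85)
})

test_that("compensation regression selects the guilt+shame model and compares coefficients", {
  design <- design_spec()
  winners <- character(3)
  for (i in 1:3) {
    sched <- build_schedule(design, 25, seed = 400 + i)
    em <- generate_emotions(design, emotion_gen_spec(), 25, seed = 410 + i)
    trials <- generate_decisions_from_emotions(sched, em$emotions,
                                               seed = 420 + i)
    merged <- merge_emotions(trials, em$emotions)
    winners[i] <- compensation_regression(merged)$winner
  }
  expect_gte(sum(winners == "III"), 2)  # majority of replicate cohorts

  # with a zero shame weight the Wald test separates the coefficients
  sched <- build_schedule(design, 40, seed = 430)
  em <- generate_emotions(design, emotion_gen_spec(), 40, seed = 431)
  trials <- generate_decisions_from_emotions(
    sched, em$emotions,
    weights = c(intercept = 1, guilt = 0.4, shame = 0),
    residual_sd = 0.8, seed = 432)
  merged <- merge_emotions(trials, em$emotions)
  reg <- compensation_regression(merged)
  expect_false(is.null(reg$wald))
  expect_lt(reg$wald$p_value, 0.05)
  expect_gt(reg$wald$difference, 0)
})

test_that("exchangeable guilt and shame columns give a near-zero Wald statistic", {
  design <- design_spec()
  sched <- build_schedule(design, 20, seed = 440)
  em <- generate_emotions(design, emotion_gen_spec(), 20, seed = 441)$emotions
  # make shame a symmetric near-copy of guilt so the two predictors are
  # exchangeable but not aliased
  em$shame <- em$guilt + rep_len(c(0.01, -0.01), nrow(em))
  trials <- generate_decisions_from_emotions(sched, em, seed = 442)
  merged <- merge_emotions(trials, em)
  fits <- compensation_regression(merged)$fits
  wfit <- fits$III
  b <- moralcomp:::fixef_any(wfit)
  V <- moralcomp:::vcov_any(wfit)
  L <- as.numeric(names(b) == "guilt") - as.numeric(names(b) == "shame")
  x2 <- sum(L * b)^2 / drop(t(L) %*% V %*% L)
  expect_lt(x2, qchisq(0.95, 1))
})

test_that("per-participant sensitivities equal common slopes in the noise-free limit", {
  em <- noise_free_emotions(n = 10)
  sched <- build_schedule(design_spec(), 10, seed = 450)
  trials <- generate_decisions_from_emotions(sched, em, residual_sd = 0,
                                             seed = 451)
  sens <- extract_sensitivities(em, trials)
  expect_equal(sens$guilt_harm, rep(0.74, 10), tolerance = 1e-6)
  expect_equal(sens$guilt_resp, rep(0.57, 10), tolerance = 1e-6)
  expect_equal(sens$shame_harm, rep(0.23, 10), tolerance = 1e-6)
  expect_equal(sens$shame_resp, rep(0.93, 10), tolerance = 1e-6)
})

test_that("heterogeneous participant slopes are recovered by the mixed model", {
  gen <- generate_emotions(design_spec(), emotion_gen_spec(), 40, seed = 460)
  sched <- build_schedule(design_spec(), 40, seed = 461)
  trials <- generate_decisions_from_emotions(sched, gen$emotions, seed = 462)
  sens <- extract_sensitivities(gen$emotions, trials)
  m <- match(sens$participant_id, gen$truth$participant_id)
  expect_gte(cor(sens$guilt_harm, gen$truth$guilt_slope_H[m]), 0.8)
  expect_gte(cor(sens$shame_resp, gen$truth$shame_slope_R[m]), 0.8)
})

test_that("model-based sensitivity relates to emotion-driven compensation", {
  # decisions generated through emotions; kappa from the utility model should
  # load positively on the extracted guilt- and shame-driven sensitivities
  design <- design_spec()
  sched <- build_schedule(design, 30, seed = 470)
  em <- generate_emotions(design, emotion_gen_spec(), 30, seed = 471)
  trials <- generate_decisions_from_emotions(sched, em$emotions, seed = 472)
  fits <- fit_cohort(trials, models = "1.3")
  sens <- extract_sensitivities(em$emotions, trials)
  m <- match(fits$participant_id, sens$participant_id)
  co <- coef(lm(fits$kappa ~ sens$comp_guilt[m] + sens$comp_shame[m]))
  expect_gt(co[2], 0)
})

test_that("the dependent-correlation Z statistic has the stated symmetries", {
  eq <- dependent_correlation_test(0.4, 0.4, 0.2, n = 40)
  expect_equal(eq$z, 0)
  expect_equal(eq$p_value, 1)

  a <- dependent_correlation_test(0.5, 0.2, 0.3, n = 40)
  b <- dependent_correlation_test(0.2, 0.5, 0.3, n = 40)
  expect_equal(a$z, -b$z)
  expect_equal(a$p_value, b$p_value)
  expect_gt(a$z, 0)

  expect_error(dependent_correlation_test(1, 0.2, 0.3, n = 40), "degenerate")
  expect_error(dependent_correlation_test(0.5, 0.2, 0.3, n = 3), "at least 4")
})

test_that("bootstrap mediation handles its degenerate and permutation cases", {
  x <- as.numeric(1:20)
  full <- bootstrap_mediation(x, x, x, n_boot = 200, seed = 1)
  expect_equal(full$indirect, full$paths$c_total)
  expect_true(full$significant)

  set.seed(2)
  xx <- rnorm(60)
  m <- 0.8 * xx + rnorm(60, 0, 0.4)
  y <- 0.8 * m + rnorm(60, 0, 0.4)
  med <- bootstrap_mediation(xx, m, y, n_boot = 500, seed = 3)
  expect_true(med$significant)
  expect_gt(med$indirect, 0)

  y_perm <- sample(y)
  med_perm <- bootstrap_mediation(xx, m, y_perm, n_boot = 500, seed = 4)
  expect_false(med_perm$significant)

  expect_error(bootstrap_mediation(rep(1, 20), m[1:20], y[1:20]),
               "zero-variance")
  expect_error(bootstrap_mediation(xx[1:5], m[1:5], y[1:5]), "at least 10")
})

test_that("trait correlations flag constants and recover coupling", {
  comp <- data.frame(participant_id = sprintf("P%02d", 1:42),
                     compensation = runif(42, 2, 8))
  traits <- data.frame(participant_id = comp$participant_id,
                       mirror = comp$compensation,
                       flat = rep(3, 42))
  out <- trait_correlations(traits, comp)
  expect_equal(out$r[out$trait == "mirror"], 1)
  expect_true(is.na(out$r[out$trait == "flat"]))
  expect_equal(out$note[out$trait == "flat"], "constant column")

  set.seed(6)
  coupled <- generate_traits(comp$participant_id, seed = 7,
                             coupled_to = comp$compensation,
                             coupling = c(repair_action = 1.2))
  out2 <- trait_correlations(coupled, comp)
  expect_lt(out2$p_value[out2$trait == "repair_action"], 0.01)
  expect_gt(out2$r[out2$trait == "repair_action"], 0)
})

test_that("independent traits reject at the nominal rate", {
  set.seed(8)
  rej <- replicate(200, {
    comp <- runif(42, 2, 8)
    trait <- rnorm(42)
    cor.test(trait, comp)$p.value < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.045)
})
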