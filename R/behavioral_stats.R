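#' Pairwise repeated-measures ANOVA manipulation checks
#'
#' Compares ratings pairwise across within-participant levels (pain ratings
#' across harm levels, perceived responsibility across responsibility levels
#' and against the correct-estimate condition). Each two-level
#' repeated-measures ANOVA is computed from the paired-differences
#' formulation, for which `F = t^2` with `df = (1, n - 1)` and partial
#' eta-squared `t^2 / (t^2 + n - 1)`.
#'
#' @param data Long data frame with one rating per participant per level.
#' @param id,level,rating Column names.
#' @param comparisons List of length-2 character vectors of level labels;
#'   default: all adjacent pairs in the order the levels appear.
#' @return Data frame with one row per comparison: `level_a`, `level_b`,
#'   `F`, `df1`, `df2`, `p_value`, `partial_eta_sq`, `n`.
#' @export
manipulation_check <- function(data, id = "participant_id", level = "level",
                               rating = "rating", comparisons = NULL) {
  levs <- unique(as.character(data[[level]]))
  if (is.null(comparisons)) {
    comparisons <- Map(c, levs[-length(levs)], levs[-1])
  }
  rows <- lapply(comparisons, function(pair) {
    a <- data[data[[level]] == pair[1], c(id, rating)]
    b <- data[data[[level]] == pair[2], c(id, rating)]
    m <- merge(a, b, by = id, suffixes = c("_a", "_b"))
    bad <- setdiff(unique(data[[id]]), m[[id]])
    assert_that(length(bad) == 0,
                paste("missing cells for participants:",
                      paste(bad, collapse = ", ")))
    d <- m[[paste0(rating, "_a")]] - m[[paste0(rating, "_b")]]
    n <- length(d)
    s <- stats::sd(d)
    if (s == 0) {
      Fv <- if (mean(d) == 0) 0 else Inf
    } else {
      Fv <- (mean(d) / (s / sqrt(n)))^2
    }
    p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
    data.frame(level_a = pair[1], level_b = pair[2], F = Fv,
               df1 = 1, df2 = n - 1, p_value = p,
               partial_eta_sq = if (is.infinite(Fv)) 1 else Fv / (Fv + n - 1),
               n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reshape per-cell emotion ratings to long format
#'
#' @param emotions Wide per-cell ratings (`participant_id`, `harm`,
#'   `responsibility`, `guilt`, `shame`).
#' @return Long data frame with `emotion` (`"guilt"`/`"shame"`) and `rating`;
#'   `type` carries the numeric coding guilt = 1, shame = 0, under which an
#'   emotion-by-predictor interaction coefficient equals the guilt slope
#'   minus the shame slope.
#' @export
emotions_long <- function(emotions) {
  base <- emotions[c("participant_id", "harm", "responsibility")]
  out <- rbind(
    cbind(base, emotion = "guilt", rating = emotions$guilt),
    cbind(base, emotion = "shame", rating = emotions$shame)
  )
  out$type <- as.integer(out$emotion == "guilt")
  rownames(out) <- NULL
  out
}

# Mixed-model fitting with the documented fallback chain: full correlated
# random slopes -> diagonal random slopes -> random intercept only -> plain
# OLS (degenerate data, e.g. the noise-free limit where lmer cannot
# estimate a zero residual variance). All fits use maximum likelihood so BIC
# is comparable across fixed-effect structures.
fit_lmm <- function(fixed, data, slope_terms, id = "participant_id") {
  forms <- c(
    sprintf("%s + (1 + %s | %s)", fixed, paste(slope_terms, collapse = " + "), id),
    sprintf("%s + (1 + %s || %s)", fixed, paste(slope_terms, collapse = " + "), id),
    sprintf("%s + (1 | %s)", fixed, id)
  )
  levels <- c("full", "diagonal", "intercept_only")
  for (i in seq_along(forms)) {
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lmerTest::lmer(stats::as.formula(forms[i]), data = data, REML = FALSE)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      singular <- tryCatch(lme4::isSingular(fit, tol = 1e-5),
                           error = function(e) TRUE)
      converged <- length(fit@optinfo$conv$lme4$messages %||% character()) == 0
      if (i < length(forms) && (singular || !converged)) next
      return(list(fit = fit, formula = forms[i], random = levels[i],
                  engine = "lmer"))
    }
  }
  fit <- stats::lm(stats::as.formula(fixed), data = data)
  list(fit = fit, formula = fixed, random = "none", engine = "lm")
}

coef_table <- function(fitted) {
  if (fitted$engine == "lmer") {
    ct <- stats::coef(summary(fitted$fit))
    data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
               se = ct[, "Std. Error"], df = ct[, "df"],
               statistic = ct[, "t value"], p_value = ct[, "Pr(>|t|)"],
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    ct <- stats::coef(summary(fitted$fit))
    data.frame(term = rownames(ct), estimate = ct[, 1], se = ct[, 2],
               df = stats::df.residual(fitted$fit), statistic = ct[, 3],
               p_value = ct[, 4], row.names = NULL, stringsAsFactors = FALSE)
  }
}

fixef_any <- function(fitted) {
  if (fitted$engine == "lmer") lme4::fixef(fitted$fit) else stats::coef(fitted$fit)
}

vcov_any <- function(fitted) {
  as.matrix(stats::vcov(fitted$fit))
}

# t test (Satterthwaite df under lmer) for a linear combination L'beta.
linear_combo_test <- function(fitted, L) {
  b <- fixef_any(fitted)
  est <- sum(L * b)
  V <- vcov_any(fitted)
  se <- sqrt(drop(t(L) %*% V %*% L))
  if (fitted$engine == "lmer") {
    ct <- tryCatch(lmerTest::contest1D(fitted$fit, L, confint = FALSE),
                   error = function(e) NULL)
    if (!is.null(ct)) {
      return(data.frame(estimate = ct[["Estimate"]], se = ct[["Std. Error"]],
                        df = ct[["df"]], statistic = ct[["t value"]],
                        p_value = ct[["Pr(>|t|)"]]))
    }
    df <- Inf
  } else {
    df <- stats::df.residual(fitted$fit)
  }
  tv <- est / se
  data.frame(estimate = est, se = se, df = df, statistic = tv,
             p_value = 2 * stats::pt(-abs(tv), df))
}

#' Mixed-effects regression of emotion ratings on harm or responsibility
#'
#' Regresses ratings on one predictor (harm or responsibility level, entered
#' as numeric 1-4), emotion type (guilt = 1, shame = 0) and their
#' interaction, with participant-specific random intercepts and random
#' slopes for each fixed effect (falling back to simpler random structures
#' if the full one does not converge). The interaction coefficient estimates
#' the guilt-minus-shame slope difference; simple slopes per emotion type
#' are tested as linear combinations of the fixed effects. Setting
#' `full = TRUE` fits instead the three-way model with harm, responsibility,
#' emotion type and all interactions.
#'
#' @param emotions Long emotion data from [emotions_long()] (or wide
#'   per-cell ratings, reshaped automatically).
#' @param predictor `"harm"` or `"responsibility"`.
#' @param full Fit the three-way model with both predictors.
#' @return A list: `coefficients` (fixed-effect table), `interaction`
#'   (slope-difference test), `simple_slopes` (per emotion type), `random`
#'   (random structure used), `fit`.
#' @export
emotion_regression <- function(emotions, predictor = c("harm", "responsibility"),
                               full = FALSE) {
  predictor <- match.arg(predictor)
  if (!"rating" %in% names(emotions)) emotions <- emotions_long(emotions)
  if (full) {
    fitted <- fit_lmm("rating ~ harm * responsibility * type", emotions,
                      c("harm", "responsibility", "type"))
    return(list(coefficients = coef_table(fitted), random = fitted$random,
                fit = fitted))
  }
  fixed <- sprintf("rating ~ %s * type", predictor)
  fitted <- fit_lmm(fixed, emotions, c(predictor, "type",
                                       paste0(predictor, ":type")))
  terms <- names(fixef_any(fitted))
  int_term <- paste0(predictor, ":type")
  L_int <- as.numeric(terms == int_term)
  L_shame <- as.numeric(terms == predictor)
  L_guilt <- L_shame + L_int
  slopes <- rbind(
    cbind(emotion = "guilt", linear_combo_test(fitted, L_guilt)),
    cbind(emotion = "shame", linear_combo_test(fitted, L_shame))
  )
  list(
    coefficients = coef_table(fitted),
    interaction = linear_combo_test(fitted, L_int),
    simple_slopes = slopes,
    random = fitted$random,
    fit = fitted
  )
}

#' Attach per-cell emotion ratings to experimental trials
#'
#' Broadcasts each participant's per-cell guilt and shame ratings onto the
#' trials of that harm x responsibility cell (ratings are collected once per
#' cell, decisions four times).
#'
#' @param trials Trial data frame.
#' @param emotions Per-cell ratings.
#' @return The self-error trials with `guilt` and `shame` columns added.
#' @export
merge_emotions <- function(trials, emotions) {
  tr <- self_error_trials(trials)
  key <- paste(tr$participant_id, tr$harm, tr$responsibility)
  ekey <- paste(emotions$participant_id, emotions$harm, emotions$responsibility)
  idx <- match(key, ekey)
  assert_that(!anyNA(idx), "missing emotion cells for some trials")
  tr$guilt <- emotions$guilt[idx]
  tr$shame <- emotions$shame[idx]
  tr
}

#' The four-model compensation regression family
#'
#' Fits the four mixed-effects models of compensation (tokens given) used to
#' establish how guilt and shame convert into behaviour — Model I: guilt
#' only; II: shame only; III: guilt + shame; IV: guilt + shame + their
#' interaction — each with participant-specific random intercepts and random
#' slopes for its fixed effects, selects the BIC-minimal model, and compares
#' the guilt and shame coefficients of the guilt + shame model with a 1-df
#' Wald chi-square test on their difference.
#'
#' @param data Self-error trials carrying `decision`, `guilt`, `shame`
#'   (see [merge_emotions()]).
#' @return A list: `bic` (per model), `winner`, `coefficients` (winner's
#'   fixed effects), `wald` (`chisq`, `df`, `p_value`, `difference`) or
#'   `NULL`, `random` structures used, `fits`.
#' @export
compensation_regression <- function(data) {
  specs <- list(
    I = list(fixed = "decision ~ guilt", slopes = "guilt"),
    II = list(fixed = "decision ~ shame", slopes = "shame"),
    III = list(fixed = "decision ~ guilt + shame", slopes = c("guilt", "shame")),
    IV = list(fixed = "decision ~ guilt * shame",
              slopes = c("guilt", "shame", "guilt:shame"))
  )
  fits <- lapply(specs, function(s) fit_lmm(s$fixed, data, s$slopes))
  bic <- vapply(fits, function(f) stats::BIC(f$fit), numeric(1))
  winner <- names(which.min(bic))
  wfit <- fits[[winner]]
  # the guilt-vs-shame coefficient comparison lives in the guilt+shame model
  terms <- names(fixef_any(fits$III))
  wald <- NULL
  if (all(c("guilt", "shame") %in% terms)) {
    L <- as.numeric(terms == "guilt") - as.numeric(terms == "shame")
    b <- fixef_any(fits$III)
    V <- vcov_any(fits$III)
    diff <- sum(L * b)
    x2 <- diff^2 / drop(t(L) %*% V %*% L)
    wald <- list(chisq = x2, df = 1,
                 p_value = stats::pchisq(x2, 1, lower.tail = FALSE),
                 difference = diff)
  }
  list(
    bic = bic, winner = winner,
    coefficients = coef_table(wfit),
    wald = wald,
    random = vapply(fits, function(f) f$random, character(1)),
    fits = fits
  )
}

#' Per-participant emotion and compensatory sensitivities
#'
#' Extracts the six participant-level slopes used as individual-difference
#' measures: harm->guilt, responsibility->guilt, harm->shame,
#' responsibility->shame (from per-emotion mixed models
#' `rating ~ harm + responsibility` with random slopes) and
#' guilt->compensation, shame->compensation (from the guilt + shame
#' compensation model). Each participant's slope is the fixed effect plus
#' their conditional mode (BLUP) of the random slope; when a model falls
#' back to a structure without random slopes, per-participant OLS slopes are
#' substituted and the `method` attribute records it.
#'
#' @param emotions Per-cell ratings.
#' @param trials Trial data frame (merged with emotions internally).
#' @return Data frame with one row per participant: `participant_id`,
#'   `guilt_harm`, `guilt_resp`, `shame_harm`, `shame_resp`, `comp_guilt`,
#'   `comp_shame`; attribute `method` gives `"blup"` or `"ols"` per source
#'   model.
#' @export
extract_sensitivities <- function(emotions, trials) {
  merged <- merge_emotions(trials, emotions)
  pids <- sort(unique(emotions$participant_id))

  slopes_from <- function(fitted, data, fixed_terms, outcome) {
    if (fitted$engine == "lmer" &&
        fitted$random %in% c("full", "diagonal")) {
      fe <- lme4::fixef(fitted$fit)
      re <- lme4::ranef(fitted$fit)$participant_id
      out <- sapply(fixed_terms, function(tm) {
        fe[[tm]] + if (tm %in% colnames(re)) re[pids, tm] else 0
      })
      method <- "blup"
    } else {
      out <- t(vapply(pids, function(p) {
        d <- data[data$participant_id == p, ]
        co <- stats::coef(stats::lm(
          stats::as.formula(paste(outcome, "~", paste(fixed_terms, collapse = "+"))),
          data = d))
        co[fixed_terms]
      }, numeric(length(fixed_terms))))
      method <- "ols"
    }
    list(slopes = matrix(out, nrow = length(pids),
                         dimnames = list(pids, fixed_terms)),
         method = method)
  }

  gfit <- fit_lmm("guilt ~ harm + responsibility", emotions,
                  c("harm", "responsibility"))
  sfit <- fit_lmm("shame ~ harm + responsibility", emotions,
                  c("harm", "responsibility"))
  cfit <- fit_lmm("decision ~ guilt + shame", merged, c("guilt", "shame"))

  g <- slopes_from(gfit, emotions, c("harm", "responsibility"), "guilt")
  s <- slopes_from(sfit, emotions, c("harm", "responsibility"), "shame")
  cc <- slopes_from(cfit, merged, c("guilt", "shame"), "decision")

  out <- data.frame(
    participant_id = pids,
    guilt_harm = g$slopes[, "harm"],
    guilt_resp = g$slopes[, "responsibility"],
    shame_harm = s$slopes[, "harm"],
    shame_resp = s$slopes[, "responsibility"],
    comp_guilt = cc$slopes[, "guilt"],
    comp_shame = cc$slopes[, "shame"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "method") <- c(guilt = g$method, shame = s$method,
                           compensation = cc$method)
  out
}

#' Pearson-Filon Z test for two dependent overlapping correlations
#'
#' Tests whether two correlations sharing one variable, `r_jk` and `r_jh`,
#' differ, given the correlation `r_kh` between the non-shared variables —
#' the classical large-sample statistic of Pearson and Filon. Used to ask,
#' e.g., whether a regional brain response correlates more strongly with one
#' sensitivity than another; here exposed for generic correlation triples.
#'
#' @param r_jk,r_jh The two correlations being compared (sharing variable j).
#' @param r_kh Correlation between the two non-shared variables.
#' @param n Sample size (>= 4).
#' @return A list: `z`, `p_value` (two-sided), `n`.
#' @export
dependent_correlation_test <- function(r_jk, r_jh, r_kh, n) {
  assert_that(n >= 4, "n must be at least 4")
  rs <- c(r_jk, r_jh, r_kh)
  assert_that(all(abs(rs) < 1), "degenerate input: |r| must be < 1")
  k <- r_kh * (1 - r_jk^2 - r_jh^2) -
    0.5 * r_jk * r_jh * (1 - r_jk^2 - r_jh^2 - r_kh^2)
  z <- sqrt(n) * (r_jk - r_jh) /
    sqrt((1 - r_jk^2)^2 + (1 - r_jh^2)^2 - 2 * k)
  list(z = z, p_value = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Percentile-bootstrap mediation analysis
#'
#' Simple mediation for a generic (X, M, Y) triple: path `a` from the
#' regression of M on X, path `b` (and direct effect `c'`) from the
#' regression of Y on M and X, indirect effect `a * b`. Significance is
#' judged by the percentile bootstrap: observations are resampled with
#' replacement `n_boot` times (5000 by default), `a * b` recomputed on each
#' resample, and the effect called significant when the 95% interval
#' excludes zero.
#'
#' @param x,m,y Equal-length numeric vectors (n >= 10).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param conf Confidence level of the percentile interval.
#' @return A list: `paths` (`a`, `b`, `c_total`, `c_prime`), `indirect`,
#'   `ci`, `significant`, `n_boot`.
#' @export
bootstrap_mediation <- function(x, m, y, n_boot = 5000, seed = 1L,
                                conf = 0.95) {
  n <- length(x)
  assert_that(length(m) == n && length(y) == n, "x, m, y must have equal length")
  assert_that(n >= 10, "mediation needs at least 10 observations")
  assert_that(stats::sd(x) > 0 && stats::sd(m) > 0 && stats::sd(y) > 0,
              "zero-variance input")
  paths <- mediation_paths(x, m, y)
  set.seed(seed)
  ab <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    ab[b] <- tryCatch({
      p <- mediation_paths(x[idx], m[idx], y[idx])
      p$a * p$b
    }, error = function(e) NA_real_)
  }
  alpha <- (1 - conf) / 2
  ci <- as.numeric(stats::quantile(ab, c(alpha, 1 - alpha), na.rm = TRUE))
  list(
    paths = paths[c("a", "b", "c_total", "c_prime")],
    indirect = paths$a * paths$b,
    ci = ci,
    significant = ci[1] > 0 || ci[2] < 0,
    n_boot = n_boot
  )
}

# OLS path coefficients, fast enough to sit inside the bootstrap loop. QR
# with pivoting tolerates an aliased direct path (M identical to X): the
# mediator, listed first, absorbs the shared effect and c' is 0.
mediation_paths <- function(x, m, y) {
  vx <- stats::var(x)
  if (vx == 0) stop("zero-variance resample")
  a <- stats::cov(x, m) / vx
  beta <- qr.coef(qr(cbind(1, m, x)), y)
  beta[is.na(beta)] <- 0
  c_total <- stats::cov(x, y) / vx
  list(a = a, b = unname(beta[2]), c_prime = unname(beta[3]),
       c_total = c_total)
}

#' Trait-behaviour Pearson correlations
#'
#' Correlates each trait column with participants' mean compensation.
#'
#' @param traits Data frame with `participant_id` and numeric trait columns.
#' @param compensation Named numeric vector (names = participant ids) or a
#'   data frame with `participant_id` and `compensation`.
#' @return Data frame: `trait`, `r`, `p_value`, `n`, `note` (flags
#'   constant columns, left `NA` otherwise).
#' @export
trait_correlations <- function(traits, compensation) {
  if (is.data.frame(compensation)) {
    comp <- stats::setNames(compensation$compensation,
                            compensation$participant_id)
  } else {
    comp <- compensation
  }
  y <- as.numeric(comp[traits$participant_id])
  assert_that(sum(!is.na(y)) >= 3, "need at least 3 participants")
  cols <- setdiff(names(traits), "participant_id")
  rows <- lapply(cols, function(cl) {
    xv <- traits[[cl]]
    keep <- stats::complete.cases(xv, y)
    if (stats::sd(xv[keep]) == 0 || stats::sd(y[keep]) == 0) {
      return(data.frame(trait = cl, r = NA_real_, p_value = NA_real_,
                        n = sum(keep), note = "constant column",
                        stringsAsFactors = FALSE))
    }
    ct <- stats::cor.test(xv[keep], y[keep])
    data.frame(trait = cl, r = unname(ct$estimate), p_value = ct$p.value,
               n = sum(keep), note = NA_character_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Mean compensation per participant
#'
#' @param trials Trial data frame.
#' @return Data frame `participant_id`, `compensation` (mean tokens over
#'   self-error trials).
#' @export
mean_compensation <- function(trials) {
  tr <- self_error_trials(trials)
  tr <- tr[!is.na(tr$decision), ]
  agg <- tapply(tr$decision, tr$participant_id, mean)
  data.frame(participant_id = names(agg), compensation = as.numeric(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}
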