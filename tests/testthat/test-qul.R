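test_that("choice probabilities follow the logistic of the utility difference", {
  expect_equal(qul_probability(0.7, -0.04, 9, 9), 0.5)
  expect_equal(qul_probability(0, 0, 18, 0), 0.5)
  expect_equal(qul_probability(0.4, -0.02, 10, 0), plogis(2))
  # complementarity
  p1 <- qul_probability(0.3, -0.05, 12, 4)
  p2 <- qul_probability(0.3, -0.05, 4, 12)
  expect_equal(p1 + p2, 1)
  expect_error(qul_probability(Inf, 0, 1, 2), class = "prefnr_invalid_input")
})

test_that("preferred strength from coefficients is clamped and total", {
  expect_equal(g_opt_from_coefficients(0.4, -0.02)$g_opt, 10)
  expect_false(g_opt_from_coefficients(0.4, -0.02)$at_boundary)
  res <- g_opt_from_coefficients(0.88, -0.02)
  expect_equal(res$g_opt, 18)
  expect_true(res$at_boundary)
  res0 <- g_opt_from_coefficients(0, -0.05)
  expect_equal(res0$g_opt, 0)
  expect_true(res0$at_boundary)
  # convex-utility tie: midpoint, degenerate
  tie <- g_opt_from_coefficients(0, 0)
  expect_equal(tie$g_opt, 9)
  expect_true(tie$degenerate)
  expect_false(tie$at_boundary)
  # clamp totality fuzz, including convex and linear utilities
  withr::with_seed(5, {
    a <- stats::runif(500, -5, 5)
    b <- stats::runif(500, -1, 1)
    g <- g_opt_from_coefficients(a, b)$g_opt
    expect_true(all(g >= 0 & g <= 18))
  })
})

test_that("coin-flip responses give a flat fitted preference", {
  des <- enumerate_design()
  tr <- withr::with_seed(21, dplyr::mutate(
    des, choice = sample(c("first", "second"), dplyr::n(), replace = TRUE)))
  fit <- fit_qul(tr)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$a), 2 * se[1])
  expect_lt(abs(fit$b), 2 * se[2])
  expect_false(fit$separated)
})

test_that("the MLE recovers planted coefficients and matches a grid search", {
  tr <- simulate_responses(enumerate_design(), a = 0.48, b = -0.03, seed = 42)
  fit <- fit_qul(tr)
  expect_lt(abs(fit$g_opt - 8), 1.5)
  oracle <- grid_mle(tr, a_range = fit$a + c(-0.05, 0.05),
                     b_range = fit$b + c(-0.02, 0.02), step = 0.005)
  expect_lte(abs(fit$a - oracle$a), oracle$step)
  expect_lte(abs(fit$b - oracle$b), oracle$step)
})

test_that("perfect monotone preference is flagged as separation", {
  des <- enumerate_design()
  higher <- dplyr::mutate(des, choice = ifelse(first_db > second_db,
                                               "first", "second"))
  fit <- fit_qul(higher)
  expect_true(fit$separated)
  expect_equal(fit$g_opt, 18)
  expect_true(fit$at_boundary)
})

test_that("a single comparison pair cannot identify the model", {
  one_pair <- tibble::tibble(first_db = c(0, 18, 0, 18),
                             second_db = c(18, 0, 18, 0),
                             choice = c("first", "second", "first", "first"))
  expect_error(fit_qul(one_pair), class = "prefnr_insufficient_design")
})

test_that("the log-likelihood carries no intercept in the difference model", {
  tr <- simulate_responses(enumerate_design(), a = 0.4, b = -0.025, seed = 9)
  fit <- fit_qul(tr)
  # adding a constant to u(g) leaves every utility difference unchanged
  expect_equal(qul_nll(fit$a, fit$b, tr),
               -fit$log_lik, tolerance = 1e-8)
  expect_equal(rownames(fit$vcov), c("a", "b"))
})

fake_fit <- function(a, b, vcov = diag(2) * 1e-4) {
  dimnames(vcov) <- list(c("a", "b"), c("a", "b"))
  structure(list(a = a, b = b, vcov = vcov, g_opt = NA, separated = FALSE,
                 converged = TRUE, clamp = c(0, 18)), class = "qul_fit")
}

test_that("a flat model predicts 0.5 everywhere with symmetric SEs", {
  curve <- preference_curve(fake_fit(0, 0))
  expect_equal(curve$expected_win_fraction, rep(0.5, 10))
  expect_true(all(curve$se > 0))
  # on a grid symmetric about its midpoint, with the covariance implied by the
  # flat model's own information matrix, mirror levels share their SE
  lv <- c(0, 6, 9, 12, 18)
  des <- enumerate_design(lv, 2)
  X <- cbind(des$first_db - des$second_db, des$first_db^2 - des$second_db^2)
  sym <- preference_curve(fake_fit(0, 0, vcov = solve(0.25 * crossprod(X))),
                          levels = lv)
  expect_equal(sym$se[sym$level_db == 0], sym$se[sym$level_db == 18])
  expect_equal(sym$se[sym$level_db == 6], sym$se[sym$level_db == 12])
})

test_that("levels utility-symmetric about the vertex have equal expected wins", {
  # vertex at 9 dB: u(8) = u(10), u(4) = u(14) etc.; on the grid 8 vs 10
  curve <- preference_curve(fake_fit(0.9, -0.05))
  f <- function(l) curve$expected_win_fraction[curve$level_db == l]
  expect_equal(f(8), f(10), tolerance = 1e-12)
})

test_that("the model curve matches Monte-Carlo win fractions", {
  tr <- simulate_responses(enumerate_design(), a = 0.48, b = -0.03, seed = 42)
  fit <- fit_qul(tr)
  curve <- preference_curve(fit)
  levels <- study_levels()
  n_mc <- 1e5
  withr::with_seed(77, {
    for (g in c(0, 8, 18)) {
      opp <- levels[levels != g]
      p <- qul_probability(fit$a, fit$b, g, opp)
      draws <- stats::rbinom(length(opp), n_mc, p) / n_mc
      mc_est <- mean(draws)
      mc_se <- sqrt(sum(p * (1 - p) / n_mc)) / length(opp)
      expect_lt(abs(curve$expected_win_fraction[curve$level_db == g] - mc_est),
                3 * mc_se + 1e-12)
    }
  })
})

test_that("curves are unimodal for concave utilities", {
  withr::with_seed(13, {
    for (i in 1:20) {
      b <- stats::runif(1, -0.06, -0.01)
      g0 <- stats::runif(1, 0, 18)
      curve <- preference_curve(fake_fit(-2 * b * g0, b))
      v <- curve$expected_win_fraction
      peak <- which.max(v)
      expect_true(all(diff(v[seq_len(peak)]) >= -1e-12))
      expect_true(all(diff(v[peak:length(v)]) <= 1e-12))
    }
  })
})

test_that("cohort fitting returns one labelled row per participant", {
  cohort <- generate_cohort(cohort_spec(sizes = c("NH" = 3, "HI-mild" = 0,
                                                  "HI-moderate" = 2)), seed = 4)
  fits <- fit_qul_cohort(cohort$trials)
  expect_equal(nrow(fits), 5)
  expect_true(all(c("a", "b", "se_a", "se_b", "g_opt", "separated",
                    "converged") %in% names(fits)))
  expect_true(all(fits$g_opt >= 0 & fits$g_opt <= 18))
})

test_that("tidy and glance summarise a fit", {
  tr <- simulate_responses(enumerate_design(), a = 0.5, b = -0.03, seed = 2)
  fit <- fit_qul(tr)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "b"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})
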