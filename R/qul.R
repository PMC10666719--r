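#' Choice probability under the quadratic-utility logistic (QUL) model
#'
#' The model assumes each listener trades off residual noise against the
#' speech distortion that stronger noise reduction introduces, summarised by
#' a quadratic utility of the strength g (in dB): u(g) = a*g + b*g^2. The
#' probability of choosing the first of two successive stimuli is the
#' logistic function of the utility difference,
#' P(first) = plogis(u(g_first) - u(g_second)). Any constant term in u
#' cancels in the difference, so the model carries no intercept.
#'
#' @param a Linear utility coefficient (per dB).
#' @param b Quadratic utility coefficient (per dB^2); negative for a
#'   single-peaked preference with optimum -a/(2b).
#' @param g_first,g_second Strengths of the two stimuli, dB. Vectorised.
#' @return Probability of choosing the first stimulus, in (0, 1).
#' @export
#' @examples
#' qul_probability(0.4, -0.02, 10, 0)  # plogis(2) = 0.8808
qul_probability <- function(a, b, g_first, g_second) {
  if (!all(is.finite(a), is.finite(b), is.finite(g_first), is.finite(g_second))) {
    abort("All QUL inputs must be finite.", class = "prefnr_invalid_input")
  }
  du <- a * (g_first - g_second) + b * (g_first^2 - g_second^2)
  plogis(du)
}

#' Preferred strength implied by QUL coefficients
#'
#' Maps fitted coefficients to the preferred strength, clamped to the tested
#' range so the estimate never extrapolates beyond the stimuli actually
#' heard. With concave utility (b < 0) the optimum is -a/(2b) clipped to the
#' clamp interval; with linear or convex utility (b >= 0) preference is
#' maximal at the endpoint with the larger utility. Equal endpoint utilities
#' carry no preference information, so the midpoint is returned with
#' `degenerate = TRUE`.
#'
#' @inheritParams qul_probability
#' @param clamp Length-2 interval of admissible strengths, dB.
#'   Default `c(0, 18)`, the study range.
#' @return Tibble with `g_opt`, `at_boundary`, `degenerate` (vectorised over
#'   `a`, `b`).
#' @export
#' @examples
#' g_opt_from_coefficients(0.4, -0.02)   # interior optimum at 10 dB
#' g_opt_from_coefficients(0.88, -0.02)  # unconstrained 22 dB, clamped to 18
g_opt_from_coefficients <- function(a, b, clamp = c(0, 18)) {
  if (!all(is.finite(a), is.finite(b))) {
    abort("Coefficients must be finite.", class = "prefnr_invalid_input")
  }
  if (length(clamp) != 2 || !all(is.finite(clamp)) || clamp[1] >= clamp[2]) {
    abort("`clamp` must be a non-empty interval c(lo, hi).",
          class = "prefnr_invalid_input")
  }
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  lo <- clamp[1]; hi <- clamp[2]
  u <- function(g) a * g + b * g^2
  g_opt <- numeric(n)
  degenerate <- logical(n)
  concave <- b < 0
  g_opt[concave] <- pmin(pmax(-a[concave] / (2 * b[concave]), lo), hi)
  if (any(!concave)) {
    ulo <- u(lo)[!concave]; uhi <- u(hi)[!concave]
    pick <- ifelse(uhi > ulo, hi, ifelse(uhi < ulo, lo, (lo + hi) / 2))
    g_opt[!concave] <- pick
    degenerate[!concave] <- uhi == ulo
  }
  tibble(
    g_opt = g_opt,
    at_boundary = !degenerate & (g_opt == lo | g_opt == hi),
    degenerate = degenerate
  )
}

#' Fit the QUL preference model to one participant's paired comparisons
#'
#' Maximises the Bernoulli log-likelihood of the observed choices under the
#' QUL choice probability. Because the utility difference is linear in
#' (a, b) with covariates (Dg, Dg^2), the maximum-likelihood fit is an
#' intercept-free binomial logistic regression, estimated by iteratively
#' reweighted least squares; the coefficient covariance comes from the
#' inverse observed information at the optimum. A response pattern the model
#' predicts perfectly (e.g. a listener who always prefers the stronger
#' stimulus) has no finite maximiser — this separation is detected and
#' flagged, and the preferred strength is reported at the favoured endpoint
#' with the covariance marked unreliable.
#'
#' @param trials Tibble with `first_db`, `second_db`, `choice` for one
#'   participant.
#' @param clamp Admissible strength interval, dB (default `c(0, 18)`).
#' @param order_effect If `TRUE`, adds a presentation-order bias term
#'   (an intercept in the utility-difference predictor). Default `FALSE`:
#'   the balanced AB/BA design cancels order effects by construction.
#' @param max_iter Iteration budget for the fitting algorithm.
#' @return An object of class `qul_fit`: coefficients `a`, `b` (and `delta`
#'   when `order_effect`), their covariance, `g_opt`, `at_boundary`,
#'   `degenerate`, `separated`, `converged`, `log_lik` and bookkeeping
#'   fields. Methods: [tidy()], [glance()], [autoplot()], `print()`.
#' @export
#' @examples
#' trials <- simulate_responses(enumerate_design(), a = 0.48, b = -0.03, seed = 7)
#' fit <- fit_qul(trials)
#' glance(fit)
fit_qul <- function(trials, clamp = c(0, 18), order_effect = FALSE,
                    max_iter = 100) {
  validate_trials(trials)
  lv <- unique(c(trials$first_db, trials$second_db))
  if (any(lv < clamp[1]) || any(lv > clamp[2])) {
    abort("Trial levels fall outside the clamp interval.",
          class = "prefnr_invalid_input")
  }
  pair_key <- paste(pmin(trials$first_db, trials$second_db),
                    pmax(trials$first_db, trials$second_db))
  if (length(unique(pair_key)) < 2) {
    abort("At least two distinct level pairs are needed to identify (a, b).",
          class = "prefnr_insufficient_design")
  }
  y <- as.integer(trials$choice == "first")
  x1 <- trials$first_db - trials$second_db
  x2 <- trials$first_db^2 - trials$second_db^2
  dat <- data.frame(y = y, x1 = x1, x2 = x2)
  fml <- if (order_effect) y ~ x1 + x2 else y ~ 0 + x1 + x2
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(),
               data = dat, control = stats::glm.control(maxit = max_iter))
  )
  cf <- stats::coef(fit)
  a <- unname(cf[["x1"]]); b <- unname(cf[["x2"]])
  delta <- if (order_effect) unname(cf[["(Intercept)"]]) else NULL
  p_hat <- stats::fitted(fit)
  # perfect separation: every observed choice assigned probability ~ 1
  separated <- all(ifelse(y == 1, p_hat, 1 - p_hat) > 1 - 1e-6)
  vc <- stats::vcov(fit)[c("x1", "x2"), c("x1", "x2"), drop = FALSE]
  dimnames(vc) <- list(c("a", "b"), c("a", "b"))
  opt <- g_opt_from_coefficients(a, b, clamp)
  structure(list(
    a = a, b = b, delta = delta,
    vcov = vc,
    g_opt = opt$g_opt,
    at_boundary = opt$at_boundary,
    degenerate = opt$degenerate,
    separated = separated,
    converged = fit$converged && !separated,
    log_lik = as.numeric(stats::logLik(fit)),
    clamp = clamp,
    order_effect = order_effect,
    n_trials = nrow(trials),
    levels = sort(lv)
  ), class = "qul_fit")
}

#' @export
print.qul_fit <- function(x, ...) {
  cat("QUL preference fit (", x$n_trials, " trials)\n", sep = "")
  cat(sprintf("  a = %.4f (SE %.4f), b = %.5f (SE %.5f)\n",
              x$a, sqrt(x$vcov[1, 1]), x$b, sqrt(x$vcov[2, 2])))
  cat(sprintf("  preferred strength g_opt = %.2f dB%s%s%s\n", x$g_opt,
              if (x$at_boundary) " [boundary]" else "",
              if (x$separated) " [separated]" else "",
              if (x$degenerate) " [degenerate]" else ""))
  cat(sprintf("  log-likelihood %.2f, converged: %s\n", x$log_lik, x$converged))
  invisible(x)
}

#' @export
tidy.qul_fit <- function(x, ...) {
  est <- c(a = x$a, b = x$b)
  se <- sqrt(diag(x$vcov))
  out <- tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se)))
  )
  if (x$separated) out$std.error <- NA_real_
  out
}

#' @export
glance.qul_fit <- function(x, ...) {
  tibble(
    g_opt = x$g_opt, at_boundary = x$at_boundary, degenerate = x$degenerate,
    separated = x$separated, converged = x$converged,
    log_lik = x$log_lik, n_trials = x$n_trials
  )
}

#' Fit the QUL model to every participant in a trial table
#'
#' @param trials Tibble with `participant_id`, `first_db`, `second_db`,
#'   `choice`.
#' @inheritParams fit_qul
#' @return One row per participant: coefficients with standard errors,
#'   `g_opt` and diagnostic flags — the response feature table the group
#'   statistics operate on.
#' @export
fit_qul_cohort <- function(trials, clamp = c(0, 18), order_effect = FALSE) {
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_qul(d, clamp = clamp, order_effect = order_effect)
      se <- sqrt(diag(f$vcov))
      tibble(a = f$a, b = f$b, se_a = se[1], se_b = se[2],
             g_opt = f$g_opt, at_boundary = f$at_boundary,
             degenerate = f$degenerate, separated = f$separated,
             converged = f$converged, log_lik = f$log_lik,
             n_trials = f$n_trials)
    }) |>
    dplyr::ungroup()
}

#' Model-implied preference curve with pointwise standard errors
#'
#' The expected win fraction at a level g is the mean, over all other design
#' levels g', of the QUL probability of choosing g over g' — the model-side
#' counterpart of the empirical win fraction, so the two can be overlaid.
#' Pointwise standard errors come from the delta method applied to the
#' coefficient covariance; for a separated fit they are computed but flagged
#' unreliable.
#'
#' @param fit A [fit_qul()] object.
#' @param levels Design grid, default [study_levels()].
#' @return Tibble with `level_db`, `expected_win_fraction`, `se`,
#'   `se_unreliable`.
#' @export
preference_curve <- function(fit, levels = study_levels()) {
  stopifnot(inherits(fit, "qul_fit"))
  levels <- validate_levels(levels)
  a <- fit$a; b <- fit$b
  rows <- purrr::map(levels, function(g) {
    opp <- levels[levels != g]
    p <- qul_probability(a, b, g, opp)
    # delta-method gradient of mean(p) wrt (a, b)
    w <- p * (1 - p)
    grad <- c(mean(w * (g - opp)), mean(w * (g^2 - opp^2)))
    se <- sqrt(drop(t(grad) %*% fit$vcov %*% grad))
    tibble(level_db = g, expected_win_fraction = mean(p), se = se)
  })
  out <- dplyr::bind_rows(rows)
  out$se_unreliable <- fit$separated
  out
}

#' Simulate forced-choice responses from a QUL listener
#'
#' Each trial template is answered by an independent Bernoulli draw with
#' success probability [qul_probability()] of choosing the first stimulus.
#'
#' @param design Tibble of trial templates from [enumerate_design()] (columns
#'   `first_db`, `second_db`, `repetition`).
#' @inheritParams qul_probability
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @param participant_id Optional id column value to attach.
#' @return The design tibble with a `choice` column (and `participant_id`
#'   when supplied).
#' @export
simulate_responses <- function(design, a, b, seed = NULL,
                               participant_id = NULL) {
  p <- qul_probability(a, b, design$first_db, design$second_db)
  draw <- function() stats::runif(nrow(design)) < p
  first <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out <- design
  out$choice <- ifelse(first, "first", "second")
  if (!is.null(participant_id)) {
    out <- dplyr::mutate(out, participant_id = participant_id,
                         .before = 1)
  }
  out
}

#' Plot a QUL fit against empirical win fractions
#'
#' Reproduces the per-participant panel style of the study: brown empirical
#' win fractions on the design grid, blue model curve with pointwise
#' standard-error bars.
#'
#' @param object A [fit_qul()] object.
#' @param trials Optional trials tibble to overlay the empirical profile.
#' @param levels Design grid for the curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qul_fit <- function(object, trials = NULL, levels = study_levels(),
                             ...) {
  curve <- preference_curve(object, levels)
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$level_db)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected_win_fraction),
                       colour = "steelblue4") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$expected_win_fraction - .data$se,
                   ymax = .data$expected_win_fraction + .data$se),
      width = 0.4, colour = "steelblue4") +
    ggplot2::labs(
      x = "Maximum gain reduction (dB)",
      y = "Win fraction",
      subtitle = sprintf("g_opt = %.1f dB%s", object$g_opt,
                         if (object$separated) " (separated)" else "")
    ) +
    ggplot2::coord_cartesian(ylim = c(0, 1))
  if (!is.null(trials)) {
    prof <- win_profile(trials, levels)
    p <- p +
      ggplot2::geom_point(data = prof,
                          ggplot2::aes(y = .data$win_fraction),
                          colour = "sienna") +
      ggplot2::geom_line(data = prof,
                         ggplot2::aes(y = .data$win_fraction),
                         colour = "sienna", linetype = 2)
  }
  p
}
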