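#' One-sample Kolmogorov-Smirnov test against a normal distribution
#'
#' Compares the empirical CDF with a normal CDF. By default the reference
#' mean and SD are estimated from the sample itself, mirroring common
#' practice with the "standard" KS test; note the resulting p-value is then
#' anti-conservative, and `lilliefors = TRUE` switches to the Lilliefors
#' test, which corrects for the estimated parameters.
#'
#' @param data A data frame, or a numeric vector.
#' @param value Column holding the values (ignored when `data` is a vector).
#' @param mean,sd Reference normal parameters; default: sample estimates.
#' @param lilliefors Use the Lilliefors correction (requires \pkg{nortest}).
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`, `n`.
#' @export
#' @examples
#' ks_normal_test(c(0, 1), mean = 0, sd = 1)  # D = 0.5
ks_normal_test <- function(data, value, mean = NULL, sd = NULL,
                           lilliefors = FALSE) {
  values <- if (is.numeric(data)) data else dplyr::pull(data, {{ value }})
  values <- values[is.finite(values)]
  if (length(values) < 2) {
    abort("Need at least 2 finite values.", class = "prefnr_degenerate_sample")
  }
  if (stats::sd(values) == 0) {
    abort("Sample has zero variance; the KS normality test is undefined.",
          class = "prefnr_degenerate_sample")
  }
  if (lilliefors) {
    rlang::check_installed("nortest")
    res <- nortest::lillie.test(values)
    return(tibble(method = "Lilliefors (KS, estimated parameters)",
                  statistic = unname(res$statistic), df = NA_real_,
                  p_value = unname(res$p.value), n = length(values)))
  }
  m <- mean %||% base::mean(values)
  s <- sd %||% stats::sd(values)
  res <- suppressWarnings(stats::ks.test(values, "pnorm", m, s))
  tibble(method = "One-sample Kolmogorov-Smirnov vs normal",
         statistic = unname(res$statistic), df = NA_real_,
         p_value = unname(res$p.value), n = length(values))
}

pull_groups <- function(data, value, group) {
  if (is.list(data) && !is.data.frame(data)) {
    groups <- data
    if (is.null(names(groups))) names(groups) <- seq_along(groups)
  } else {
    v <- dplyr::pull(data, {{ value }})
    g <- dplyr::pull(data, {{ group }})
    groups <- split(v, g)
  }
  purrr::map(groups, ~ .x[is.finite(.x)])
}

#' Bartlett's test for equal group variances
#'
#' Homoscedasticity check run before the rank-based group comparison.
#'
#' @param data A data frame, or a plain list of numeric vectors.
#' @param value,group Columns holding values and group labels (data-frame
#'   interface).
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`, `n`.
#' @export
bartlett_test <- function(data, value, group) {
  groups <- pull_groups(data, {{ value }}, {{ group }})
  if (length(groups) < 2) {
    abort("Need at least 2 groups.", class = "prefnr_invalid_input")
  }
  if (any(vapply(groups, length, integer(1)) < 2)) {
    abort("Every group needs n >= 2.", class = "prefnr_invalid_input")
  }
  if (any(vapply(groups, stats::var, numeric(1)) == 0)) {
    abort("A group has zero variance; Bartlett's test is undefined.",
          class = "prefnr_degenerate_sample")
  }
  res <- stats::bartlett.test(groups)
  tibble(method = "Bartlett's test for equal variances",
         statistic = unname(res$statistic),
         df = unname(res$parameter),
         p_value = unname(res$p.value),
         n = sum(lengths(groups)))
}

#' Kruskal-Wallis rank test across groups
#'
#' Nonparametric one-way comparison of the preferred-strength response
#' feature across hearing-loss groups, with the mid-rank ties correction.
#' A sample in which every pooled value is identical carries no rank
#' information and returns H = 0, p = 1.
#'
#' @inheritParams bartlett_test
#' @return One-row tibble: `method`, `statistic` (H), `df`, `p_value`, `n`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4)))  # H = 2.4
kruskal_wallis <- function(data, value, group) {
  groups <- pull_groups(data, {{ value }}, {{ group }})
  if (length(groups) < 2) {
    abort("Need at least 2 groups.", class = "prefnr_invalid_input")
  }
  if (any(lengths(groups) == 0)) {
    abort("Every group needs at least one observation.",
          class = "prefnr_invalid_input")
  }
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    return(tibble(method = "Kruskal-Wallis rank sum test",
                  statistic = 0, df = length(groups) - 1,
                  p_value = 1, n = length(pooled)))
  }
  res <- stats::kruskal.test(groups)
  tibble(method = "Kruskal-Wallis rank sum test",
         statistic = unname(res$statistic),
         df = unname(res$parameter),
         p_value = unname(res$p.value),
         n = length(pooled))
}

#' Dunn's post hoc z-tests on mean ranks, Bonferroni corrected
#'
#' Pairwise follow-up to a significant Kruskal-Wallis test: z-statistics on
#' pooled mean ranks with the ties-corrected rank variance, two-sided
#' p-values multiplied by the number of comparisons `m` and capped at 1.
#'
#' @inheritParams bartlett_test
#' @param alpha Significance level for the `significant` flag.
#' @param m Number of comparisons in the Bonferroni correction; default: the
#'   number of group pairs. Must be at least that number.
#' @return Tibble with one row per group pair: `group1`, `group2`, `z`,
#'   `p_raw`, `p_adjusted`, `significant`.
#' @export
#' @examples
#' dunn_bonferroni(list(a = c(1, 2, 3), b = c(11, 12, 13), c = c(21, 22, 23)))
dunn_bonferroni <- function(data, value, group, alpha = 0.05, m = NULL) {
  groups <- pull_groups(data, {{ value }}, {{ group }})
  k <- length(groups)
  if (k < 2) abort("Need at least 2 groups.", class = "prefnr_invalid_input")
  pairs <- utils::combn(k, 2)
  if (is.null(m)) m <- ncol(pairs)
  if (m < ncol(pairs)) {
    abort("`m` must be at least the number of pairwise comparisons.",
          class = "prefnr_invalid_input")
  }
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  mean_ranks <- tapply(r, idx, mean)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  sigma2 <- N * (N + 1) / 12 - tie_term
  nm <- names(groups)
  out <- purrr::map(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    n1 <- lengths(groups)[i1]; n2 <- lengths(groups)[i2]
    z <- (mean_ranks[i1] - mean_ranks[i2]) / sqrt(sigma2 * (1 / n1 + 1 / n2))
    p <- 2 * pnorm(-abs(z))
    tibble(group1 = nm[i1], group2 = nm[i2], z = unname(z),
           p_raw = unname(p), p_adjusted = min(1, unname(p) * m))
  })
  out <- dplyr::bind_rows(out)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Spearman rank correlation
#'
#' Pairs with a missing member are dropped (the study had no speech
#' reception threshold for five normal-hearing participants). The p-value
#' uses the exact permutation distribution for n <= 9 and the
#' t-approximation otherwise.
#'
#' @param data A data frame (or `x` may be a numeric vector with `y` the
#'   paired vector).
#' @param x,y Columns (or vectors) to correlate.
#' @return One-row tibble: `method`, `estimate` (rho), `statistic`,
#'   `p_value`, `n`.
#' @export
#' @examples
#' spearman_correlation(tibble::tibble(x = 1:4, y = c(2, 1, 4, 3)), x, y)
spearman_correlation <- function(data, x, y) {
  if (is.numeric(data)) {
    xv <- data; yv <- x
  } else {
    xv <- dplyr::pull(data, {{ x }})
    yv <- dplyr::pull(data, {{ y }})
  }
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 4) {
    abort("Need at least 4 complete pairs.", class = "prefnr_invalid_input")
  }
  res <- suppressWarnings(
    stats::cor.test(xv, yv, method = "spearman", exact = n <= 9)
  )
  tibble(method = "Spearman rank correlation",
         estimate = unname(res$estimate),
         statistic = unname(res$statistic),
         p_value = unname(res$p.value),
         n = n)
}

#' Per-group sample size for a two-sample comparison
#'
#' Normal-approximation sample size for detecting a mean difference `delta`
#' between two independent groups with common SD `sigma`:
#' n = 2 sigma^2 (z_{1-alpha/2} + z_{power})^2 / delta^2, rounded to the
#' nearest integer. With sigma = 1.8 dB, delta = 2.5 dB, alpha = 0.05 and
#' power 0.80 this gives 8 listeners per group. `method = "exact-t"` uses
#' the noncentral-t calculation instead (never smaller).
#'
#' @param sigma Within-group standard deviation, dB.
#' @param delta Detectable mean difference, dB.
#' @param alpha Two-sided type-I level.
#' @param power Target power.
#' @param method `"normal"` (default) or `"exact-t"`.
#' @return Integer sample size per group (>= 1).
#' @export
#' @examples
#' power_sample_size(sigma = 1.8, delta = 2.5)  # 8
power_sample_size <- function(sigma, delta, alpha = 0.05, power = 0.8,
                              method = c("normal", "exact-t")) {
  method <- match.arg(method)
  if (!(sigma > 0 && delta > 0 && alpha > 0 && alpha < 1 &&
        power > 0 && power < 1)) {
    abort("Require sigma > 0, delta > 0, alpha and power in (0, 1).",
          class = "prefnr_invalid_input")
  }
  if (method == "normal") {
    n <- 2 * sigma^2 * (qnorm(1 - alpha / 2) + qnorm(power))^2 / delta^2
    max(1L, as.integer(round(n)))
  } else {
    n <- stats::power.t.test(delta = delta, sd = sigma, sig.level = alpha,
                             power = power, type = "two.sample")$n
    max(1L, as.integer(ceiling(n)))
  }
}

#' Full response-feature group analysis
#'
#' Runs the analysis sequence on a per-participant response-feature table:
#' Bartlett homoscedasticity check on the preferred strengths by group, KS
#' normality check on the group-mean-centred residuals, Kruskal-Wallis
#' across groups with Dunn-Bonferroni post hoc, and Spearman correlations of
#' the preferred strength with better-ear PTA, SRT and age, plus PTA with
#' age.
#'
#' @param fits Output of [fit_qul_cohort()] (needs `participant_id`,
#'   `g_opt`).
#' @param meta Participant metadata with `participant_id`, `group`,
#'   `pta_better_db_hl`, `age_years`, `srt_db`.
#' @param alpha Significance level for post hoc flags.
#' @return Named list: `bartlett`, `ks_residuals`, `kruskal`, `dunn`
#'   (tibbles), `correlations` (tibble with one row per variable pair),
#'   `medians` (per-group median preferred strength).
#' @export
group_stats_report <- function(fits, meta, alpha = 0.05) {
  d <- dplyr::inner_join(fits, meta, by = "participant_id")
  resid <- d$g_opt - stats::ave(d$g_opt, d$group)
  corr_pair <- function(label, x, y) {
    res <- spearman_correlation(x, y)
    dplyr::mutate(res, pair = label, .before = 1)
  }
  correlations <- dplyr::bind_rows(
    corr_pair("g_opt ~ pta_better", d$g_opt, d$pta_better_db_hl),
    corr_pair("g_opt ~ srt", d$g_opt, d$srt_db),
    corr_pair("g_opt ~ age", d$g_opt, d$age_years),
    corr_pair("pta_better ~ age", d$pta_better_db_hl, d$age_years)
  )
  list(
    bartlett = bartlett_test(d, .data$g_opt, .data$group),
    ks_residuals = ks_normal_test(resid),
    kruskal = kruskal_wallis(d, .data$g_opt, .data$group),
    dunn = dunn_bonferroni(d, .data$g_opt, .data$group, alpha = alpha),
    correlations = correlations,
    medians = d |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(median_g_opt = stats::median(.data$g_opt),
                       n = dplyr::n(), .groups = "drop")
  )
}
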