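rtrunc_norm <- function(n, mu, sd, lo, hi) {
  u <- stats::runif(n, pnorm(lo, mu, sd), pnorm(hi, mu, sd))
  qnorm(u, mu, sd)
}

#' Specification of a synthetic paired-comparison cohort
#'
#' Defines the generative model mirrored on the study design: three
#' hearing-status groups of 10 listeners whose preferred strengths are drawn
#' from truncated normals on the tested range with group medians 8.2, 11.6
#' and 15.7 dB; utility curvature b uniform on \[-0.06, -0.01\] (spanning the
#' flat to sharply peaked preference profiles seen empirically); better-ear
#' PTA uniform within each group's defining range (NH <= 20 dB HL, HI-mild
#' 20-40, HI-moderate > 40); age and SRT affine in PTA plus noise so the
#' usual positive hearing-loss/age and hearing-loss/SRT associations emerge.
#' The default within-group spread of the preferred strength is 3.8 dB,
#' between the 3.6 and 4.0 dB spreads reported for comparable listening
#' experiments.
#'
#' @param sizes Named group sizes (NH, HI-mild, HI-moderate).
#' @param g_opt_median Per-group median preferred strength, dB.
#' @param g_opt_sd Within-group SD of preferred strength, dB (scalar or
#'   per group).
#' @param b_range Range of the (negative) quadratic utility coefficient.
#' @param pta_range 2-column matrix-like list of per-group PTA bounds,
#'   dB HL.
#' @param levels,repetitions The paired-comparison design.
#' @param age_model,srt_model Lists `list(intercept, slope, sd)` for the
#'   affine-in-PTA covariate models (years and dB respectively).
#' @param n_missing_srt Number of NH participants without an SRT
#'   measurement (the study lacked it for its first five).
#' @return A `cohort_spec` list, validated.
#' @export
cohort_spec <- function(sizes = c("NH" = 10, "HI-mild" = 10, "HI-moderate" = 10),
                        g_opt_median = c(8.2, 11.6, 15.7),
                        g_opt_sd = 3.8,
                        b_range = c(-0.06, -0.01),
                        pta_range = list(c(0, 20), c(21, 40), c(41, 70)),
                        levels = study_levels(),
                        repetitions = 2,
                        age_model = list(intercept = 40, slope = 0.5, sd = 9),
                        srt_model = list(intercept = 20, slope = 0.6, sd = 6),
                        n_missing_srt = 5) {
  if (any(sizes < 0)) {
    abort("Group sizes must be >= 0.", class = "prefnr_invalid_spec")
  }
  if (any(b_range >= 0) || b_range[1] > b_range[2]) {
    abort("`b_range` must be an interval of negative values.",
          class = "prefnr_invalid_spec")
  }
  g_opt_sd <- rep_len(g_opt_sd, length(sizes))
  if (any(g_opt_sd <= 0)) {
    abort("`g_opt_sd` must be positive.", class = "prefnr_invalid_spec")
  }
  if (pta_range[[1]][2] > 20 || pta_range[[2]][2] > 40 || pta_range[[3]][1] <= 40) {
    abort(paste0("PTA ranges must respect the group definitions ",
                 "(NH <= 20, HI-mild <= 40, HI-moderate > 40 dB HL)."),
          class = "prefnr_invalid_spec")
  }
  validate_levels(levels)
  structure(list(
    sizes = sizes, g_opt_median = g_opt_median, g_opt_sd = g_opt_sd,
    b_range = b_range, pta_range = pta_range,
    levels = levels, repetitions = repetitions,
    age_model = age_model, srt_model = srt_model,
    n_missing_srt = n_missing_srt
  ), class = "cohort_spec")
}

participant_seed <- function(master, group_index, within_index) {
  # per-participant substream: stable under changes to other group sizes
  (abs(master) %% 1000003L) * 1000L + group_index * 100L + within_index
}

#' Generate a synthetic cohort of paired-comparison listeners
#'
#' Draws, per participant, a true preferred strength and curvature from the
#' group distributions (the linear coefficient is then a = -2 b g_opt, so
#' the utility peaks exactly at the drawn optimum), simulates every design
#' trial as an independent Bernoulli choice with the QUL probability, and
#' generates PTA/age/SRT covariates. Each participant has a dedicated RNG
#' substream derived from the master seed, so cohorts are reproducible and
#' individual participants are stable when other group sizes change.
#'
#' @param spec A [cohort_spec()].
#' @param seed Master integer seed.
#' @return List of tibbles: `trials` (`participant_id`, `group`,
#'   `repetition`, `first_db`, `second_db`, `choice`), `meta`
#'   (`participant_id`, `group`, `pta_better_db_hl`, `age_years`,
#'   `srt_db`), `truth` (`participant_id`, `group`, `a`, `b`,
#'   `g_opt_true`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(sizes = c("NH" = 2, "HI-mild" = 2,
#'                                                 "HI-moderate" = 2)), seed = 1)
#' cohort$truth
generate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  design <- enumerate_design(spec$levels, spec$repetitions)
  groups <- names(spec$sizes)
  out <- purrr::map(seq_along(groups), function(gi) {
    size <- spec$sizes[[gi]]
    if (size == 0) return(NULL)
    purrr::map(seq_len(size), function(j) {
      id <- paste0(groups[gi], j)
      withr::with_seed(participant_seed(seed, gi, j), {
        g_opt <- rtrunc_norm(1, spec$g_opt_median[gi], spec$g_opt_sd[gi],
                             min(spec$levels), max(spec$levels))
        b <- stats::runif(1, spec$b_range[1], spec$b_range[2])
        a <- -2 * b * g_opt
        pta <- stats::runif(1, spec$pta_range[[gi]][1], spec$pta_range[[gi]][2])
        age <- spec$age_model$intercept + spec$age_model$slope * pta +
          stats::rnorm(1, 0, spec$age_model$sd)
        age <- min(max(age, 18), 90)
        srt <- spec$srt_model$intercept + spec$srt_model$slope * pta +
          stats::rnorm(1, 0, spec$srt_model$sd)
        if (groups[gi] == "NH" && j <= spec$n_missing_srt) srt <- NA_real_
        p <- qul_probability(a, b, design$first_db, design$second_db)
        first <- stats::runif(nrow(design)) < p
        list(
          trials = dplyr::mutate(design,
                                 participant_id = id, group = groups[gi],
                                 choice = ifelse(first, "first", "second"),
                                 .before = 1),
          meta = tibble(participant_id = id, group = groups[gi],
                        pta_better_db_hl = pta, age_years = age,
                        srt_db = srt),
          truth = tibble(participant_id = id, group = groups[gi],
                         a = a, b = b, g_opt_true = g_opt)
        )
      })
    })
  })
  out <- purrr::flatten(out)
  if (length(out) == 0) {
    return(list(trials = tibble(), meta = tibble(), truth = tibble()))
  }
  list(
    trials = dplyr::bind_rows(purrr::map(out, "trials")),
    meta = dplyr::bind_rows(purrr::map(out, "meta")),
    truth = dplyr::bind_rows(purrr::map(out, "truth"))
  )
}

#' Archetypal preference cohort with planted clusters
#'
#' A 30-listener cohort in three planted preference groups sized 6, 9 and
#' 15 — the no-NR, intermediate-NR and strong-NR cluster sizes the
#' full-cohort analysis is expected to recover. Archetype utilities are
#' kept inside the QUL family: the boundary preferrers use a steep linear
#' utility (large |a|, b = 0) and the intermediate group a sharply concave
#' utility peaking at 10 dB. With `noise = 0` every choice follows the
#' archetype's utility ordering deterministically (utility ties fall to the
#' first stimulus; the balanced AB/BA design cancels the bias); `noise`
#' is the per-trial probability that a choice is flipped.
#'
#' @param noise Per-trial choice-flip probability in \[0, 0.5\).
#' @param seed Master integer seed (used for flips; `noise = 0` is fully
#'   deterministic).
#' @param levels,repetitions The paired-comparison design.
#' @return List: `trials`, `truth` (tibble with `participant_id`,
#'   `planted_cluster`, `g_opt_true`, `a`, `b`).
#' @export
#' @examples
#' arch <- archetypes(noise = 0)
#' table(arch$truth$planted_cluster)  # 6, 9, 15
archetypes <- function(noise = 0, seed = 1, levels = study_levels(),
                       repetitions = 2) {
  if (noise < 0 || noise >= 0.5) {
    abort("`noise` must be in [0, 0.5).", class = "prefnr_invalid_spec")
  }
  design <- enumerate_design(levels, repetitions)
  arch <- tibble(
    planted_cluster = c(1L, 2L, 3L),
    n = c(6L, 9L, 15L),
    g_opt_true = c(0, 10, 18),
    a = c(-1.5, 3, 1.5),
    b = c(0, -0.15, 0)
  )
  rows <- purrr::pmap(arch, function(planted_cluster, n, g_opt_true, a, b) {
    purrr::map(seq_len(n), function(j) {
      id <- sprintf("A%02d_c%d", j, planted_cluster)
      du <- a * (design$first_db - design$second_db) +
        b * (design$first_db^2 - design$second_db^2)
      first <- du >= 0
      if (noise > 0) {
        flip <- withr::with_seed(
          participant_seed(seed, planted_cluster, j),
          stats::runif(nrow(design)) < noise
        )
        first <- xor(first, flip)
      }
      list(
        trials = dplyr::mutate(design,
                               participant_id = id,
                               choice = ifelse(first, "first", "second"),
                               .before = 1),
        truth = tibble(participant_id = id,
                       planted_cluster = planted_cluster,
                       g_opt_true = g_opt_true, a = a, b = b)
      )
    })
  })
  rows <- purrr::flatten(rows)
  list(
    trials = dplyr::bind_rows(purrr::map(rows, "trials")),
    truth = dplyr::bind_rows(purrr::map(rows, "truth"))
  )
}
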