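#' Noise-reduction strength grid of the reference study
#'
#' The ten maximum gain-reduction (Gmin) levels, in dB, at which stimuli were
#' processed: 0, 4, 6, 7, 8, 9, 10, 12, 16, 18. Every analysis function that
#' takes a `levels` argument defaults to this grid.
#'
#' @return Numeric vector of ten strictly increasing dB values.
#' @export
#' @examples
#' study_levels()
study_levels <- function() {
  c(0, 4, 6, 7, 8, 9, 10, 12, 16, 18)
}

validate_levels <- function(levels) {
  if (!is.numeric(levels) || anyNA(levels) || any(!is.finite(levels))) {
    abort("`levels` must be finite numeric dB values.", class = "prefnr_invalid_design")
  }
  if (length(levels) < 2) {
    abort("A paired-comparison design needs at least 2 distinct levels.",
          class = "prefnr_invalid_design")
  }
  if (anyDuplicated(levels)) {
    abort("`levels` contains duplicates; the design grid must be duplicate-free.",
          class = "prefnr_invalid_design")
  }
  if (any(levels < 0)) {
    abort("Gain-reduction levels are non-negative dB values.",
          class = "prefnr_invalid_design")
  }
  sort(levels)
}

#' Enumerate a complete round-robin paired-comparison design
#'
#' Builds every ordered pair (AB and BA, so presentation order is balanced) of
#' distinct strength levels, repeated `repetitions` times, giving
#' L(L-1) x repetitions trial templates per participant — 180 for the study
#' grid with two repetitions. Templates are emitted in a deterministic
#' canonical order (first level, second level, repetition); randomising the
#' presentation order is left to the caller so that enumeration stays
#' reproducible.
#'
#' @param levels Numeric vector of distinct dB levels. Default [study_levels()].
#' @param repetitions Number of repeats of every ordered pair (>= 1).
#' @return A tibble with columns `first_db`, `second_db`, `repetition`.
#' @export
#' @examples
#' nrow(enumerate_design())                      # 180
#' enumerate_design(c(0, 18), repetitions = 1)   # the two orders of one pair
enumerate_design <- function(levels = study_levels(), repetitions = 2) {
  levels <- validate_levels(levels)
  if (!is.numeric(repetitions) || length(repetitions) != 1 ||
      repetitions < 1 || repetitions != round(repetitions)) {
    abort("`repetitions` must be a single integer >= 1.",
          class = "prefnr_invalid_design")
  }
  grid <- tidyr::expand_grid(first_db = levels, second_db = levels,
                             repetition = seq_len(repetitions))
  grid |>
    dplyr::filter(.data$first_db != .data$second_db) |>
    dplyr::arrange(.data$first_db, .data$second_db, .data$repetition)
}

validate_trials <- function(trials, require_choice = TRUE) {
  needed <- c("first_db", "second_db", if (require_choice) "choice")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) {
    abort(paste0("`trials` is missing column(s): ", paste(missing, collapse = ", ")),
          class = "prefnr_invalid_trials")
  }
  if (nrow(trials) == 0) {
    abort("`trials` is empty.", class = "prefnr_invalid_trials")
  }
  if (any(trials$first_db == trials$second_db)) {
    abort("A trial presents two distinct levels; found first_db == second_db.",
          class = "prefnr_invalid_trials")
  }
  if (require_choice && !all(trials$choice %in% c("first", "second"))) {
    abort('`choice` must be "first" or "second" (forced choice, no ties).',
          class = "prefnr_invalid_trials")
  }
  invisible(trials)
}

#' Win-count profile of one participant
#'
#' For each level of the design grid, counts the trials in which the level
#' appeared and the trials in which it was the chosen stimulus, and forms the
#' win fraction wins/appearances. On the complete design every level appears
#' 2(L-1) x repetitions times (36 on the study grid). Partial trial sets
#' (e.g. resampled subsets) are allowed: a level that never appears gets
#' `win_fraction = NA` — deliberately not 0, which would fabricate
#' dispreference.
#'
#' @param trials Tibble with `first_db`, `second_db`, `choice` for a single
#'   participant.
#' @param levels Design grid the trials must live on. Default [study_levels()].
#' @return Tibble with `level_db`, `appearances`, `wins`, `win_fraction`,
#'   one row per grid level.
#' @export
#' @examples
#' trials <- simulate_responses(enumerate_design(), a = 0.48, b = -0.03, seed = 1)
#' win_profile(trials)
win_profile <- function(trials, levels = study_levels()) {
  levels <- validate_levels(levels)
  validate_trials(trials)
  used <- unique(c(trials$first_db, trials$second_db))
  off <- setdiff(used, levels)
  if (length(off)) {
    abort(paste0("Trial level(s) not on the design grid: ",
                 paste(off, collapse = ", ")),
          class = "prefnr_off_grid")
  }
  chosen <- ifelse(trials$choice == "first", trials$first_db, trials$second_db)
  appearances <- vapply(levels, function(l) {
    sum(trials$first_db == l) + sum(trials$second_db == l)
  }, integer(1))
  wins <- vapply(levels, function(l) sum(chosen == l), integer(1))
  tibble(
    level_db = levels,
    appearances = appearances,
    wins = wins,
    win_fraction = ifelse(appearances > 0, wins / appearances, NA_real_)
  )
}

#' Win-count profiles for every participant in a trial table
#'
#' @param trials Tibble with `participant_id`, `first_db`, `second_db`,
#'   `choice`.
#' @inheritParams win_profile
#' @return Tibble with `participant_id` plus the [win_profile()] columns.
#' @export
win_profiles <- function(trials, levels = study_levels()) {
  if (!"participant_id" %in% names(trials)) {
    abort("`trials` needs a `participant_id` column.", class = "prefnr_invalid_trials")
  }
  trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ win_profile(.x, levels = levels)) |>
    dplyr::ungroup()
}

#' Participants-by-levels matrix of win fractions
#'
#' Reshapes the long output of [win_profiles()] into the numeric matrix used
#' by the clustering functions (rows = participants, columns = dB levels).
#'
#' @param profiles Output of [win_profiles()].
#' @return Numeric matrix with participant ids as row names.
#' @export
profile_matrix <- function(profiles) {
  wide <- profiles |>
    dplyr::select("participant_id", "level_db", "win_fraction") |>
    tidyr::pivot_wider(names_from = "level_db", values_from = "win_fraction") |>
    dplyr::arrange(match(.data$participant_id, unique(profiles$participant_id)))
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$participant_id
  m
}
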