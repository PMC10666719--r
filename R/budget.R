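#' Build the reduced paired-comparison design for quick classification
#'
#' The clinical-screening design pairs each extreme strength with every
#' mid-range strength in both presentation orders, and weights the
#' extreme-vs-extreme comparison because it is the only one separating the
#' no-NR cluster from the strong-NR cluster. The study configuration
#' (mids 7, 8, 9, 10 dB; extremes 0 and 18 dB; weight 2) yields
#' 8 + 8 + 2 x 2 = 20 weighted ordered pairs and, with two repetitions, a
#' pool of 40 comparisons per participant.
#'
#' @param levels Full design grid the reduced levels must come from.
#' @param mids Mid-range strengths, dB.
#' @param extremes Length-2 vector: the low and high extreme strengths, dB.
#' @param extreme_weight Multiplicity of each extreme-vs-extreme ordered
#'   pair (>= 1).
#' @param repetitions Repetitions of every pool entry.
#' @return A `reduced_design` list: `levels`, `pairs` (tibble `first_db`,
#'   `second_db`, `multiplicity`), `n_pairs` (weighted count),
#'   `repetitions`, `pool_size`.
#' @export
#' @examples
#' build_reduced_design()$n_pairs   # 20
#' build_reduced_design()$pool_size # 40
build_reduced_design <- function(levels = study_levels(),
                                 mids = c(7, 8, 9, 10),
                                 extremes = c(0, 18),
                                 extreme_weight = 2,
                                 repetitions = 2) {
  if (length(extremes) != 2) {
    abort("`extremes` must hold exactly the low and high strength.",
          class = "prefnr_invalid_design")
  }
  if (length(intersect(mids, extremes))) {
    abort("`mids` and `extremes` must not overlap.",
          class = "prefnr_invalid_design")
  }
  off <- setdiff(c(mids, extremes), levels)
  if (length(off)) {
    abort(paste0("Reduced levels not on the design grid: ",
                 paste(off, collapse = ", ")),
          class = "prefnr_invalid_design")
  }
  if (extreme_weight < 1 || extreme_weight != round(extreme_weight)) {
    abort("`extreme_weight` must be an integer >= 1.",
          class = "prefnr_invalid_design")
  }
  lo <- min(extremes); hi <- max(extremes)
  pairs <- dplyr::bind_rows(
    tibble(first_db = lo, second_db = mids, multiplicity = 1),
    tibble(first_db = mids, second_db = lo, multiplicity = 1),
    tibble(first_db = hi, second_db = mids, multiplicity = 1),
    tibble(first_db = mids, second_db = hi, multiplicity = 1),
    tibble(first_db = c(lo, hi), second_db = c(hi, lo),
           multiplicity = extreme_weight)
  ) |>
    dplyr::arrange(.data$first_db, .data$second_db)
  structure(list(
    levels = sort(unique(c(mids, extremes))),
    pairs = pairs,
    n_pairs = sum(pairs$multiplicity),
    repetitions = repetitions,
    pool_size = sum(pairs$multiplicity) * repetitions
  ), class = "reduced_design")
}

#' @export
print.reduced_design <- function(x, ...) {
  cat("Reduced paired-comparison design: levels",
      paste(x$levels, collapse = ", "), "dB;",
      x$n_pairs, "weighted pairs x", x$repetitions, "repetitions =",
      x$pool_size, "comparisons\n")
  invisible(x)
}

#' Extract a participant's reduced-design comparison pool
#'
#' Pulls, from a full-design trial table, the responses to the ordered pairs
#' of a reduced design, expanded by pair multiplicity and repetition. A pair
#' with multiplicity 2 contributes the same underlying response twice — the
#' pool reuses the data, it does not re-ask the listener.
#'
#' @param trials Trials of a single participant (full design).
#' @param design A [build_reduced_design()] object.
#' @return Tibble of pool comparisons (`first_db`, `second_db`,
#'   `repetition`, `choice`), `design$pool_size` rows.
#' @export
reduced_pool <- function(trials, design = build_reduced_design()) {
  validate_trials(trials)
  templates <- design$pairs |>
    tidyr::uncount(.data$multiplicity) |>
    tidyr::expand_grid(repetition = seq_len(design$repetitions))
  pool <- dplyr::left_join(
    templates,
    dplyr::select(trials, "first_db", "second_db", "repetition", "choice"),
    by = c("first_db", "second_db", "repetition"),
    relationship = "many-to-one"
  )
  if (anyNA(pool$choice)) {
    abort("Trials do not cover every comparison of the reduced design.",
          class = "prefnr_invalid_input")
  }
  pool
}

centroid_matrix <- function(centroids, levels) {
  missing_lv <- setdiff(levels, centroids$level_db)
  if (length(missing_lv)) {
    abort(paste0("Centroids not defined at level(s): ",
                 paste(missing_lv, collapse = ", ")),
          class = "prefnr_invalid_input")
  }
  wide <- centroids |>
    dplyr::filter(.data$level_db %in% levels) |>
    dplyr::select("cluster", "level_db", "mean_win_fraction") |>
    tidyr::pivot_wider(names_from = "level_db",
                       values_from = "mean_win_fraction") |>
    dplyr::arrange(.data$cluster)
  m <- as.matrix(wide[-1])
  m <- m[, as.character(sort(levels)), drop = FALSE]
  rownames(m) <- wide$cluster
  m
}

# integer-coded pool for fast repeated tallying inside the resampling loop
pool_codes <- function(pool, levels) {
  fi <- match(pool$first_db, levels)
  si <- match(pool$second_db, levels)
  list(fi = fi, si = si,
       ci = ifelse(pool$choice == "first", fi, si),
       n_levels = length(levels))
}

classify_draw <- function(codes, idx, cmat) {
  app <- tabulate(c(codes$fi[idx], codes$si[idx]), nbins = codes$n_levels)
  wins <- tabulate(codes$ci[idx], nbins = codes$n_levels)
  defined <- app > 0  # levels absent from the draw are excluded, not imputed
  w <- wins[defined] / app[defined]
  d2 <- apply(cmat[, defined, drop = FALSE], 1,
              function(cv) sum((w - cv)^2))
  near <- d2 <= min(d2) + 1e-12
  near / sum(near)  # ties split equally across nearest centroids
}

#' Classify resampled comparison subsets to the nearest preference cluster
#'
#' Simulates a shortened listening test: draw `budget` comparisons from the
#' participant's reduced-design pool uniformly without replacement, form win
#' fractions over the levels actually appearing in the draw, and assign the
#' draw to the cluster whose centroid profile is nearest in Euclidean
#' distance (levels absent from the draw are excluded from the distance;
#' exact ties split the assignment equally). Repeating the draw estimates
#' the probability of each assignment; `method = "exact"` averages over
#' every subset instead when the enumeration is feasible.
#'
#' @param pool Participant pool from [reduced_pool()] (or any trial tibble).
#' @param centroids Cluster centroid profiles ([cluster_centroids()] output
#'   or any tibble with `cluster`, `level_db`, `mean_win_fraction`); levels
#'   beyond the pool's are ignored.
#' @param budget Number of comparisons to draw (1 <= budget <= pool size).
#' @param replicates Monte-Carlo replicates (default 500).
#' @param seed Optional integer seed; same seed, same estimate.
#' @param method `"montecarlo"` (default) or `"exact"` (full subset
#'   enumeration; requires choose(pool, budget) <= 2e5).
#' @return Tibble with `cluster`, `probability`, `replicates`, `method`;
#'   probabilities sum to 1.
#' @export
subsample_classify <- function(pool, centroids, budget, replicates = 500,
                               seed = NULL,
                               method = c("montecarlo", "exact")) {
  method <- match.arg(method)
  validate_trials(pool)
  n_pool <- nrow(pool)
  if (budget < 1 || budget > n_pool) {
    abort("`budget` must be between 1 and the pool size.",
          class = "prefnr_invalid_input")
  }
  levels <- sort(unique(c(pool$first_db, pool$second_db)))
  cmat <- centroid_matrix(centroids, levels)
  codes <- pool_codes(pool, levels)
  if (method == "exact") {
    if (choose(n_pool, budget) > 2e5) {
      abort("Exact enumeration infeasible for this pool/budget.",
            class = "prefnr_invalid_input")
    }
    subsets <- utils::combn(n_pool, budget)
    acc <- rowMeans(apply(subsets, 2, function(idx) {
      classify_draw(codes, idx, cmat)
    }))
    reps <- ncol(subsets)
  } else {
    run <- function() {
      out <- matrix(0, nrow(cmat), replicates)
      for (r in seq_len(replicates)) {
        idx <- sample.int(n_pool, budget)
        out[, r] <- classify_draw(codes, idx, cmat)
      }
      rowMeans(out)
    }
    acc <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    reps <- replicates
  }
  tibble(cluster = rownames(cmat), probability = unname(acc),
         replicates = reps, method = method)
}

#' Probability of correct cluster assignment versus comparison budget
#'
#' For each budget, estimates by resampling how often a draw of that many
#' comparisons from the participant's pool lands in the participant's true
#' cluster (the one assigned from the complete design).
#'
#' @inheritParams subsample_classify
#' @param true_cluster The participant's cluster from the full-design
#'   clustering; must match a centroid `cluster` id.
#' @param budgets Budgets to evaluate (default 5, 10, ..., 40).
#' @param seed One integer seed governing the whole curve.
#' @return Tibble with `budget`, `p_correct`, `replicates`.
#' @export
budget_curve <- function(pool, centroids, true_cluster,
                         budgets = seq(5, 40, by = 5), replicates = 500,
                         seed = NULL) {
  if (!true_cluster %in% unique(centroids$cluster)) {
    abort("`true_cluster` does not match any centroid cluster id.",
          class = "prefnr_invalid_input")
  }
  run <- function() {
    purrr::map(budgets, function(n) {
      res <- subsample_classify(pool, centroids, n, replicates = replicates)
      tibble(budget = n,
             p_correct = res$probability[res$cluster == as.character(true_cluster)],
             replicates = replicates)
    }) |> dplyr::bind_rows()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Budget curves for a whole cohort
#'
#' Runs [budget_curve()] for every participant: extracts each reduced pool
#' from the full-design trials and uses the participant's cluster label as
#' the ground truth.
#'
#' @param trials Full-design trial table with `participant_id`.
#' @param labels Cluster labels from [cut_tree()].
#' @param centroids Cluster centroid profiles.
#' @param design Reduced design, default [build_reduced_design()].
#' @inheritParams budget_curve
#' @return Tibble with `participant_id`, `true_cluster`, `budget`,
#'   `p_correct`, `replicates`.
#' @export
budget_curve_cohort <- function(trials, labels, centroids,
                                design = build_reduced_design(),
                                budgets = seq(5, 40, by = 5),
                                replicates = 500, seed = NULL) {
  ids <- unique(trials$participant_id)
  run <- function() {
    purrr::imap(ids, function(id, i) {
      pool <- reduced_pool(trials[trials$participant_id == id, ], design)
      tc <- labels$cluster[labels$participant_id == id]
      if (length(tc) != 1) {
        abort(paste0("No unique cluster label for participant ", id),
              class = "prefnr_invalid_input")
      }
      budget_curve(pool, centroids, tc, budgets = budgets,
                   replicates = replicates) |>
        dplyr::mutate(participant_id = id, true_cluster = tc, .before = 1)
    }) |> dplyr::bind_rows()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Plot probability-of-correct-cluster curves
#'
#' @param object Output of [budget_curve_cohort()] (or [budget_curve()]
#'   with a `participant_id` column added).
#' @param ... Unused.
#' @return A ggplot object, one panel per participant.
#' @export
plot_budget_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$budget, y = .data$p_correct)) +
    ggplot2::geom_hline(yintercept = 0.5, colour = "steelblue",
                        linewidth = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Number of paired comparisons",
                  y = "P(correct cluster)")
}
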