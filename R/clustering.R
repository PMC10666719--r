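#' Manhattan (L1) distance matrix between win-count profiles
#'
#' Pairwise L1 distances between participants' win-fraction vectors,
#' d(p, q) = sum over levels of |fraction_p - fraction_q|. The L1 metric is
#' used because it is more robust to outlying profiles than the Euclidean
#' distance. Distances are computed on win fractions rather than raw counts;
#' on the complete design the two differ only by the constant appearance
#' count, so the clustering is identical, while fractions stay comparable
#' across reduced designs.
#'
#' @param profiles Long profile tibble from [win_profiles()], or a numeric
#'   participants-by-levels matrix such as [profile_matrix()] returns.
#' @return A `stats::dist` object (participants in input order).
#' @export
manhattan_matrix <- function(profiles) {
  m <- if (is.matrix(profiles)) profiles else profile_matrix(profiles)
  if (anyNA(m)) {
    abort(paste0("Profiles contain undefined win fractions (levels with no ",
                 "appearances); distances would be meaningless."),
          class = "prefnr_invalid_input")
  }
  dist(m, method = "manhattan")
}

#' Ward agglomerative clustering of participants
#'
#' Hierarchical agglomeration under Ward's minimum within-cluster variance
#' criterion, chosen because it tends to find same-size, compact clusters.
#' The Lance-Williams Ward coefficients are applied to the dissimilarities
#' as supplied (the classic `"ward.D"` convention, the default and the
#' variant used in the reference analysis); `variant = "ward.D2"` applies
#' the criterion to squared dissimilarities instead.
#'
#' @param d A `dist` object, e.g. from [manhattan_matrix()].
#' @param variant `"ward.D"` (default) or `"ward.D2"`.
#' @return A `stats::hclust` tree; merge heights are the cluster
#'   dissimilarities at merge time.
#' @export
ward_linkage <- function(d, variant = c("ward.D", "ward.D2")) {
  variant <- match.arg(variant)
  d <- as.dist(d)
  if (attr(d, "Size") < 2) {
    abort("Clustering needs at least 2 participants.",
          class = "prefnr_invalid_input")
  }
  hclust(d, method = variant)
}

#' Merge table of a linkage tree
#'
#' Flat tidy view of the agglomeration: one row per merge with child ids
#' (negative = leaf, positive = earlier merge, the `hclust` convention),
#' merge height and merged cluster size.
#'
#' @param linkage An `hclust` tree.
#' @return Tibble with `step`, `child_a`, `child_b`, `height`, `size`.
#' @export
linkage_table <- function(linkage) {
  stopifnot(inherits(linkage, "hclust"))
  sizes <- numeric(nrow(linkage$merge))
  for (i in seq_len(nrow(linkage$merge))) {
    ch <- linkage$merge[i, ]
    sizes[i] <- sum(ifelse(ch < 0, 1, sizes[pmax(ch, 1)]))
  }
  tibble(step = seq_along(linkage$height),
         child_a = linkage$merge[, 1],
         child_b = linkage$merge[, 2],
         height = linkage$height,
         size = sizes)
}

#' Cut a linkage tree into k clusters
#'
#' @param linkage An `hclust` tree over participants.
#' @param k Number of clusters, 1 <= k <= n.
#' @return Tibble with `participant_id`, `cluster` (integer ids 1..k).
#' @export
cut_tree <- function(linkage, k) {
  stopifnot(inherits(linkage, "hclust"))
  n <- length(linkage$labels %||% seq_len(nrow(linkage$merge) + 1))
  if (k < 1 || k > n) {
    abort("`k` must be between 1 and the number of participants.",
          class = "prefnr_invalid_input")
  }
  labels <- cutree(linkage, k = k)
  tibble(participant_id = names(labels) %||% as.character(seq_along(labels)),
         cluster = unname(labels))
}

#' Rank cluster counts by dendrogram stability
#'
#' A clustering into k groups is stable when it persists over a long span of
#' merge heights: lifetime(k) is the height at which k clusters collapse to
#' k - 1 minus the height at which k + 1 collapsed to k. The k = 2 solution
#' is bounded above by the root merge, the end of the dendrogram's range.
#' Solutions are returned in decreasing order of lifetime.
#'
#' @param linkage An `hclust` tree.
#' @return Tibble with `k`, `lifetime`, `height_lower`, `height_upper`,
#'   sorted by descending lifetime.
#' @export
stable_solutions <- function(linkage) {
  stopifnot(inherits(linkage, "hclust"))
  h <- linkage$height
  n <- length(h) + 1
  if (n < 3) {
    return(tibble(k = integer(), lifetime = numeric(),
                  height_lower = numeric(), height_upper = numeric()))
  }
  ks <- 2:(n - 1)
  # after merge i there are n - i clusters: k clusters live on [h[n-k], h[n-k+1]]
  lower <- h[n - ks]
  upper <- h[n - ks + 1]
  tibble(k = ks, lifetime = upper - lower,
         height_lower = lower, height_upper = upper) |>
    dplyr::arrange(dplyr::desc(.data$lifetime), .data$k)
}

#' Per-cluster mean win-count profiles
#'
#' The profile of a preference cluster is the arithmetic mean of its
#' members' win fractions at each level, with the across-participant sample
#' SD as a dispersion estimate. Singleton clusters report SD 0, flagged.
#'
#' @param labels Tibble from [cut_tree()] (`participant_id`, `cluster`).
#' @param profiles Long profile tibble from [win_profiles()].
#' @return Tibble with `cluster`, `level_db`, `mean_win_fraction`,
#'   `sd_win_fraction`, `n_members`, `singleton`.
#' @export
cluster_centroids <- function(labels, profiles) {
  missing <- setdiff(unique(profiles$participant_id), labels$participant_id)
  if (length(missing)) {
    abort(paste0("No cluster label for participant(s): ",
                 paste(missing, collapse = ", ")),
          class = "prefnr_invalid_input")
  }
  profiles |>
    dplyr::inner_join(labels, by = "participant_id") |>
    dplyr::group_by(.data$cluster, .data$level_db) |>
    dplyr::summarise(
      mean_win_fraction = mean(.data$win_fraction),
      sd_win_fraction = ifelse(dplyr::n() > 1, stats::sd(.data$win_fraction), 0),
      n_members = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(singleton = .data$n_members == 1)
}

#' Plot cluster centroid profiles
#'
#' Mean win fraction per level for each preference cluster, with error bars
#' showing the across-participant SD.
#'
#' @param object Output of [cluster_centroids()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_cluster_centroids <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$level_db, y = .data$mean_win_fraction,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_win_fraction - .data$sd_win_fraction,
                   ymax = .data$mean_win_fraction + .data$sd_win_fraction),
      width = 0.4) +
    ggplot2::labs(x = "Maximum gain reduction (dB)", y = "Mean win fraction",
                  colour = "Cluster") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}
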