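# Independent reference implementations used only to check the package.

# Naive O(n^3) Lance-Williams agglomerator (Ward coefficients applied to the
# dissimilarities as given). Returns merge heights and the partition after
# each merge, canonically labelled.
naive_ward <- function(d) {
  D <- as.matrix(d)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  part <- seq_len(n)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        i <- active[ii]; j <- active[jj]
        if (D[i, j] < best_d - 1e-12) {
          best_d <- D[i, j]; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- best_d
    ni <- sizes[i]; nj <- sizes[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- sizes[k]
      tot <- ni + nj + nk
      new_d <- (ni + nk) / tot * D[i, k] + (nj + nk) / tot * D[j, k] -
        nk / tot * D[i, j]
      D[i, k] <- D[k, i] <- new_d
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
    part[members[[i]]] <- i
    partitions[[step]] <- canon_labels(part)
  }
  list(heights = heights, partitions = partitions)
}

# canonical labelling: clusters numbered by first appearance
canon_labels <- function(x) {
  match(x, unique(x))
}

# Grid-search maximum-likelihood oracle for the QUL model.
qul_nll <- function(a, b, trials) {
  du <- a * (trials$first_db - trials$second_db) +
    b * (trials$first_db^2 - trials$second_db^2)
  y <- trials$choice == "first"
  -sum(ifelse(y, plogis(du, log.p = TRUE), plogis(-du, log.p = TRUE)))
}

grid_mle <- function(trials, a_range, b_range, step = 0.005) {
  a_grid <- seq(a_range[1], a_range[2], by = step)
  b_grid <- seq(b_range[1], b_range[2], by = step)
  nll <- outer(a_grid, b_grid, Vectorize(function(a, b) qul_nll(a, b, trials)))
  idx <- arrayInd(which.min(nll), dim(nll))
  list(a = a_grid[idx[1]], b = b_grid[idx[2]], step = step)
}

# random win-fraction profile tibbles on the study grid
random_profiles <- function(n, levels = prefnr::study_levels()) {
  purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(participant_id = paste0("p", i), level_db = levels,
                   appearances = 36L, wins = 18L,
                   win_fraction = stats::runif(length(levels)))
  })
}

adjusted_rand <- function(x, y) mclust::adjustedRandIndex(x, y)
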