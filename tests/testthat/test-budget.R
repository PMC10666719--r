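# a deterministic no-NR preferrer and simple centroid set used throughout
make_pool <- function() {
  arch <- archetypes(noise = 0)
  id <- arch$truth$participant_id[arch$truth$planted_cluster == 1][1]
  reduced_pool(arch$trials[arch$trials$participant_id == id, ])
}

make_centroids <- function() {
  arch <- archetypes(noise = 0)
  prof <- win_profiles(arch$trials)
  hc <- ward_linkage(manhattan_matrix(prof))
  lab <- cut_tree(hc, 3)
  # relabel clusters by planted identity so cluster 1 = no-NR archetype
  map <- arch$truth |>
    dplyr::inner_join(lab, by = "participant_id") |>
    dplyr::distinct(planted_cluster, cluster)
  lab$cluster <- map$planted_cluster[match(lab$cluster, map$cluster)]
  cluster_centroids(lab, prof)
}

test_that("the reduced design counts its weighted pairs and pool", {
  rd <- build_reduced_design()
  expect_equal(rd$n_pairs, 20)
  expect_equal(rd$pool_size, 40)
  expect_equal(rd$levels, c(0, 7, 8, 9, 10, 18))
  # the extreme-vs-extreme ordered pairs carry multiplicity 2 each way
  ext <- rd$pairs[rd$pairs$first_db %in% c(0, 18) &
                    rd$pairs$second_db %in% c(0, 18), ]
  expect_equal(ext$multiplicity, c(2, 2))
  expect_equal(build_reduced_design(extreme_weight = 1)$n_pairs, 18)
  expect_error(build_reduced_design(mids = c(0, 8)),
               class = "prefnr_invalid_design")
})

test_that("the pool reuses full-design responses, doubled pairs included", {
  pool <- make_pool()
  expect_equal(nrow(pool), 40)
  # 0 vs 18 appears 2 (weight) x 2 (orders) x 2 (repetitions) = 8 times
  ext <- pool[pool$first_db %in% c(0, 18) & pool$second_db %in% c(0, 18), ]
  expect_equal(nrow(ext), 8)
  short <- tibble::tibble(first_db = 0, second_db = 7, repetition = 1,
                          choice = "first")
  expect_error(reduced_pool(short), class = "prefnr_invalid_input")
})

test_that("a responder on a centroid is classified to it", {
  pool <- make_pool()
  cent <- make_centroids()
  # at very small budgets an unlucky draw (e.g. only mid-vs-18 comparisons)
  # can sit nearer another centroid, so certainty is only reached with budget
  res5 <- subsample_classify(pool, cent, 5, replicates = 200, seed = 1)
  expect_gte(res5$probability[res5$cluster == "1"], 0.9)
  expect_equal(sum(res5$probability), 1)
  for (n in c(20, 40)) {
    res <- subsample_classify(pool, cent, n, replicates = 200, seed = 1)
    expect_equal(res$probability[res$cluster == "1"], 1)
    expect_equal(sum(res$probability), 1)
  }
})

test_that("the full-pool budget is deterministic across replicates", {
  pool <- make_pool()
  cent <- make_centroids()
  r1 <- subsample_classify(pool, cent, 40, replicates = 7, seed = 5)
  r2 <- subsample_classify(pool, cent, 40, replicates = 123, seed = 99)
  expect_equal(r1$probability, r2$probability)
  expect_true(all(r1$probability %in% c(0, 1)))
})

test_that("identical seeds give bit-identical estimates", {
  arch <- archetypes(noise = 0.2, seed = 3)
  id <- arch$truth$participant_id[15]
  pool <- reduced_pool(arch$trials[arch$trials$participant_id == id, ])
  cent <- make_centroids()
  a <- subsample_classify(pool, cent, 15, seed = 42)
  b <- subsample_classify(pool, cent, 15, seed = 42)
  c <- subsample_classify(pool, cent, 15, seed = 43)
  expect_identical(a$probability, b$probability)
  expect_false(identical(a$probability, c$probability))
})

test_that("Monte-Carlo estimates match exhaustive enumeration at budget 39", {
  arch <- archetypes(noise = 0.25, seed = 11)
  id <- arch$truth$participant_id[arch$truth$planted_cluster == 2][1]
  pool <- reduced_pool(arch$trials[arch$trials$participant_id == id, ])
  cent <- make_centroids()
  exact <- subsample_classify(pool, cent, 39, method = "exact")
  mc <- subsample_classify(pool, cent, 39, replicates = 500, seed = 7)
  se <- sqrt(pmax(exact$probability * (1 - exact$probability), 1e-6) / 500)
  expect_true(all(abs(mc$probability - exact$probability) <= 3 * se + 1e-9))
})

test_that("tied centroids split the assignment equally", {
  pool <- make_pool()
  cent <- make_centroids()
  dup <- dplyr::bind_rows(
    dplyr::mutate(cent[cent$cluster == 1, ], cluster = 1L),
    dplyr::mutate(cent[cent$cluster == 1, ], cluster = 2L)
  )
  res <- subsample_classify(pool, dup, 10, replicates = 20, seed = 2)
  expect_equal(res$probability, c(0.5, 0.5))
})

test_that("budget curves are reproducible and consistent at the endpoints", {
  pool <- make_pool()
  cent <- make_centroids()
  bc1 <- budget_curve(pool, cent, true_cluster = 1, replicates = 100, seed = 9)
  bc2 <- budget_curve(pool, cent, true_cluster = 1, replicates = 100, seed = 9)
  expect_identical(bc1, bc2)
  full <- subsample_classify(pool, cent, 40, replicates = 1)
  expect_equal(bc1$p_correct[bc1$budget == 40],
               full$probability[full$cluster == "1"])
  expect_error(budget_curve(pool, cent, true_cluster = 99),
               class = "prefnr_invalid_input")
  expect_error(subsample_classify(pool, cent, 41),
               class = "prefnr_invalid_input")
})

test_that("mean correct probability is non-decreasing in budget for archetypes", {
  cent <- make_centroids()
  arch <- archetypes(noise = 0)
  ids <- arch$truth$participant_id[c(1, 7, 16)]  # one per planted cluster
  curves <- purrr::map(seq_along(ids), function(i) {
    pool <- reduced_pool(arch$trials[arch$trials$participant_id == ids[i], ])
    tc <- arch$truth$planted_cluster[arch$truth$participant_id == ids[i]]
    purrr::map(1:10, function(s) {
      budget_curve(pool, cent, tc, replicates = 100, seed = s)$p_correct
    }) |> purrr::reduce(`+`) / 10
  })
  avg <- purrr::reduce(curves, `+`) / length(curves)
  expect_true(all(diff(avg) >= -0.02))
})

test_that("cohort-level curves carry ids and the true cluster", {
  arch <- archetypes(noise = 0.1, seed = 21)
  sub_ids <- arch$truth$participant_id[c(1, 8)]
  trials <- arch$trials[arch$trials$participant_id %in% sub_ids, ]
  labels <- tibble::tibble(
    participant_id = sub_ids,
    cluster = arch$truth$planted_cluster[match(sub_ids,
                                               arch$truth$participant_id)]
  )
  res <- budget_curve_cohort(trials, labels, make_centroids(),
                             budgets = c(10, 20), replicates = 50, seed = 1)
  expect_equal(nrow(res), 4)
  expect_setequal(unique(res$participant_id), sub_ids)
  expect_true(all(res$p_correct >= 0 & res$p_correct <= 1))
})
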