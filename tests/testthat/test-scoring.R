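test_that("true interactors outrank null preys in the combined ranking", {
  sim <- simulate_apms_dataset(apms_sim_config(
    n_baits = 2, n_preys = 24, n_true_interactors_per_bait = 3,
    conserved_fraction = 0, effect_mean = 3, effect_sd = 0.1, seed = 6))
  scores <- suppressMessages(score_interactions(sim$dataset, quick_inference()))
  truth <- sim$truth$true_effects
  joined <- dplyr::left_join(scores,
                             dplyr::mutate(truth, true = TRUE),
                             by = c("bait_id", "prey_id"))
  for (b in unique(truth$bait_id)) {
    sub <- joined[joined$bait_id == b, ]
    best_null <- min(sub$rank_within_bait[is.na(sub$true)])
    worst_true <- max(sub$rank_within_bait[!is.na(sub$true)])
    expect_lt(worst_true, best_null)
  }
  # ranks are a permutation consistent with ascending combined p
  for (b in unique(scores$bait_id)) {
    sub <- scores[scores$bait_id == b, ]
    expect_setequal(sub$rank_within_bait, seq_len(nrow(sub)))
    ord <- order(sub$p_combined, sub$prey_id)
    expect_equal(sub$rank_within_bait[ord], seq_len(nrow(sub)))
  }
})

test_that("missing channels reduce the degrees of freedom, never impute", {
  sim <- simulate_apms_dataset(apms_sim_config(
    n_baits = 2, n_preys = 20, n_true_interactors_per_bait = 0,
    baseline_mean = 0.3, seed = 8))
  scores <- suppressMessages(score_interactions(sim$dataset, quick_inference()))
  pm <- as.matrix(scores[, c("p_counts", "p_score_a", "p_score_b")])
  recombined <- apply(pm, 1, function(p) fisher_combine(p[!is.na(p)]))
  expect_equal(scores$p_combined, unname(recombined))
  expect_true(any(is.na(pm)))  # the sparse regime does produce missing channels
})

test_that("top-k selection flags exactly min(k, n) pairs per bait", {
  tbl <- tibble::tibble(
    bait_id = rep(c("b1", "b2"), c(5, 2)),
    prey_id = c(paste0("p", 1:5), "q1", "q2"),
    p_combined = c(0.5, 0.01, 0.2, 0.03, 0.9, 0.4, 0.1)
  ) |>
    dplyr::group_by(bait_id) |>
    dplyr::arrange(p_combined, prey_id, .by_group = TRUE) |>
    dplyr::mutate(rank_within_bait = dplyr::row_number()) |>
    dplyr::ungroup()
  out <- select_top_interactions(tbl, k = 3)
  expect_equal(sort(out$prey_id[out$selected & out$bait_id == "b1"]),
               c("p2", "p3", "p4"))
  expect_equal(sum(out$selected[out$bait_id == "b2"]), 2)  # fewer than k
  all_sel <- select_top_interactions(tbl, k = 300)
  expect_true(all(all_sel$selected))
  expect_error(select_top_interactions(tbl, k = 0), "k")
})

test_that("conservation filtering keeps >=min_baits preys minus exclusions", {
  sets <- list(b1 = c("shared", "edge4", "excl"), b2 = c("shared", "edge4", "excl"),
               b3 = c("shared", "edge4", "excl"), b4 = c("shared", "edge4", "excl"),
               b5 = c("shared", "excl"), b6 = c("shared", "excl"),
               b7 = c("shared", "excl"))
  expect_equal(conserved_interactors(sets, min_baits = 5,
                                     exclusion_list = "excl"),
               "shared")                       # 7/7 kept, exclusion dropped
  expect_false("edge4" %in% conserved_interactors(sets, min_baits = 5))  # 4/7
  expect_true("edge4" %in% conserved_interactors(sets, min_baits = 4))
  expect_error(conserved_interactors(sets, min_baits = 8), "exceeds")
  # empty result is allowed
  expect_length(conserved_interactors(list(b1 = "x", b2 = "y"), min_baits = 2),
                0)
})

test_that("union of per-bait selections is bounded by baits x k", {
  sim <- simulate_apms_dataset(apms_sim_config(
    n_baits = 3, n_preys = 15, n_true_interactors_per_bait = 2,
    conserved_fraction = 0, seed = 12))
  scores <- suppressMessages(score_interactions(sim$dataset, quick_inference()))
  sel <- select_top_interactions(scores, k = 4)
  chosen <- sel[sel$selected, ]
  expect_lte(length(unique(chosen$prey_id)), 3 * 4)
  expect_equal(nrow(chosen), 3 * 4)
})
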