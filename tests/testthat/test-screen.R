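test_that("relative depletion normalizes to the baseline measurement", {
  flat <- tibble::tibble(timepoint_day = c(2, 7, 14),
                         gfp_percent = c(50, 50, 50))
  expect_equal(relative_depletion(flat)$ratio, c(1, 1, 1))

  half <- tibble::tibble(timepoint_day = c(2, 14), gfp_percent = c(50, 25))
  expect_equal(relative_depletion(half)$ratio[2], 0.5)

  expect_error(relative_depletion(half, baseline_day = 5), "absent")
  zero <- tibble::tibble(timepoint_day = c(2, 14), gfp_percent = c(0, 10))
  expect_error(relative_depletion(zero), "zero")
})

test_that("control scaling anchors the negative control at 0 and positive at 1", {
  expect_equal(control_scaled_score(0.9, 0.9, 0.2), 0)
  expect_equal(control_scaled_score(0.2, 0.9, 0.2), 1)
  expect_equal(control_scaled_score(0.55, 0.9, 0.2), 0.5)
  expect_error(control_scaled_score(0.5, 0.3, 0.3), "degenerate")
  # gene ordering is invariant to a common rescaling of all final ratios
  g <- c(0.8, 0.5, 0.2)
  s1 <- control_scaled_score(g, 1, 0.1)
  s2 <- control_scaled_score(2 * g, 2, 0.2)
  expect_equal(order(s1), order(s2))
})

test_that("depletion z-scores standardize with the population sd, depletion positive", {
  z <- depletion_zscore(c(a = 1, b = 0, c = -1))
  expect_equal(unname(z), c(1, 0, -1) / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(z[["a"]], 3), 1.225)
  expect_error(depletion_zscore(c(a = 1, b = 1, c = 1)), "zero spread")
  expect_error(depletion_zscore(c(a = 1, b = 2)), "at least 3")
  base <- depletion_zscore(c(a = 1, b = 0, c = -1))
  shifted <- depletion_zscore(c(a = 6, b = 5, c = 4))
  expect_equal(base, shifted)
  s <- c(a = 0.9, b = 0.2, c = 0.4, d = 0.1)
  zz <- depletion_zscore(s)
  expect_equal(mean(zz), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(zz^2)), 1, tolerance = 1e-12)
  expect_gt(zz[["a"]], zz[["d"]])  # strongest depletion gets the largest z
})

test_that("the combined essentiality score flips exactly at the threshold", {
  m <- rbind(ubiq = rep(1, 18),
             ten = c(rep(1, 10), rep(0, 8)),
             nine = c(rep(1, 9), rep(0, 9)),
             none = rep(0, 18))
  tab <- essentiality_score(m)
  expect_equal(tab$score, c(18L, 10L, 9L, 0L))
  expect_equal(tab$essential, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(essentiality_score(m[, 1:17]), "17")
  m2 <- m; m2[1, 1] <- 2
  expect_error(essentiality_score(m2), "0 or 1")
})

test_that("selectivity contrasts fusion-context and wild-type depletion", {
  scores <- tibble::tibble(
    gene_id = rep(c("sel", "flat"), each = 4),
    context = rep(c("fusion", "fusion", "wildtype", "wildtype"), 2),
    scaled_score = c(0.9, 0.8, 0.1, 0.0, 0.5, 0.5, 0.5, 0.5)
  )
  out <- selectivity(scores)
  sel <- out[out$gene_id == "sel", ]
  expect_equal(sel$mean_fusion, 0.85)
  expect_equal(sel$mean_wt, 0.05)
  expect_equal(sel$delta, 0.8)
  expect_equal(out$delta[out$gene_id == "flat"], 0)
  # genes missing a context are skipped with a message
  part <- dplyr::bind_rows(scores,
                           tibble::tibble(gene_id = "orphan",
                                          context = "fusion",
                                          scaled_score = 1))
  expect_message(out2 <- selectivity(part), "orphan")
  expect_false("orphan" %in% out2$gene_id)
})

test_that("comet tail moment is distance times tail fraction", {
  expect_equal(comet_tail_moment(10, 0.5), 5)
  expect_equal(comet_tail_moment(7, 0), 0)
  expect_equal(comet_tail_moment(0, 0.8), 0)
  expect_error(comet_tail_moment(-1, 0.5), "non-negative")
  expect_error(comet_tail_moment(1, 1.5), "0, 1")
})

test_that("noise-free simulated screens behave exactly as labelled", {
  sim <- simulate_screen(n_genes = 30, noise_sd = 0, seed = 5)
  tr <- sim$trajectories

  neutral <- sim$truth$neutral_set[1]
  nt <- tr[tr$gene_id == neutral & tr$cell_line == "MOLM-13", ]
  expect_true(all(nt$gfp_percent == nt$gfp_percent[1]))

  pos <- tr[tr$gene_id == sim$controls$positive & tr$cell_line == "MOLM-13", ]
  expect_true(all(diff(pos$gfp_percent) < 0))

  sel_gene <- sim$truth$selective_set[1]
  sf <- relative_depletion(tr[tr$gene_id == sel_gene & tr$context == "fusion" &
                                tr$cell_line == "MOLM-13", ])
  sw <- relative_depletion(tr[tr$gene_id == sel_gene & tr$cell_line == "K562", ])
  expect_lt(sf$ratio[nrow(sf)], 1)
  expect_equal(sw$ratio[nrow(sw)], 1)

  expect_true(all(tr$gfp_percent >= 0 & tr$gfp_percent <= 100))
  expect_error(simulate_screen(noise_sd = -0.1), "noise_sd")
  expect_identical(simulate_screen(n_genes = 10, seed = 3)$trajectories,
                   simulate_screen(n_genes = 10, seed = 3)$trajectories)
})

test_that("screen scoring recovers the planted gene classes at zero noise", {
  sim <- simulate_screen(n_genes = 40, noise_sd = 0, seed = 8)
  scored <- screen_score(sim$trajectories)
  ess <- scored$scaled_score[scored$gene_id %in% sim$truth$essential_set]
  expect_true(all(abs(ess - 1) < 1e-9))  # essential tracks the positive control
  neu <- scored$scaled_score[scored$gene_id %in% sim$truth$neutral_set]
  expect_true(all(abs(neu) < 1e-9))
  sel <- selectivity(scored)
  expect_true(all(sel$delta[sel$gene_id %in% sim$truth$selective_set] > 0.9))
  expect_true(all(abs(sel$delta[sel$gene_id %in% sim$truth$essential_set]) < 1e-9))
  wt_sel <- sel$mean_wt[sel$gene_id %in% sim$truth$selective_set]
  expect_true(all(abs(wt_sel) < 1e-9))
})
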