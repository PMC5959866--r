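test_that("spike-in factors downscale to the smallest library", {
  expect_equal(spikein_factors(c(a = 5, b = 5, c = 5)),
               c(a = 1, b = 1, c = 1))
  expect_equal(spikein_factors(c(A = 1e6, B = 2e6)), c(A = 1, B = 0.5))
  expect_equal(spikein_factors(c(only = 3)), c(only = 1))
  # scale invariance: doubling every total leaves factors unchanged
  x <- c(a = 8e5, b = 1.2e6, c = 1e6)
  expect_equal(spikein_factors(x), spikein_factors(2 * x))
  expect_error(spikein_factors(c(a = 0, b = 1)), "positive")
})

test_that("input subtraction scales both libraries and floors at zero", {
  counts <- tibble::tibble(gene_id = c("g1", "g2", "g3"),
                           mark = "H3K36me3",
                           ip_count = c(80, 50, 80),
                           input_count = c(60, 60, 20))
  f <- c(H3K36me3 = 1, input = 1)
  out <- normalize_and_subtract(counts, f)
  expect_equal(out$adjusted_signal, c(20, 0, 60))
  f2 <- c(H3K36me3 = 0.5, input = 1)
  out2 <- normalize_and_subtract(counts, f2)
  expect_equal(out2$adjusted_signal[3], 20)  # 80*0.5 - 20*1
  expect_error(normalize_and_subtract(counts, c(H3K36me3 = 1)), "missing factors")
})

test_that("TMM factors match hand-derived values and multiply to one", {
  set.seed(4)
  base <- matrix(rpois(300, 80), 100, 3)
  ident <- cbind(base[, 1], base[, 1], base[, 1])
  expect_equal(unname(tmm_factors(ident)), rep(1, 3))

  two <- cbind(A = base[, 1], B = 2 * base[, 1])
  f <- tmm_factors(two)
  expect_equal(unname(f), c(sqrt(2), 1 / sqrt(2)), tolerance = 1e-9)

  four <- cbind(base[, 1], base[, 1], base[, 1], 2 * base[, 1])
  f4 <- tmm_factors(four)
  expect_lt(f4[4], 1)
  expect_true(all(f4[1:3] > 1))
  expect_equal(prod(f4), 1, tolerance = 1e-9)
  # invariant to gene ordering
  perm <- sample(nrow(four))
  expect_equal(tmm_factors(four[perm, ]), f4, tolerance = 1e-12)
  expect_error(tmm_factors(cbind(base[, 1], 0 * base[, 1])), "all-zero")
})

test_that("TMM factors agree with edgeR once depth conventions are aligned", {
  set.seed(9)
  m <- matrix(rpois(600, 100), 200, 3)
  m[1:40, 2] <- rpois(40, 400)  # composition shift in one sample
  mine <- unname(tmm_factors(m))
  ef <- edgeR::calcNormFactors(m, refColumn = 1)
  libs <- colSums(m)
  theirs <- 1 / (ef * libs)
  theirs <- unname(theirs / exp(mean(log(theirs))))
  expect_equal(mine, theirs, tolerance = 0.02)
})

test_that("the high/low call is strict: equality does not exceed input", {
  expect_equal(classify_high_low(80, 60), "high")
  expect_equal(classify_high_low(60, 60), "low")
  expect_equal(classify_high_low(0, 0), "low")
  expect_equal(classify_high_low(c(5, 1), c(2, 9)), c("high", "low"))
})

test_that("noise-free ChIP simulation is classified back exactly", {
  sim <- simulate_chip_counts(n_genes = 400, noise = "none", seed = 6)
  calls <- classify_signature(sim$table)
  merged <- dplyr::inner_join(calls, sim$truth, by = "gene_id",
                              suffix = c("_call", "_truth"))
  expect_equal(merged$H3K36me3_call, merged$H3K36me3_truth)
  expect_equal(merged$H3K79me2_call, merged$H3K79me2_truth)
  expect_equal(merged$dual_high_call, merged$dual_high_truth)

  # degenerate probabilities recover the target set exactly
  sim2 <- simulate_chip_counts(n_genes = 200, p_dual_high_target = 1,
                               p_dual_high_nontarget = 0, noise = "none",
                               seed = 7)
  calls2 <- classify_signature(sim2$table)
  expect_setequal(calls2$gene_id[calls2$dual_high],
                  sim2$table$gene_sets$MLL_target)
})

test_that("the chip generator is deterministic and validates inputs", {
  a <- simulate_chip_counts(n_genes = 100, seed = 3)
  b <- simulate_chip_counts(n_genes = 100, seed = 3)
  expect_identical(a$table$counts, b$table$counts)
  expect_error(simulate_chip_counts(n_genes = 50, target_set = "nope"),
               "subset")
  expect_error(simulate_chip_counts(p_dual_high_target = 1.5), "proportion")
  expect_error(simulate_chip_counts(
    spikein_totals = c(H3K36me3 = 0, H3K79me2 = 1, input = 1)), "positive")
})

test_that("dual-signature fractions and ordering match the planted labels", {
  sim <- simulate_chip_counts(n_genes = 2000, seed = 10)
  calls <- classify_signature(sim$table)
  target <- sim$table$gene_sets$MLL_target
  nontarget <- setdiff(calls$gene_id, target)
  ft <- dual_signature_fraction(calls, target)
  fn <- dual_signature_fraction(calls, nontarget)
  expect_gt(ft, fn)  # ordered as the generator probabilities
  expect_equal(dual_signature_fraction(calls, calls$gene_id),
               mean(calls$dual_high))
  expect_error(dual_signature_fraction(calls, character(0)), "nonempty")
  expect_error(dual_signature_fraction(calls, "absent_gene"), "without")
})

test_that("mark correlation is plain Pearson with guard rails", {
  x <- 1:10
  expect_equal(mark_correlation(x, 2 * x + 1), 1)
  expect_equal(mark_correlation(x, -x), -1)
  set.seed(2)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(abs(mark_correlation(a, b)), 0.05)
  expect_error(mark_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(mark_correlation(1:2, 1:2), "at least 3")
})
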