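test_that("a strongly bait-enriched prey gets a positive, confident enrichment", {
  ds <- tiny_apms_dataset()
  fit <- fit_enrichment_model(ds, "counts", quick_inference())
  td <- tidy(fit)
  x <- td[td$prey_id == "preyX", ]
  expect_gt(x$estimate, 0)
  expect_gt(x$conf.low, 0)   # 95% credible interval excludes 0

  # independent oracle: exact Poisson rate-ratio test on the same totals
  # (60 spectra over 3 bait runs vs 2 over 3 control runs)
  pt <- stats::poisson.test(c(60, 2), c(3, 3), alternative = "greater")
  expect_lt(pt$p.value, 0.001)  # the exact test agrees the rate is elevated
  expect_lt(enrichment_pvalue(fit, "MLL-AF9", "preyX"), 0.01)
})

test_that("an exchangeable prey's credible interval covers zero", {
  ds <- tiny_apms_dataset()
  fit <- fit_enrichment_model(ds, "counts", quick_inference())
  td <- tidy(fit)
  y <- td[td$prey_id == "preyY", ]
  expect_lt(abs(y$estimate), 0.75)
  expect_lt(y$conf.low, 0)
  expect_gt(y$conf.high, 0)
})

test_that("with large counts the fitted baseline matches the observed log mean", {
  tbl <- tiny_apms_table()
  tbl$spectral_count[tbl$prey_id == "bg1"] <- 150
  tbl$score_a[tbl$prey_id == "bg1"] <- 150 * 8
  tbl$score_b[tbl$prey_id == "bg1"] <- 150 * 10
  ds <- preprocess_apms(tbl, background_prey_ids = c("bg1", "bg2"))
  fit <- fit_enrichment_model(ds, "counts", quick_inference())
  a0 <- fit$estimates$A0[["bg1"]]
  alpha <- fit$estimates$alpha[["MLL-AF9"]]
  expect_lt(abs((a0 + alpha) - log(150)) / log(150), 0.05)
})

test_that("the sampler reproduces the posterior of a general-purpose MCMC engine", {
  ds <- tiny_apms_dataset()
  inf <- inference_config(chains = 2, iter = 2000, burnin = 1000, seed = 3)
  fit <- fit_enrichment_model(ds, "counts", inf)

  runs <- ds$runs
  preys <- sort(unique(ds$observations$prey_id))
  Y <- matrix(0, nrow(runs), length(preys),
              dimnames = list(runs$run_id, preys))
  Y[cbind(match(ds$observations$run_id, runs$run_id),
          match(ds$observations$prey_id, preys))] <- ds$observations$spectral_count
  free_prey <- as.integer(!preys %in% c("bg1", "bg2"))
  jm <- rjags::jags.model(
    textConnection("
      model {
        for (r in 1:R) {
          for (j in 1:J) {
            lambda[r, j] <- exp(A0[j] +
              (1 - ctrl[r]) * (freep[j] * A[j] + alpha + beta[r]))
            Y[r, j] ~ dpois(lambda[r, j])
          }
        }
        for (j in 1:J) {
          A0[j] ~ dnorm(0, 0.01)
          A[j] ~ dnorm(0, 0.04)
        }
        alpha ~ dnorm(0, 0.04)
        for (r in 1:R) { beta[r] ~ dnorm(0, 1 / (sb * sb)) }
        sb ~ dnorm(0, 1) T(0,)
      }"),
    data = list(Y = Y, R = nrow(Y), J = ncol(Y),
                ctrl = as.integer(runs$is_control), freep = free_prey),
    n.chains = 2, n.adapt = 1000, quiet = TRUE,
    inits = list(.RNG.name = "base::Mersenne-Twister", .RNG.seed = 7))
  samp <- rjags::coda.samples(jm, c("A"), n.iter = 4000)
  jags_mean <- colMeans(as.matrix(samp))
  for (p in c("preyX", "preyY")) {
    mine <- fit$estimates$A[[paste("MLL-AF9", p, sep = "|")]]
    theirs <- jags_mean[[sprintf("A[%d]", match(p, preys))]]
    expect_lt(abs(mine - theirs), 0.2)
  }
})

test_that("fits are deterministic given the inference seed", {
  ds <- tiny_apms_dataset()
  f1 <- fit_enrichment_model(ds, "counts", quick_inference(seed = 9))
  f2 <- fit_enrichment_model(ds, "counts", quick_inference(seed = 9))
  expect_identical(f1$draws$A, f2$draws$A)
})

test_that("log-normal score channels are fitted on observed cells only", {
  ds <- tiny_apms_dataset()
  fit <- fit_enrichment_model(ds, "score_a", quick_inference())
  td <- tidy(fit)
  expect_gt(td$estimate[td$prey_id == "preyX"], 0)
  expect_true(all(c("preyX", "preyY") %in% td$prey_id))
  expect_false(any(td$prey_id %in% c("bg1", "bg2")))  # anchors carry no A
})

test_that("posterior tail p-values follow the add-one correction exactly", {
  mkfit <- function(draws) {
    structure(list(pairs = tibble::tibble(bait_id = "b", prey_id = "p",
                                          column = 1L),
                   draws = list(A = matrix(draws, ncol = 1))),
              class = "apms_fit")
  }
  expect_equal(enrichment_pvalue(mkfit(rep(1, 99)), "b", "p"), 1 / 100)
  expect_equal(enrichment_pvalue(mkfit(rep(-1, 50)), "b", "p"), 1)
  sym <- c(seq(-1, -0.01, length.out = 50), seq(0.01, 1, length.out = 50))
  expect_equal(enrichment_pvalue(mkfit(sym), "b", "p"), 51 / 101)
  expect_error(enrichment_pvalue(mkfit(1), "b", "nope"), "no enrichment")
})

test_that("fit metadata reports dimensions and convergence diagnostics", {
  ds <- tiny_apms_dataset()
  fit <- fit_enrichment_model(ds, "counts", quick_inference())
  g <- glance(fit)
  expect_equal(g$channel, "counts")
  expect_equal(g$n_enrichment_params, 2)  # preyX, preyY (anchors fixed)
  expect_true(is.finite(g$max_rhat))
})
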