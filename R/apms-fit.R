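
#' MCMC settings for the enrichment model
#'
#' Controls the random-walk Metropolis-within-Gibbs sampler used by
#' [fit_enrichment_model()]. Defaults (4 chains, 5,000 kept draws after
#' 2,000 adaptation/burn-in iterations) are sized for a full analysis;
#' simulation studies in the vignette use fewer draws.
#'
#' Priors are weakly informative on the log scale and can be overridden:
#' baselines `A0 ~ N(0, 10^2)`, enrichments `A ~ N(0, 5^2)`, bait offsets
#' `alpha ~ N(0, 5^2)`, replicate offsets `beta ~ N(0, sigma_beta^2)` with
#' `sigma_beta ~ Half-Normal(1)`, and the log-normal channel sd
#' `~ Half-Normal(1)`.
#'
#' @param chains Number of independent chains.
#' @param iter Kept draws per chain (after burn-in).
#' @param burnin Adaptation/burn-in iterations discarded per chain.
#' @param seed Integer seed; chain c uses `seed + c`.
#' @param prior_sd_A0,prior_sd_A,prior_sd_alpha Prior sds.
#' @param half_normal_scale Scale of the half-normal priors on variance
#'   components.
#' @param rhat_threshold Split-R-hat above which the fit is flagged
#'   non-converged.
#' @return A list of class `apms_inference_config`.
#' @export
inference_config <- function(chains = 4, iter = 5000, burnin = 2000,
                             seed = 1L,
                             prior_sd_A0 = 10, prior_sd_A = 5,
                             prior_sd_alpha = 5, half_normal_scale = 1,
                             rhat_threshold = 1.05) {
  structure(list(
    chains = check_count(chains, "chains"),
    iter = check_count(iter, "iter"),
    burnin = check_count(burnin, "burnin", min = 0L),
    seed = check_count(seed, "seed", min = 0L),
    prior_sd_A0 = check_sd(prior_sd_A0, "prior_sd_A0"),
    prior_sd_A = check_sd(prior_sd_A, "prior_sd_A"),
    prior_sd_alpha = check_sd(prior_sd_alpha, "prior_sd_alpha"),
    half_normal_scale = check_sd(half_normal_scale, "half_normal_scale"),
    rhat_threshold = as.numeric(rhat_threshold)
  ), class = "apms_inference_config")
}

# split-R-hat over a list of per-chain draw matrices (iter x params)
split_rhat <- function(chain_mats) {
  halves <- list()
  for (m in chain_mats) {
    n <- nrow(m)
    h <- n %/% 2L
    halves <- c(halves, list(m[seq_len(h), , drop = FALSE],
                             m[seq(h + 1L, 2L * h), , drop = FALSE]))
  }
  n <- nrow(halves[[1]])
  means <- vapply(halves, colMeans, numeric(ncol(halves[[1]])))
  vars <- vapply(halves, function(x) apply(x, 2, var),
                 numeric(ncol(halves[[1]])))
  if (is.null(dim(means))) {  # single parameter
    means <- matrix(means, nrow = 1)
    vars <- matrix(vars, nrow = 1)
  }
  W <- rowMeans(vars)
  B <- n * apply(means, 1, var)
  rhat <- sqrt((((n - 1) / n) * W + B / n) / W)
  rhat[W == 0] <- 1
  rhat
}

# one chain of the vectorized random-walk Metropolis-within-Gibbs sampler.
# V: R x J data matrix (counts, or log scores with NA), M: observation mask,
# ib: bait index per run (NA for controls), family: "poisson" | "normal".
run_chain <- function(V, M, ib, free, family, inf, chain_seed) {
  R <- nrow(V); J <- ncol(V); B <- nrow(free)
  bait_rows <- which(!is.na(ib))
  ibr <- ib[bait_rows]
  Vm <- ifelse(M, V, 0)

  # sufficient statistics that never change
  S1_col <- colSums(Vm)
  S1_bait <- rowsum(Vm[bait_rows, , drop = FALSE], ibr)
  S1_run <- rowSums(Vm)[bait_rows]
  n_col <- colSums(M)
  n_bait <- rowsum(M[bait_rows, , drop = FALSE] * 1, ibr)
  n_run <- rowSums(M)[bait_rows]
  n_tot <- sum(M)

  with_seed(chain_seed, {
    # initial values from crude moment matching
    if (family == "poisson") {
      ctrl <- which(is.na(ib))
      A0 <- log(pmax(colSums(Vm[ctrl, , drop = FALSE]) /
                       pmax(colSums(M[ctrl, , drop = FALSE]), 1), 0.5))
    } else {
      A0 <- colSums(Vm) / pmax(n_col, 1)
      A0[n_col == 0] <- mean(V[M])
    }
    Amat <- matrix(0, B, J)
    alpha <- numeric(B)
    beta <- numeric(R)
    sigma <- if (family == "normal") max(sd(V[M]), 0.2) else NA_real_
    sigma_b <- 0.5

    eta <- matrix(A0, R, J, byrow = TRUE)
    eta[bait_rows, ] <- eta[bait_rows, ] + Amat[ibr, , drop = FALSE] +
      alpha[ibr] + beta[bait_rows]

    # step sizes, adapted during burn-in only
    s_A0 <- rep(0.2, J); s_A <- matrix(0.4, B, J); s_alpha <- rep(0.1, B)
    s_beta <- rep(0.1, R); s_lsb <- 0.3; s_lsig <- 0.2
    s_shift_b <- rep(0.2, B); s_shift_j <- rep(0.2, J)

    # cells NOT compensated by a free enrichment parameter; these carry the
    # likelihood signal of the joint ridge updates below
    NF <- !free
    ctrl_rows <- which(is.na(ib))
    nfree_row <- rowSums(free)
    nfree_col <- colSums(free)
    S1_ctrl_col <- colSums(Vm[ctrl_rows, , drop = FALSE])
    n_ctrl_col <- colSums(M[ctrl_rows, , drop = FALSE])
    S1_shift_b <- rowSums(S1_bait * NF)
    n_shift_b <- rowSums(n_bait * NF)
    S1_shift_j <- S1_ctrl_col + colSums(S1_bait * NF)
    n_shift_j <- n_ctrl_col + colSums(n_bait * NF)

    n_free <- sum(free)
    keep_A <- matrix(NA_real_, inf$iter, n_free)
    keep_A0 <- matrix(NA_real_, inf$iter, J)
    keep_alpha <- matrix(NA_real_, inf$iter, B)
    keep_beta <- matrix(NA_real_, inf$iter, length(bait_rows))
    keep_sig <- matrix(NA_real_, inf$iter, if (family == "normal") 2L else 1L)

    total <- inf$burnin + inf$iter
    for (t in seq_len(total)) {
      adapting <- t <= inf$burnin
      gam <- if (adapting) min(0.25, 2 / sqrt(t)) else 0
      EX <- if (family == "poisson") M * exp(eta) else NULL
      Rm <- if (family == "normal") M * (V - eta) else NULL
      if (family == "normal") Rm[is.na(Rm)] <- 0

      # -- baselines A0 (one independent scalar update per prey)
      eps <- rnorm(J, 0, s_A0)
      if (family == "poisson") {
        d <- eps * S1_col - (exp(eps) - 1) * colSums(EX)
      } else {
        d <- (eps * colSums(Rm) - eps^2 * n_col / 2) / sigma^2
      }
      d <- d - ((A0 + eps)^2 - A0^2) / (2 * inf$prior_sd_A0^2)
      acc <- log(runif(J)) < d
      A0 <- A0 + eps * acc
      eta <- eta + rep(eps * acc, each = R)
      if (adapting) s_A0 <- s_A0 * exp(gam * ((acc * 1) - 0.44))

      # -- enrichments A (free bait x prey cells)
      if (family == "poisson") {
        EX <- M * exp(eta)
        EXb <- rowsum(EX[bait_rows, , drop = FALSE], ibr)
      } else {
        Rm <- M * (V - eta); Rm[is.na(Rm)] <- 0
        Rb <- rowsum(Rm[bait_rows, , drop = FALSE], ibr)
      }
      eps <- matrix(rnorm(B * J, 0, s_A), B, J) * free
      if (family == "poisson") {
        d <- eps * S1_bait - (exp(eps) - 1) * EXb
      } else {
        d <- (eps * Rb - eps^2 * n_bait / 2) / sigma^2
      }
      d <- d - ((Amat + eps)^2 - Amat^2) / (2 * inf$prior_sd_A^2)
      acc <- (matrix(log(runif(B * J)), B, J) < d) & free
      step <- eps * acc
      Amat <- Amat + step
      eta[bait_rows, ] <- eta[bait_rows, ] + step[ibr, , drop = FALSE]
      if (adapting) s_A <- s_A * exp(gam * ((acc * 1) - 0.44) * free)

      # -- bait background offsets alpha
      if (family == "poisson") {
        EX <- M * exp(eta)
        EXa <- rowSums(rowsum(EX[bait_rows, , drop = FALSE], ibr))
      } else {
        Rm <- M * (V - eta); Rm[is.na(Rm)] <- 0
        Ra <- rowSums(rowsum(Rm[bait_rows, , drop = FALSE], ibr))
      }
      S1a <- rowSums(S1_bait)
      na_ <- rowSums(n_bait)
      eps <- rnorm(B, 0, s_alpha)
      if (family == "poisson") {
        d <- eps * S1a - (exp(eps) - 1) * EXa
      } else {
        d <- (eps * Ra - eps^2 * na_ / 2) / sigma^2
      }
      d <- d - ((alpha + eps)^2 - alpha^2) / (2 * inf$prior_sd_alpha^2)
      acc <- log(runif(B)) < d
      alpha <- alpha + eps * acc
      eta[bait_rows, ] <- eta[bait_rows, ] + (eps * acc)[ibr]
      if (adapting) s_alpha <- s_alpha * exp(gam * ((acc * 1) - 0.44))

      # -- replicate offsets beta (bait runs only; fixed 0 in controls)
      if (family == "poisson") {
        EXr <- rowSums((M * exp(eta)))[bait_rows]
      } else {
        Rm <- M * (V - eta); Rm[is.na(Rm)] <- 0
        Rr <- rowSums(Rm)[bait_rows]
      }
      eps <- rnorm(length(bait_rows), 0, s_beta[bait_rows])
      if (family == "poisson") {
        d <- eps * S1_run - (exp(eps) - 1) * EXr
      } else {
        d <- (eps * Rr - eps^2 * n_run / 2) / sigma^2
      }
      b0 <- beta[bait_rows]
      d <- d - ((b0 + eps)^2 - b0^2) / (2 * sigma_b^2)
      acc <- log(runif(length(eps))) < d
      beta[bait_rows] <- b0 + eps * acc
      eta[bait_rows, ] <- eta[bait_rows, ] + eps * acc
      if (adapting) {
        s_beta[bait_rows] <- s_beta[bait_rows] * exp(gam * ((acc * 1) - 0.44))
      }

      # -- joint ridge update: alpha_i + eps, A_ij - eps for free j.
      # likelihood changes only at bait i's uncompensated (background) cells
      if (family == "poisson") {
        EXb <- rowsum((M * exp(eta))[bait_rows, , drop = FALSE], ibr)
        EX_sh <- rowSums(EXb * NF)
      } else {
        Rm <- M * (V - eta); Rm[is.na(Rm)] <- 0
        Rb <- rowsum(Rm[bait_rows, , drop = FALSE], ibr)
        R_sh <- rowSums(Rb * NF)
      }
      eps <- rnorm(B, 0, s_shift_b)
      if (family == "poisson") {
        d <- eps * S1_shift_b - (exp(eps) - 1) * EX_sh
      } else {
        d <- (eps * R_sh - eps^2 * n_shift_b / 2) / sigma^2
      }
      d <- d - ((alpha + eps)^2 - alpha^2) / (2 * inf$prior_sd_alpha^2)
      d <- d - (-2 * eps * rowSums(Amat * free) + eps^2 * nfree_row) /
        (2 * inf$prior_sd_A^2)
      acc <- log(runif(B)) < d
      step <- eps * acc
      alpha <- alpha + step
      Amat <- Amat - outer(step, rep(1, J)) * free
      eta[bait_rows, ] <- eta[bait_rows, ] + step[ibr] -
        (outer(step, rep(1, J)) * free)[ibr, , drop = FALSE]
      if (adapting) s_shift_b <- s_shift_b * exp(gam * ((acc * 1) - 0.44))

      # -- joint ridge update: A0_j + eps, A_ij - eps for all free baits.
      # signal comes from control runs and uncompensated bait cells
      if (family == "poisson") {
        EX <- M * exp(eta)
        EXb <- rowsum(EX[bait_rows, , drop = FALSE], ibr)
        EX_shj <- colSums(EX[ctrl_rows, , drop = FALSE]) + colSums(EXb * NF)
      } else {
        Rm <- M * (V - eta); Rm[is.na(Rm)] <- 0
        Rb <- rowsum(Rm[bait_rows, , drop = FALSE], ibr)
        R_shj <- colSums(Rm[ctrl_rows, , drop = FALSE]) + colSums(Rb * NF)
      }
      eps <- rnorm(J, 0, s_shift_j)
      if (family == "poisson") {
        d <- eps * S1_shift_j - (exp(eps) - 1) * EX_shj
      } else {
        d <- (eps * R_shj - eps^2 * n_shift_j / 2) / sigma^2
      }
      d <- d - ((A0 + eps)^2 - A0^2) / (2 * inf$prior_sd_A0^2)
      d <- d - (-2 * eps * colSums(Amat * free) + eps^2 * nfree_col) /
        (2 * inf$prior_sd_A^2)
      acc <- log(runif(J)) < d
      step <- eps * acc
      A0 <- A0 + step
      stepM <- matrix(step, B, J, byrow = TRUE) * free
      Amat <- Amat - stepM
      eta <- eta + rep(step, each = R)
      eta[bait_rows, ] <- eta[bait_rows, ] - stepM[ibr, , drop = FALSE]
      if (adapting) s_shift_j <- s_shift_j * exp(gam * ((acc * 1) - 0.44))

      # -- exact Gibbs redraw of the alpha/beta decomposition: the
      # likelihood depends on alpha_i + beta_ik only, so given those sums
      # alpha_i | rest is conjugate Normal and beta picks up the remainder
      csum <- alpha[ibr] + beta[bait_rows]
      tot <- rowsum(csum, ibr)[, 1]
      K_i <- tabulate(ibr, B)
      prec <- 1 / inf$prior_sd_alpha^2 + K_i / sigma_b^2
      mu_a <- (tot / sigma_b^2) / prec
      alpha <- rnorm(B, mu_a, sqrt(1 / prec))
      beta[bait_rows] <- csum - alpha[ibr]

      # -- sigma_beta (half-normal prior, log-scale random walk)
      lsb <- log(sigma_b)
      lsb_new <- lsb + rnorm(1, 0, s_lsb)
      bb <- beta[bait_rows]
      lp <- function(ls) {
        s <- exp(ls)
        -length(bb) * ls - sum(bb^2) / (2 * s^2) -
          s^2 / (2 * inf$half_normal_scale^2) + ls
      }
      if (log(runif(1)) < lp(lsb_new) - lp(lsb)) sigma_b <- exp(lsb_new)
      # (step size for the two scalars left at its default; they mix fast)

      # -- residual sd of the log-normal channel
      if (family == "normal") {
        ls <- log(sigma)
        ls_new <- ls + rnorm(1, 0, s_lsig)
        SS <- sum((M * (V - eta))[M]^2)
        lpn <- function(l) {
          s <- exp(l)
          -n_tot * l - SS / (2 * s^2) - s^2 / (2 * inf$half_normal_scale^2) + l
        }
        if (log(runif(1)) < lpn(ls_new) - lpn(ls)) sigma <- exp(ls_new)
      }

      if (!adapting) {
        k <- t - inf$burnin
        keep_A[k, ] <- Amat[free]
        keep_A0[k, ] <- A0
        keep_alpha[k, ] <- alpha
        keep_beta[k, ] <- beta[bait_rows]
        keep_sig[k, ] <- if (family == "normal") c(sigma_b, sigma) else sigma_b
      }
    }
    list(A = keep_A, A0 = keep_A0, alpha = keep_alpha, beta = keep_beta,
         sigma = keep_sig)
  })
}

#' Fit the Bayesian enrichment model to one MS evidence channel
#'
#' Fits the log-linear model `A0_j + A_ij + alpha_i + beta_ik` to one
#' evidence channel of an AP-MS dataset: spectral counts under a Poisson
#' likelihood, or a peptide-score channel under a log-normal likelihood.
#' `A0_j` is the log baseline abundance of prey j, `A_ij` its specific
#' enrichment in bait i's pulldowns, and `alpha_i`, `beta_ik` bait- and
#' replicate-level background terms.
#'
#' Identifiability is enforced by two anchors: (a) control runs carry no
#' enrichment or background terms, so control data pin the baselines; and
#' (b) designated background preys (DDX5/DDX17 analogues) are constrained
#' to `A_ij = 0` in every bait, so their abundance in bait runs identifies
#' `alpha_i + beta_ik`. Enrichments are estimated only for (bait, prey)
#' pairs with at least one observation in that bait's runs. Inference is a
#' vectorized random-walk Metropolis-within-Gibbs sampler; convergence is
#' monitored by split-R-hat and flagged (with a warning) in the fit
#' metadata when above the threshold, never silently.
#'
#' @param dataset An `apms_dataset` from [preprocess_apms()] or
#'   [simulate_apms_dataset()].
#' @param channel `"counts"`, `"score_a"`, or `"score_b"`.
#' @param inference An [inference_config()].
#' @return An object of class `apms_fit` with posterior draws, posterior
#'   mean point estimates, the free (bait, prey) pair index, and metadata
#'   (chains, iterations, seed, max split-R-hat, anchoring description).
#' @seealso [enrichment_pvalue()], [score_interactions()], [tidy.apms_fit()]
#' @export
fit_enrichment_model <- function(dataset,
                                 channel = c("counts", "score_a", "score_b"),
                                 inference = inference_config()) {
  if (!inherits(dataset, "apms_dataset")) {
    abort("`dataset` must be an apms_dataset.")
  }
  channel <- match.arg(channel)
  obs <- dataset$observations
  runs <- dataset$runs
  if (!any(runs$is_control)) abort("dataset needs at least one control run.")
  baits <- sort(unique(stats::na.omit(runs$bait_id)))
  if (length(baits) == 0) abort("dataset has no bait runs.")
  preys <- sort(unique(obs$prey_id))
  R <- nrow(runs); J <- length(preys); B <- length(baits)

  # dense matrices; (run, prey) pairs absent from the table are count 0
  key_r <- match(obs$run_id, runs$run_id)
  key_j <- match(obs$prey_id, preys)
  counts <- matrix(0, R, J, dimnames = list(runs$run_id, preys))
  counts[cbind(key_r, key_j)] <- obs$spectral_count
  if (channel == "counts") {
    V <- counts
    M <- matrix(TRUE, R, J)
    family <- "poisson"
  } else {
    V <- matrix(NA_real_, R, J, dimnames = list(runs$run_id, preys))
    V[cbind(key_r, key_j)] <- log(obs[[channel]])
    M <- !is.na(V)
    V[!M] <- 0
    family <- "normal"
    if (!any(M)) abort(sprintf("channel %s has no observed data.", channel))
  }

  ib <- match(runs$bait_id, baits)
  bg_j <- match(intersect(dataset$background_prey_ids, preys), preys)
  if (length(bg_j) > 0) {
    bg_seen <- colSums(M[, bg_j, drop = FALSE] *
                         (counts[, bg_j, drop = FALSE] > 0 | channel != "counts"))
    if (any(rowSums(M[, bg_j, drop = FALSE]) == 0)) {
      warn("background preys are not observed in every run; the background anchor will be weak.")
    }
  }

  # free enrichment cells: non-background pairs observed in that bait's runs
  bait_rows <- which(!is.na(ib))
  obs_bait <- rowsum((M & (if (channel == "counts") counts > 0 else TRUE))[
    bait_rows, , drop = FALSE] * 1, ib[bait_rows]) > 0
  if (channel == "counts") {
    # a count of 0 is still an observation; every non-background pair is free
    free <- matrix(TRUE, B, J)
  } else {
    free <- obs_bait
  }
  if (length(bg_j) > 0) free[, bg_j] <- FALSE

  chains <- lapply(seq_len(inference$chains), function(cc) {
    run_chain(V, M, ib, free, family, inference, inference$seed + cc)
  })

  pool <- function(name) do.call(rbind, lapply(chains, `[[`, name))
  draws <- list(A = pool("A"), A0 = pool("A0"), alpha = pool("alpha"),
                beta = pool("beta"), sigma = pool("sigma"))
  free_idx <- which(free)
  pairs <- tibble(
    bait_id = baits[row(free)[free_idx]],
    prey_id = preys[col(free)[free_idx]],
    column = seq_along(free_idx)
  )
  colnames(draws$A) <- paste(pairs$bait_id, pairs$prey_id, sep = "|")
  colnames(draws$A0) <- preys
  colnames(draws$alpha) <- baits
  colnames(draws$beta) <- runs$run_id[bait_rows]
  colnames(draws$sigma) <- if (family == "normal") c("sigma_beta", "sigma") else "sigma_beta"

  rhats <- c(
    A = max(split_rhat(lapply(chains, `[[`, "A"))),
    A0 = max(split_rhat(lapply(chains, `[[`, "A0"))),
    alpha = max(split_rhat(lapply(chains, `[[`, "alpha"))),
    beta = max(split_rhat(lapply(chains, `[[`, "beta")))
  )
  converged <- max(rhats) < inference$rhat_threshold
  if (!converged) {
    warn(sprintf("enrichment model (%s): max split-R-hat %.3f exceeds %.2f; inspect glance() output.",
                 channel, max(rhats), inference$rhat_threshold))
  }

  structure(list(
    channel = channel,
    family = family,
    pairs = pairs,
    baits = baits,
    preys = preys,
    draws = draws,
    estimates = list(
      A = setNames(colMeans(draws$A), colnames(draws$A)),
      A0 = colMeans(draws$A0),
      alpha = colMeans(draws$alpha),
      beta = colMeans(draws$beta)
    ),
    meta = list(
      chains = inference$chains, iter = inference$iter,
      burnin = inference$burnin, seed = inference$seed,
      rhat = rhats, max_rhat = max(rhats), converged = converged,
      rhat_threshold = inference$rhat_threshold,
      anchoring = paste("controls pin baselines (A=0, beta=0 in controls);",
                        "background preys pin alpha+beta (A=0 in all baits)")
    )
  ), class = "apms_fit")
}

#' @export
print.apms_fit <- function(x, ...) {
  cat(sprintf("<apms_fit> channel=%s (%s), %d baits x %d preys, %d enrichment parameters\n",
              x$channel, x$family, length(x$baits), length(x$preys),
              nrow(x$pairs)))
  cat(sprintf("  %d chains x %d draws (burn-in %d), max split-R-hat %.3f (%s)\n",
              x$meta$chains, x$meta$iter, x$meta$burnin, x$meta$max_rhat,
              if (x$meta$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Tidy posterior summaries of an enrichment-model fit
#'
#' @param x An `apms_fit`.
#' @param ... Unused.
#' @return A tibble with one row per enrichment parameter `A_ij`:
#'   `bait_id`, `prey_id`, `estimate` (posterior mean), `conf.low`/
#'   `conf.high` (central 95% credible interval) and `p_enriched`
#'   (posterior tail probability from [enrichment_pvalue()]).
#' @export
tidy.apms_fit <- function(x, ...) {
  qs <- apply(x$draws$A, 2, quantile, probs = c(0.025, 0.975))
  n <- nrow(x$draws$A)
  x$pairs |>
    mutate(estimate = unname(x$estimates$A),
           conf.low = qs[1, ], conf.high = qs[2, ],
           p_enriched = (1 + colSums(x$draws$A <= 0)) / (1 + n)) |>
    select(-"column")
}

#' One-line fit summary
#'
#' @param x An `apms_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the channel, sampler dimensions, maximum
#'   split-R-hat and convergence flag.
#' @export
glance.apms_fit <- function(x, ...) {
  tibble(channel = x$channel, family = x$family,
         chains = x$meta$chains, iter = x$meta$iter, burnin = x$meta$burnin,
         n_enrichment_params = nrow(x$pairs),
         max_rhat = x$meta$max_rhat, converged = x$meta$converged)
}
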