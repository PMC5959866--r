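
# run code with a private RNG stream, leaving the caller's stream untouched
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

default_bait_names <- function(n) {
  canonical <- c("MLL-AF1p", "MLL-AF4", "MLL-AF9", "MLL-CBP",
                 "MLL-EEN", "MLL-ENL", "MLL-GAS7")
  if (n <= length(canonical)) canonical[seq_len(n)]
  else c(canonical, sprintf("bait_%02d", seq(length(canonical) + 1L, n)))
}

#' Configuration for the AP-MS simulator
#'
#' Bundles and validates the parameters of the generative model behind
#' [simulate_apms_dataset()]. The simulator is the enrichment model read
#' forward: each (run, prey) cell has a log-scale linear predictor
#' `A0_j + A_ij + alpha_i + beta_ik` (baseline abundance, bait-specific
#' enrichment, bait-level background, replicate-level background); spectral
#' counts are Poisson around `exp()` of it and the two search-engine score
#' channels are log-normal around it plus a channel offset.
#'
#' @param n_baits Number of bait pulldowns (default 7, one per MLL-fusion).
#' @param n_preys Number of distinct prey proteins.
#' @param n_replicates_per_bait Replicate pulldowns per bait.
#' @param n_control_runs Control (mock) AP-MS runs that pin the baselines.
#' @param n_true_interactors_per_bait True interactors simulated per bait
#'   (may be 0 for a fully null dataset).
#' @param conserved_fraction Fraction of each bait's true interactors drawn
#'   from a shared pool that is attached to at least five baits.
#' @param baseline_mean,baseline_sd Log-scale baseline abundance `A0_j`.
#' @param effect_mean,effect_sd Log-scale enrichment `A_ij` of true pairs;
#'   `effect_mean` should be positive (specific binding adds material).
#' @param bait_offset_sd Spread of the bait-level background term `alpha_i`.
#' @param replicate_sd Spread of the replicate-level term `beta_ik`.
#' @param score_channel_sd Log-normal noise sd of each score channel.
#' @param background_prey_ids Identifiers of ubiquitous background preys
#'   (DDX5/DDX17 analogues). Default: the first two prey ids. These get an
#'   elevated baseline and never a true effect, so they anchor the
#'   background terms when the model is refit.
#' @param background_baseline_bonus Log-scale baseline bump for background
#'   preys.
#' @param score_offsets Named additive log-scale offsets of the two score
#'   channels relative to the count channel.
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return A list of class `apms_sim_config`.
#' @export
apms_sim_config <- function(n_baits = 7,
                            n_preys = 200,
                            n_replicates_per_bait = 3,
                            n_control_runs = 3,
                            n_true_interactors_per_bait = 25,
                            conserved_fraction = 0.4,
                            baseline_mean = 1.5,
                            baseline_sd = 1,
                            effect_mean = 2.5,
                            effect_sd = 0.5,
                            bait_offset_sd = 0.3,
                            replicate_sd = 0.2,
                            score_channel_sd = 0.5,
                            background_prey_ids = NULL,
                            background_baseline_bonus = 2,
                            score_offsets = c(score_a = 2, score_b = 2.3),
                            seed = 1L) {
  cfg <- list(
    n_baits = check_count(n_baits, "n_baits"),
    n_preys = check_count(n_preys, "n_preys"),
    n_replicates_per_bait = check_count(n_replicates_per_bait,
                                        "n_replicates_per_bait"),
    n_control_runs = check_count(n_control_runs, "n_control_runs"),
    n_true_interactors_per_bait = check_count(n_true_interactors_per_bait,
                                              "n_true_interactors_per_bait",
                                              min = 0L),
    conserved_fraction = check_proportion(conserved_fraction,
                                          "conserved_fraction"),
    baseline_mean = as.numeric(baseline_mean),
    baseline_sd = check_sd(baseline_sd, "baseline_sd"),
    effect_mean = as.numeric(effect_mean),
    effect_sd = check_sd(effect_sd, "effect_sd"),
    bait_offset_sd = check_sd(bait_offset_sd, "bait_offset_sd"),
    replicate_sd = check_sd(replicate_sd, "replicate_sd"),
    score_channel_sd = check_sd(score_channel_sd, "score_channel_sd"),
    background_prey_ids = background_prey_ids,
    background_baseline_bonus = as.numeric(background_baseline_bonus),
    score_offsets = score_offsets,
    seed = check_count(seed, "seed", min = 0L)
  )
  prey_ids <- sprintf("prey_%04d", seq_len(cfg$n_preys))
  if (is.null(cfg$background_prey_ids)) {
    cfg$background_prey_ids <- prey_ids[seq_len(min(2L, cfg$n_preys))]
  }
  if (!all(cfg$background_prey_ids %in% prey_ids)) {
    abort("`background_prey_ids` must be a subset of the simulated prey ids.")
  }
  if (!all(c("score_a", "score_b") %in% names(cfg$score_offsets))) {
    abort("`score_offsets` must name score_a and score_b.")
  }
  cfg$prey_ids <- prey_ids
  cfg$bait_ids <- default_bait_names(cfg$n_baits)
  structure(cfg, class = "apms_sim_config")
}

#' Simulate a multi-channel AP-MS evidence table with known ground truth
#'
#' Draws a full bait x prey x replicate evidence table (spectral counts plus
#' two peptide-score channels) from the generative model described in
#' [apms_sim_config()], along with the ground truth needed to test
#' recovery: the nonzero enrichment effects and the conserved prey set.
#' Control runs carry no enrichment and no background offsets, so they pin
#' the per-prey baselines; background preys have elevated baselines and a
#' zero effect in every bait. Score-channel values are emitted as missing
#' wherever the spectral count is zero (no identified peptides means no
#' peptide-score sum).
#'
#' @param config An [apms_sim_config()].
#' @return A list with elements `dataset` (an `apms_dataset`, see
#'   [preprocess_apms()]) and `truth` (list with `true_effects` tibble,
#'   `conserved_set`, `conservation_threshold`, and the drawn nuisance
#'   parameters).
#' @examples
#' sim <- simulate_apms_dataset(apms_sim_config(n_preys = 40, seed = 7))
#' head(sim$dataset$observations)
#' @export
simulate_apms_dataset <- function(config) {
  if (!inherits(config, "apms_sim_config")) {
    abort("`config` must be created by apms_sim_config().")
  }
  with_seed(config$seed, {
    preys <- config$prey_ids
    baits <- config$bait_ids
    J <- config$n_preys
    bg <- config$background_prey_ids
    cons_thresh <- min(5L, config$n_baits)

    # ground-truth interactor assignment
    n_true <- config$n_true_interactors_per_bait
    n_cons <- round(config$conserved_fraction * n_true)
    free_preys <- setdiff(preys, bg)
    if (n_true > 0 && length(free_preys) <
        n_cons + config$n_baits * (n_true - n_cons)) {
      abort("not enough preys for the requested interactor structure; increase `n_preys`.")
    }
    conserved_preys <- character(0)
    assignment <- list()  # bait -> prey set
    for (b in baits) assignment[[b]] <- character(0)
    if (n_cons > 0) {
      conserved_preys <- sample(free_preys, n_cons)
      for (p in conserved_preys) {
        n_b <- sample(seq(cons_thresh, config$n_baits), 1L)
        for (b in sample(baits, n_b)) {
          assignment[[b]] <- c(assignment[[b]], p)
        }
      }
    }
    pool <- setdiff(free_preys, conserved_preys)
    for (b in baits) {
      n_need <- n_true - length(assignment[[b]])
      if (n_need > 0) {
        specific <- sample(pool, n_need)
        pool <- setdiff(pool, specific)
        assignment[[b]] <- c(assignment[[b]], specific)
      }
    }

    true_effects <- purrr::map_dfr(baits, function(b) {
      ps <- assignment[[b]]
      if (length(ps) == 0) return(tibble(bait_id = character(0),
                                         prey_id = character(0),
                                         effect = numeric(0)))
      tibble(bait_id = b, prey_id = ps,
             effect = rnorm(length(ps), config$effect_mean, config$effect_sd))
    })

    # nuisance parameters
    A0 <- rnorm(J, config$baseline_mean, config$baseline_sd)
    names(A0) <- preys
    A0[bg] <- A0[bg] + config$background_baseline_bonus
    alpha <- setNames(rnorm(config$n_baits, 0, config$bait_offset_sd), baits)

    runs <- bind_rows(
      tibble(run_id = sprintf("control_%02d", seq_len(config$n_control_runs)),
             bait_id = NA_character_, is_control = TRUE, replicate = NA_integer_),
      tidyr::expand_grid(bait_id = baits,
                         replicate = seq_len(config$n_replicates_per_bait)) |>
        mutate(run_id = sprintf("%s_rep%d", .data$bait_id, .data$replicate),
               is_control = FALSE) |>
        select("run_id", "bait_id", "is_control", "replicate")
    )
    beta <- setNames(
      ifelse(runs$is_control, 0, rnorm(nrow(runs), 0, config$replicate_sd)),
      runs$run_id
    )

    # effect matrix (baits x preys), zero unless a true pair
    A <- matrix(0, nrow = config$n_baits, ncol = J,
                dimnames = list(baits, preys))
    if (nrow(true_effects) > 0) {
      A[cbind(true_effects$bait_id, true_effects$prey_id)] <- true_effects$effect
    }

    eta <- matrix(rep(A0, each = nrow(runs)), nrow = nrow(runs),
                  dimnames = list(runs$run_id, preys))
    bait_rows <- which(!runs$is_control)
    eta[bait_rows, ] <- eta[bait_rows, ] + A[runs$bait_id[bait_rows], ] +
      alpha[runs$bait_id[bait_rows]] + beta[runs$run_id[bait_rows]]

    counts <- matrix(rpois(length(eta), exp(eta)), nrow = nrow(eta),
                     dimnames = dimnames(eta))
    draw_scores <- function(offset) {
      s <- exp(eta + offset +
                 rnorm(length(eta), 0, config$score_channel_sd))
      s[counts == 0] <- NA_real_
      s
    }
    score_a <- draw_scores(config$score_offsets[["score_a"]])
    score_b <- draw_scores(config$score_offsets[["score_b"]])

    observations <- tidyr::expand_grid(run_id = runs$run_id, prey_id = preys) |>
      left_join(runs, by = "run_id") |>
      mutate(spectral_count = counts[cbind(.data$run_id, .data$prey_id)],
             score_a = score_a[cbind(.data$run_id, .data$prey_id)],
             score_b = score_b[cbind(.data$run_id, .data$prey_id)]) |>
      select("bait_id", "run_id", "is_control", "prey_id",
             "spectral_count", "score_a", "score_b")

    n_baits_per_prey <- table(unlist(lapply(assignment, unique)))
    conserved_set <- sort(names(n_baits_per_prey)[n_baits_per_prey >= cons_thresh])

    dataset <- new_apms_dataset(observations, runs,
                                background_prey_ids = bg,
                                contaminant_ids = character(0))
    truth <- list(
      true_effects = arrange(true_effects, .data$bait_id, .data$prey_id),
      conserved_set = conserved_set,
      conservation_threshold = cons_thresh,
      A0 = A0, alpha = alpha, beta = beta
    )
    list(dataset = dataset, truth = truth)
  })
}
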