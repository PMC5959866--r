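
#' Posterior tail probability that a prey is enriched in a bait
#'
#' The evidence against specific binding is summarised as the posterior
#' probability that the enrichment is non-positive, estimated from the
#' draws with the add-one correction `p = (1 + #{draws <= 0}) / (1 + n)`,
#' which keeps p strictly inside (0, 1] even when every draw is positive.
#'
#' @param fit An `apms_fit`.
#' @param bait,prey Identifiers of the pair.
#' @return A single p-value in (0, 1].
#' @export
enrichment_pvalue <- function(fit, bait, prey) {
  stopifnot(inherits(fit, "apms_fit"))
  col <- fit$pairs$column[fit$pairs$bait_id == bait & fit$pairs$prey_id == prey]
  if (length(col) != 1L) {
    abort(sprintf("pair (%s, %s) has no enrichment parameter in this fit.",
                  bait, prey))
  }
  d <- fit$draws$A[, col]
  (1 + sum(d <= 0)) / (1 + length(d))
}

# vectorized version over all pairs of a fit
all_enrichment_pvalues <- function(fit) {
  n <- nrow(fit$draws$A)
  fit$pairs |>
    mutate(p = (1 + colSums(fit$draws$A <= 0)) / (1 + n)) |>
    select("bait_id", "prey_id", "p")
}

#' Combine per-channel p-values by Fisher's method
#'
#' `X = -2 * sum(log(p))` is referred to the upper tail of a chi-square
#' distribution with `2 * length(p)` degrees of freedom. Channels with
#' missing evidence are simply omitted by the caller, so the degrees of
#' freedom adjust to the evidence actually available.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @examples
#' fisher_combine(c(0.05, 0.05, 0.05))
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0) abort("`p_values` must be nonempty.")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("all p-values must lie in (0, 1].")
  }
  x <- -2 * sum(log(p_values))
  pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Score all bait-prey pairs across the three MS evidence channels
#'
#' Fits the enrichment model independently to the spectral-count channel
#' (Poisson) and the two peptide-score channels (log-normal), converts each
#' fit to per-pair posterior tail p-values, combines them with Fisher's
#' method (degrees of freedom adjust when a channel has no data for a
#' pair), and ranks pairs within each bait by the combined p-value, ties
#' broken by prey identifier.
#'
#' @param dataset An `apms_dataset`.
#' @param inference An [inference_config()]; channel c is fitted with seed
#'   `seed + 100 * c` so the three fits use distinct streams.
#' @param channels Channels to fit (default all three).
#' @return A tibble of class `apms_scores` with columns `bait_id`,
#'   `prey_id`, `p_counts`, `p_score_a`, `p_score_b`, `p_combined`,
#'   `rank_within_bait`, `selected` (all `FALSE`; see
#'   [select_top_interactions()]). Fit summaries are attached as the
#'   `"fits"` attribute (a list of [glance.apms_fit()] rows).
#' @export
score_interactions <- function(dataset, inference = inference_config(),
                               channels = c("counts", "score_a", "score_b")) {
  fits <- lapply(seq_along(channels), function(i) {
    inf_i <- inference
    inf_i$seed <- inference$seed + 100L * i
    fit_enrichment_model(dataset, channels[i], inf_i)
  })
  names(fits) <- channels

  tabs <- purrr::imap(fits, function(f, ch) {
    rename(all_enrichment_pvalues(f), !!paste0("p_", ch) := "p")
  })
  scores <- purrr::reduce(tabs, dplyr::full_join, by = c("bait_id", "prey_id"))
  pcols <- paste0("p_", channels)
  pm <- as.matrix(scores[, pcols])
  all_missing <- rowSums(!is.na(pm)) == 0
  if (any(all_missing)) {
    inform(sprintf("dropping %d pairs with no evidence in any channel",
                   sum(all_missing)))
    scores <- scores[!all_missing, ]
    pm <- pm[!all_missing, , drop = FALSE]
  }
  scores$p_combined <- apply(pm, 1, function(p) fisher_combine(p[!is.na(p)]))
  scores <- scores |>
    group_by(.data$bait_id) |>
    arrange(.data$p_combined, .data$prey_id, .by_group = TRUE) |>
    mutate(rank_within_bait = row_number()) |>
    ungroup() |>
    mutate(selected = FALSE)
  attr(scores, "fits") <- lapply(fits, glance)
  class(scores) <- c("apms_scores", class(scores))
  scores
}

#' Flag the k most significant interactions per bait
#'
#' Retains, per bait, the `k` pairs with the smallest combined p-value
#' (all pairs when a bait has fewer than `k`), mirroring the
#' top-300-per-bait cut that defines the high-confidence network.
#'
#' @param table An `apms_scores` tibble (or any table with `bait_id`,
#'   `p_combined`, `rank_within_bait`).
#' @param k Number of interactions to keep per bait (default 300).
#' @return The table with its `selected` column set.
#' @export
select_top_interactions <- function(table, k = 300) {
  k <- check_count(k, "k")
  if (!all(c("bait_id", "rank_within_bait") %in% names(table))) {
    abort("`table` must contain bait_id and rank_within_bait columns.")
  }
  mutate(table, selected = .data$rank_within_bait <= k)
}

#' Conserved interactors shared by several baits
#'
#' Returns the preys present in at least `min_baits` of the baits'
#' selected interaction sets, minus a manual exclusion list (frequent
#' contaminants, proteins absent from the system under study).
#'
#' @param selected Either an `apms_scores` table with its `selected`
#'   column set, or a named list mapping bait to a character vector of
#'   selected preys.
#' @param min_baits Conservation threshold (default 5, as in a
#'   seven-bait design).
#' @param exclusion_list Prey identifiers to drop from the result.
#' @return Sorted character vector of conserved prey identifiers.
#' @export
conserved_interactors <- function(selected, min_baits = 5,
                                  exclusion_list = character(0)) {
  min_baits <- check_count(min_baits, "min_baits")
  if (is.data.frame(selected)) {
    if (!"selected" %in% names(selected)) {
      abort("`selected` table must carry a selected column; run select_top_interactions() first.")
    }
    sets <- selected |>
      filter(.data$selected) |>
      distinct(.data$bait_id, .data$prey_id)
  } else {
    if (min_baits > length(selected)) {
      abort("`min_baits` exceeds the number of baits.")
    }
    sets <- purrr::imap_dfr(selected, ~ tibble(bait_id = .y, prey_id = .x)) |>
      distinct(.data$bait_id, .data$prey_id)
  }
  shared <- sets |>
    count(.data$prey_id) |>
    filter(.data$n >= min_baits) |>
    pull("prey_id")
  sort(setdiff(shared, exclusion_list))
}
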