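
# constructor + invariant checks for the AP-MS evidence container
new_apms_dataset <- function(observations, runs, background_prey_ids,
                             contaminant_ids = character(0)) {
  observations <- as_tibble(observations)
  runs <- as_tibble(runs)
  validate_apms_observations(observations, runs)
  structure(
    list(observations = observations,
         runs = runs,
         background_prey_ids = background_prey_ids,
         contaminant_ids = contaminant_ids),
    class = "apms_dataset"
  )
}

validate_apms_observations <- function(obs, runs) {
  required <- c("bait_id", "run_id", "is_control", "prey_id",
                "spectral_count", "score_a", "score_b")
  missing_cols <- setdiff(required, names(obs))
  if (length(missing_cols) > 0) {
    abort(paste0("AP-MS table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  bad <- which(is.na(obs$spectral_count) | obs$spectral_count < 0 |
                 obs$spectral_count != round(obs$spectral_count))
  if (length(bad) > 0) {
    abort(sprintf("row %d: spectral_count must be a non-negative integer (got %s)",
                  bad[1], obs$spectral_count[bad[1]]))
  }
  for (ch in c("score_a", "score_b")) {
    bad <- which(obs$spectral_count == 0 & !is.na(obs[[ch]]))
    if (length(bad) > 0) {
      abort(sprintf("row %d: %s present although spectral_count is 0",
                    bad[1], ch))
    }
    bad <- which(!is.na(obs[[ch]]) & obs[[ch]] <= 0)
    if (length(bad) > 0) {
      abort(sprintf("row %d: %s must be positive when present", bad[1], ch))
    }
  }
  orphan <- setdiff(unique(obs$run_id), runs$run_id)
  if (length(orphan) > 0) {
    abort(paste0("observations refer to unknown run ids: ",
                 paste(head(orphan, 3), collapse = ", ")))
  }
  invisible(obs)
}

#' Assemble and clean a raw AP-MS evidence table
#'
#' Removes known mass-spectrometry contaminants (trypsin, keratins, ...)
#' and validates the table against the container invariants: integer
#' non-negative spectral counts, positive score values, and score channels
#' missing exactly where the spectral count is zero.
#'
#' @param raw_table Data frame with columns `bait_id`, `run_id`,
#'   `is_control`, `prey_id`, `spectral_count`, `score_a`, `score_b`
#'   (the TSV schema written by [simulate_apms_dataset()]).
#' @param contaminant_ids Character vector of prey identifiers to drop.
#' @param background_prey_ids Identifiers of ubiquitous background preys
#'   used to anchor the model's background terms (DDX5/DDX17 analogues).
#' @return An `apms_dataset` object.
#' @examples
#' sim <- simulate_apms_dataset(apms_sim_config(n_preys = 30, seed = 1))
#' ds <- preprocess_apms(sim$dataset$observations,
#'                       contaminant_ids = "prey_0005",
#'                       background_prey_ids = sim$dataset$background_prey_ids)
#' @export
preprocess_apms <- function(raw_table, contaminant_ids = character(0),
                            background_prey_ids = character(0)) {
  raw_table <- as_tibble(raw_table)
  required <- c("bait_id", "run_id", "is_control", "prey_id",
                "spectral_count", "score_a", "score_b")
  if (!all(required %in% names(raw_table))) {
    abort(paste0("AP-MS table is missing columns: ",
                 paste(setdiff(required, names(raw_table)), collapse = ", ")))
  }
  obs <- filter(raw_table, !.data$prey_id %in% contaminant_ids)
  runs <- distinct(obs, .data$run_id, .data$bait_id, .data$is_control)
  if (!"replicate" %in% names(obs)) {
    runs <- runs |>
      group_by(.data$bait_id) |>
      mutate(replicate = ifelse(.data$is_control, NA_integer_,
                                row_number())) |>
      ungroup()
  } else {
    runs <- distinct(obs, .data$run_id, .data$bait_id, .data$is_control,
                     .data$replicate)
  }
  new_apms_dataset(obs, runs,
                   background_prey_ids = intersect(background_prey_ids,
                                                   unique(obs$prey_id)),
                   contaminant_ids = contaminant_ids)
}

#' @export
print.apms_dataset <- function(x, ...) {
  cat("<apms_dataset>\n")
  cat(sprintf("  %d observations, %d runs (%d control), %d baits, %d preys\n",
              nrow(x$observations), nrow(x$runs), sum(x$runs$is_control),
              length(unique(stats::na.omit(x$runs$bait_id))),
              length(unique(x$observations$prey_id))))
  cat(sprintf("  background preys: %s\n",
              paste(x$background_prey_ids, collapse = ", ")))
  invisible(x)
}
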