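
#' Depletion of a trajectory relative to its baseline measurement
#'
#' GFP percentages are normalized to the initial measurement (after 2
#' days of induction by default): `ratio(day) = gfp(day) / gfp(baseline)`.
#'
#' @param trajectory Data frame with columns `timepoint_day` and
#'   `gfp_percent` (one gene in one cell line).
#' @param baseline_day Baseline day; must be present in the trajectory.
#' @return Tibble with `timepoint_day` and `ratio` (1 at the baseline).
#' @export
relative_depletion <- function(trajectory, baseline_day = 2) {
  trajectory <- as_tibble(trajectory)
  base <- trajectory$gfp_percent[trajectory$timepoint_day == baseline_day]
  if (length(base) != 1L) {
    abort(sprintf("baseline day %s absent (or duplicated) in trajectory.",
                  baseline_day))
  }
  if (base == 0) abort("baseline GFP percentage is zero; ratio undefined.")
  tibble(timepoint_day = trajectory$timepoint_day,
         ratio = trajectory$gfp_percent / base)
}

#' Scale a depletion value between the control anchors
#'
#' Linearly rescales a gene's final depletion ratio so the negative
#' control maps to 0 and the strongly depleting positive control maps to
#' 1: `scaled = (neg - gene) / (neg - pos)`. Values outside \[0, 1\]
#' indicate depletion weaker than the negative or stronger than the
#' positive control.
#'
#' @param gene_final_ratio Final/baseline GFP ratio(s) of the gene(s).
#' @param neg_ctrl_final_ratio,pos_ctrl_final_ratio Final ratios of the
#'   negative and positive controls (must differ).
#' @return Scaled depletion score(s).
#' @export
control_scaled_score <- function(gene_final_ratio, neg_ctrl_final_ratio,
                                 pos_ctrl_final_ratio) {
  if (any(neg_ctrl_final_ratio == pos_ctrl_final_ratio)) {
    abort("negative and positive control ratios coincide; scaling is degenerate.")
  }
  (neg_ctrl_final_ratio - gene_final_ratio) /
    (neg_ctrl_final_ratio - pos_ctrl_final_ratio)
}

#' z-scores of screen depletion scores
#'
#' Standardizes scores over all screened genes (controls are excluded by
#' the caller) using the population standard deviation. Because the
#' scaled score grows with depletion, stronger depletion maps to a
#' positive z-score.
#'
#' @param scaled_scores Named numeric vector, gene -> scaled depletion.
#' @return Named numeric vector of z-scores.
#' @export
depletion_zscore <- function(scaled_scores) {
  if (length(scaled_scores) < 3) abort("need at least 3 genes for z-scores.")
  mu <- mean(scaled_scores)
  sigma <- sqrt(mean((scaled_scores - mu)^2))
  if (sigma == 0) abort("scores have zero spread; z-scores undefined.")
  (scaled_scores - mu) / sigma
}

#' Combined essentiality score across published screens
#'
#' Sums binary essential/non-essential calls per gene across datasets; a
#' gene is flagged essential when it scores in at least `threshold` of
#' the `n_datasets` cell lines (default 10 of 18).
#'
#' @param binary_matrix Numeric gene x dataset matrix of 0/1 calls with
#'   gene identifiers as row names.
#' @param threshold Minimum combined score for the essential flag.
#' @param n_datasets Expected number of dataset columns.
#' @return Tibble with `gene_id`, `score`, `essential`.
#' @export
essentiality_score <- function(binary_matrix, threshold = 10, n_datasets = 18) {
  binary_matrix <- as.matrix(binary_matrix)
  if (ncol(binary_matrix) != n_datasets) {
    abort(sprintf("expected %d dataset columns, got %d.", n_datasets,
                  ncol(binary_matrix)))
  }
  if (!all(binary_matrix %in% c(0, 1))) {
    abort("essentiality calls must be 0 or 1.")
  }
  score <- rowSums(binary_matrix)
  tibble(gene_id = rownames(binary_matrix) %||%
           as.character(seq_len(nrow(binary_matrix))),
         score = as.integer(score),
         essential = score >= threshold)
}

#' Fusion-context selectivity of depletion scores
#'
#' Averages scaled depletion per gene within MLL-fusion-context and
#' wild-type cell lines and reports the difference
#' `delta = mean_fusion - mean_wt`; positive values flag fusion-selective
#' dependencies. A difference (not a ratio) is used because wild-type
#' depletion of neutral genes is near zero.
#'
#' @param scores Tibble with columns `gene_id`, `context`
#'   (`"fusion"`/`"wildtype"`), `scaled_score` — e.g. from
#'   [screen_score()].
#' @return Tibble with `gene_id`, `mean_fusion`, `mean_wt`, `delta`.
#'   Genes lacking one context are skipped with a message.
#' @export
selectivity <- function(scores) {
  wide <- scores |>
    group_by(.data$gene_id, .data$context) |>
    summarise(m = mean(.data$scaled_score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "context", values_from = "m")
  for (ctx in c("fusion", "wildtype")) {
    if (!ctx %in% names(wide)) wide[[ctx]] <- NA_real_
  }
  skipped <- wide$gene_id[is.na(wide$fusion) | is.na(wide$wildtype)]
  if (length(skipped) > 0) {
    inform(sprintf("skipping %d genes lacking one screening context (e.g. %s)",
                   length(skipped), skipped[1]))
  }
  wide |>
    filter(!is.na(.data$fusion), !is.na(.data$wildtype)) |>
    mutate(mean_fusion = .data$fusion, mean_wt = .data$wildtype,
           delta = .data$mean_fusion - .data$mean_wt) |>
    select("gene_id", "mean_fusion", "mean_wt", "delta")
}

#' Comet-assay tail moment
#'
#' DNA-damage metric: the average distance migrated by the DNA multiplied
#' by the fraction of DNA in the comet tail.
#'
#' @param mean_distance Mean migration distance (>= 0).
#' @param tail_dna_fraction Fraction of DNA in the tail, in \[0, 1\].
#' @return The tail moment, `mean_distance * tail_dna_fraction`.
#' @export
comet_tail_moment <- function(mean_distance, tail_dna_fraction) {
  if (any(mean_distance < 0)) abort("`mean_distance` must be non-negative.")
  if (any(tail_dna_fraction < 0 | tail_dna_fraction > 1)) {
    abort("`tail_dna_fraction` must lie in [0, 1].")
  }
  mean_distance * tail_dna_fraction
}

#' Score a whole screen table against its control anchors
#'
#' For every (gene, cell line), computes the final/baseline GFP ratio and
#' rescales it between that cell line's negative- and positive-control
#' ratios (see [control_scaled_score()]).
#'
#' @param trajectories Tibble with `gene_id`, `cell_line`, `context`,
#'   `timepoint_day`, `gfp_percent` (schema of [simulate_screen()]).
#' @param negative_control,positive_control Identifiers of the control
#'   entries within `gene_id`.
#' @param baseline_day Baseline day (default 2).
#' @param final_day Day at which depletion is summarized; default the
#'   last day shared by all trajectories (day 14 in the default design).
#' @return Tibble with `gene_id`, `cell_line`, `context`, `final_ratio`,
#'   `scaled_score` for all non-control genes.
#' @export
screen_score <- function(trajectories,
                         negative_control = "shRen.713",
                         positive_control = "shMyb.670",
                         baseline_day = 2, final_day = NULL) {
  trajectories <- as_tibble(trajectories)
  final_day <- final_day %||% max(trajectories$timepoint_day)
  ratios <- trajectories |>
    filter(.data$timepoint_day %in% c(baseline_day, final_day)) |>
    group_by(.data$gene_id, .data$cell_line, .data$context) |>
    summarise(
      final_ratio = {
        base <- .data$gfp_percent[.data$timepoint_day == baseline_day]
        fin <- .data$gfp_percent[.data$timepoint_day == final_day]
        if (length(base) != 1 || length(fin) != 1) {
          abort(sprintf("gene %s in %s lacks baseline or final measurement.",
                        .data$gene_id[1], .data$cell_line[1]))
        }
        if (base == 0) abort(sprintf("gene %s in %s: baseline GFP is zero.",
                                     .data$gene_id[1], .data$cell_line[1]))
        fin / base
      },
      .groups = "drop"
    )
  ctrl <- ratios |>
    filter(.data$gene_id %in% c(negative_control, positive_control)) |>
    select("gene_id", "cell_line", "final_ratio") |>
    tidyr::pivot_wider(names_from = "gene_id", values_from = "final_ratio")
  if (!all(c(negative_control, positive_control) %in% names(ctrl))) {
    abort("both control entries must be present in every cell line.")
  }
  ratios |>
    filter(!.data$gene_id %in% c(negative_control, positive_control)) |>
    left_join(ctrl, by = "cell_line") |>
    mutate(scaled_score = control_scaled_score(
      .data$final_ratio,
      .data[[negative_control]],
      .data[[positive_control]]
    )) |>
    select("gene_id", "cell_line", "context", "final_ratio", "scaled_score")
}
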