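
#' Simulate a competitive-proliferation shRNA screen
#'
#' Emulates a FACS-based negative-selection screen: reporter-marked
#' knockdown cells are mixed 50:50 with control cells, and the percentage
#' of GFP-positive cells is followed over two weeks. Trajectories start
#' near 50% and decay multiplicatively per measurement interval for
#' depleted genes (truncated to \[0, 100\]): essential genes deplete in
#' every cell line, fusion-selective genes only in MLL-fusion-context
#' lines, neutral genes stay flat. A flat negative-control entry
#' (`shRen.713`) and a strongly depleting positive control (`shMyb.670`)
#' anchor downstream scaling.
#'
#' @param n_genes Number of screened genes (default 128).
#' @param timepoint_days Measurement days; the first is the baseline
#'   (default days 2, 5, 8, 11, 14).
#' @param n_celllines_fusion,n_celllines_wt Number of MLL-fusion-context
#'   and wild-type cell lines (defaults 1 and 2: MOLM-13 vs K562/HL-60).
#' @param essential_set,selective_set Gene identifiers; default: the first
#'   35% of genes essential, the next 8% fusion-selective.
#' @param noise_sd Log-scale multiplicative noise per interval (>= 0).
#' @param depletion_rate Per-interval GFP% retention factor of depleted
#'   genes (default 0.75).
#' @param pos_control_rate Per-interval retention of the positive control.
#' @param start_gfp Baseline GFP percentage (default 50, the 50:50 mix).
#' @param seed Integer seed.
#' @return List with `trajectories` (tibble: `gene_id`, `cell_line`,
#'   `context`, `timepoint_day`, `gfp_percent`), `controls` (list with
#'   `negative`, `positive`), and `truth` (essential/selective/neutral
#'   gene sets).
#' @export
simulate_screen <- function(n_genes = 128,
                            timepoint_days = c(2, 5, 8, 11, 14),
                            n_celllines_fusion = 1,
                            n_celllines_wt = 2,
                            essential_set = NULL,
                            selective_set = NULL,
                            noise_sd = 0.05,
                            depletion_rate = 0.75,
                            pos_control_rate = 0.75,
                            start_gfp = 50,
                            seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  noise_sd <- check_sd(noise_sd, "noise_sd")
  if (length(timepoint_days) < 2) abort("need at least two timepoints.")
  genes <- sprintf("gene_%03d", seq_len(n_genes))
  if (is.null(essential_set)) {
    essential_set <- genes[seq_len(round(0.35 * n_genes))]
  }
  if (is.null(selective_set)) {
    selective_set <- setdiff(genes, essential_set)[
      seq_len(max(1L, round(0.08 * n_genes)))]
  }
  if (!all(c(essential_set, selective_set) %in% genes)) {
    abort("essential_set and selective_set must be subsets of the gene set.")
  }
  if (length(intersect(essential_set, selective_set)) > 0) {
    abort("a gene cannot be both ubiquitously essential and fusion-selective.")
  }
  fusion_lines <- c("MOLM-13", sprintf("fusion_%d", seq_len(n_celllines_fusion)))[
    seq_len(n_celllines_fusion)]
  wt_lines <- c("K562", "HL-60", sprintf("wt_%d", seq_len(n_celllines_wt)))[
    seq_len(n_celllines_wt)]
  neg <- "shRen.713"
  pos <- "shMyb.670"

  lines <- tibble(cell_line = c(fusion_lines, wt_lines),
                  context = c(rep("fusion", length(fusion_lines)),
                              rep("wildtype", length(wt_lines))))
  entries <- c(genes, neg, pos)

  with_seed(seed, {
    traj <- tidyr::expand_grid(gene_id = entries, lines) |>
      mutate(rate = dplyr::case_when(
        .data$gene_id == pos ~ pos_control_rate,
        .data$gene_id == neg ~ 1,
        .data$gene_id %in% essential_set ~ depletion_rate,
        .data$gene_id %in% selective_set & .data$context == "fusion" ~ depletion_rate,
        TRUE ~ 1
      ))
    n_steps <- length(timepoint_days) - 1L
    gfp <- matrix(NA_real_, nrow(traj), length(timepoint_days))
    gfp[, 1] <- start_gfp
    for (s in seq_len(n_steps)) {
      noise <- if (noise_sd > 0) exp(rnorm(nrow(traj), 0, noise_sd)) else 1
      gfp[, s + 1] <- pmin(100, pmax(0, gfp[, s] * traj$rate * noise))
    }
    trajectories <- traj |>
      select(-"rate") |>
      mutate(.row = row_number()) |>
      tidyr::expand_grid(tp = seq_along(timepoint_days)) |>
      mutate(timepoint_day = timepoint_days[.data$tp],
             gfp_percent = gfp[cbind(.data$.row, .data$tp)]) |>
      select("gene_id", "cell_line", "context", "timepoint_day",
             "gfp_percent") |>
      arrange(.data$gene_id, .data$cell_line, .data$timepoint_day)
    list(
      trajectories = trajectories,
      controls = list(negative = neg, positive = pos),
      truth = list(
        essential_set = essential_set,
        selective_set = selective_set,
        neutral_set = setdiff(genes, c(essential_set, selective_set))
      )
    )
  })
}
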