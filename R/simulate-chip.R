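
#' Simulate per-gene dual-histone-mark ChIP counts with spike-in
#'
#' Emulates a spike-in-normalized (ChIP-Rx style) per-gene count table for
#' two histone marks (H3K36me3, H3K79me2) plus a shared input library.
#' Each gene is first assigned a high/low status per mark: with the stated
#' probability a gene is jointly high for both marks (0.76 for designated
#' MLL-target genes, 0.42 for the rest, matching the emulated signature);
#' otherwise one of the remaining status combinations is drawn uniformly.
#' "High" genes then receive IP counts above their input on the
#' spike-in-normalized scale (fold `fold_high`), "low" genes at or below
#' input (fold `fold_low`); raw counts are the normalized intensities
#' divided by each library's spike-in factor, so sequencing-depth
#' differences are built in and undone again by [classify_signature()].
#'
#' @param n_genes Number of genes.
#' @param target_set Gene identifiers of the MLL-target label set;
#'   default the first 10% of genes.
#' @param p_dual_high_target,p_dual_high_nontarget Probability of the
#'   joint high/high signature for target and non-target genes.
#' @param spikein_totals Named positive totals of exogenous spike-in reads
#'   per library; must name both marks and `input`.
#' @param base_input Median normalized input intensity per gene.
#' @param gene_dispersion Log-normal spread of per-gene input intensity.
#' @param fold_high,fold_low IP/input fold of high- and low-status genes
#'   (`fold_high > 1 >= fold_low`).
#' @param noise `"poisson"` for count noise, `"none"` for deterministic
#'   rounded counts (classification then recovers the assigned statuses
#'   exactly).
#' @param seed Integer seed.
#' @return List with `table` (a `gene_mark_table`: `counts` tibble with
#'   `gene_id`, `mark`, `ip_count`, `input_count`; `spikein` named totals;
#'   `gene_sets$MLL_target`) and `truth` (tibble of assigned statuses and
#'   the `dual_high` flag).
#' @export
simulate_chip_counts <- function(n_genes = 5000,
                                 target_set = NULL,
                                 p_dual_high_target = 0.76,
                                 p_dual_high_nontarget = 0.42,
                                 spikein_totals = c(H3K36me3 = 1e6,
                                                    H3K79me2 = 8e5,
                                                    input = 1.2e6),
                                 base_input = 100,
                                 gene_dispersion = 0.5,
                                 fold_high = 2,
                                 fold_low = 0.5,
                                 noise = c("poisson", "none"),
                                 seed = 1L) {
  n_genes <- check_count(n_genes, "n_genes")
  p_dual_high_target <- check_proportion(p_dual_high_target,
                                         "p_dual_high_target")
  p_dual_high_nontarget <- check_proportion(p_dual_high_nontarget,
                                            "p_dual_high_nontarget")
  noise <- match.arg(noise)
  marks <- setdiff(names(spikein_totals), "input")
  if (length(marks) != 2 || !"input" %in% names(spikein_totals)) {
    abort("`spikein_totals` must name two marks and `input`.")
  }
  if (any(spikein_totals <= 0)) abort("spike-in totals must be positive.")
  if (fold_high <= 1 || fold_low > 1) {
    abort("need fold_high > 1 and fold_low <= 1 for the status contract.")
  }
  genes <- sprintf("gene_%05d", seq_len(n_genes))
  target_set <- target_set %||% genes[seq_len(max(1L, round(0.1 * n_genes)))]
  if (!all(target_set %in% genes)) {
    abort("`target_set` must be a subset of the simulated gene ids.")
  }

  with_seed(seed, {
    is_target <- genes %in% target_set
    p_dual <- ifelse(is_target, p_dual_high_target, p_dual_high_nontarget)
    dual <- rbinom(n_genes, 1, p_dual) == 1
    other <- sample(c("hl", "lh", "ll"), n_genes, replace = TRUE)
    status1 <- ifelse(dual, "high", ifelse(other == "hl", "high", "low"))
    status2 <- ifelse(dual, "high", ifelse(other == "lh", "high", "low"))

    lambda <- base_input * exp(rnorm(n_genes, 0, gene_dispersion))
    factors <- min(spikein_totals) / spikein_totals
    draw <- function(intensity, library) {
      raw <- intensity / factors[[library]]
      if (noise == "poisson") rpois(length(raw), raw) else round(raw)
    }
    input_raw <- draw(lambda, "input")
    status <- cbind(status1, status2)
    counts <- purrr::map_dfr(seq_along(marks), function(mi) {
      fold <- ifelse(status[, mi] == "high", fold_high, fold_low)
      tibble(gene_id = genes, mark = marks[mi],
             ip_count = draw(lambda * fold, marks[mi]),
             input_count = input_raw)
    }) |>
      arrange(.data$gene_id, .data$mark)

    truth <- tibble(gene_id = genes, is_target = is_target,
                    !!marks[1] := status1, !!marks[2] := status2,
                    dual_high = status1 == "high" & status2 == "high")
    list(
      table = new_gene_mark_table(counts, spikein_totals,
                                  gene_sets = list(MLL_target = target_set)),
      truth = truth
    )
  })
}

new_gene_mark_table <- function(counts, spikein_totals, gene_sets = list()) {
  counts <- as_tibble(counts)
  req <- c("gene_id", "mark", "ip_count", "input_count")
  if (!all(req %in% names(counts))) {
    abort(paste0("counts must have columns: ", paste(req, collapse = ", ")))
  }
  if (any(counts$ip_count < 0) || any(counts$input_count < 0)) {
    abort("counts must be non-negative.")
  }
  marks <- unique(counts$mark)
  needed <- c(marks, "input")
  if (!all(needed %in% names(spikein_totals))) {
    abort("spikein_totals must cover every mark library and `input`.")
  }
  if (any(spikein_totals <= 0)) abort("spike-in totals must be positive.")
  structure(list(counts = counts,
                 spikein = spikein_totals[needed],
                 gene_sets = gene_sets),
            class = "gene_mark_table")
}

#' @export
print.gene_mark_table <- function(x, ...) {
  cat(sprintf("<gene_mark_table> %d genes x %d marks; spike-in libraries: %s\n",
              length(unique(x$counts$gene_id)),
              length(unique(x$counts$mark)),
              paste(names(x$spikein), collapse = ", ")))
  invisible(x)
}
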