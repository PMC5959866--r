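
#' Spike-in normalization factors
#'
#' Converts exogenous (Drosophila) spike-in read totals into per-library
#' scaling factors `factor_s = reference / total_s`, with the smallest
#' total as the reference so every factor is at most 1 (downscaling only).
#' The library with the most spike-in reads — i.e. the most efficient
#' recovery — receives the smallest factor.
#'
#' @param spikein_totals Named numeric vector of positive spike-in totals.
#' @return Named numeric factors.
#' @export
spikein_factors <- function(spikein_totals) {
  if (any(is.na(spikein_totals)) || any(spikein_totals <= 0)) {
    abort("spike-in totals must be positive.")
  }
  min(spikein_totals) / spikein_totals
}

#' Spike-in scale ChIP counts and subtract input
#'
#' Applies each library's spike-in factor and subtracts the scaled input
#' from the scaled IP signal per gene and mark, flooring at zero:
#' `adjusted = max(0, ip * factor_mark - input * factor_input)`.
#'
#' @param table A `gene_mark_table` (see [simulate_chip_counts()]) or a
#'   tibble with `gene_id`, `mark`, `ip_count`, `input_count`.
#' @param factors Named per-library factors covering every mark and
#'   `input`; computed from the table's spike-in totals when omitted.
#' @return Tibble with `gene_id`, `mark`, `scaled_ip`, `scaled_input`,
#'   `adjusted_signal`.
#' @export
normalize_and_subtract <- function(table, factors = NULL) {
  counts <- if (inherits(table, "gene_mark_table")) table$counts else as_tibble(table)
  if (is.null(factors)) {
    if (!inherits(table, "gene_mark_table")) {
      abort("`factors` must be given when `table` carries no spike-in totals.")
    }
    factors <- spikein_factors(table$spikein)
  }
  needed <- c(unique(counts$mark), "input")
  if (!all(needed %in% names(factors))) {
    abort(paste0("missing factors for: ",
                 paste(setdiff(needed, names(factors)), collapse = ", ")))
  }
  counts |>
    mutate(scaled_ip = .data$ip_count * unname(factors[.data$mark]),
           scaled_input = .data$input_count * factors[["input"]],
           adjusted_signal = pmax(0, .data$scaled_ip - .data$scaled_input)) |>
    select("gene_id", "mark", "scaled_ip", "scaled_input", "adjusted_signal")
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes between-sample correction factors from a gene x sample count
#' matrix: per sample, the precision-weighted mean of log2 ratios against
#' the reference (first) column, after trimming the most extreme 30% of
#' M-values (log-ratios) and 5% of A-values (log-abundances) on each
#' side; genes with a zero in either compared column are excluded
#' pairwise. The per-sample scales are inverted and rescaled so the
#' factors multiply to 1 (geometric-mean normalization). Unlike
#' library-size-relative TMM implementations, the factor here folds the
#' depth difference in: doubling a column elementwise halves its factor.
#'
#' @param count_matrix Numeric gene x sample matrix (>= 2 columns).
#' @param trim_M,trim_A Two-sided trim fractions for M and A (defaults
#'   0.30 and 0.05, the method's canonical values).
#' @return Named per-sample factors multiplying to 1.
#' @export
tmm_factors <- function(count_matrix, trim_M = 0.30, trim_A = 0.05) {
  count_matrix <- as.matrix(count_matrix)
  if (ncol(count_matrix) < 2) abort("need at least 2 samples.")
  if (any(colSums(count_matrix) == 0)) {
    abort("a sample with all-zero counts cannot be normalized.")
  }
  if (is.null(colnames(count_matrix))) {
    colnames(count_matrix) <- paste0("sample_", seq_len(ncol(count_matrix)))
  }
  N <- colSums(count_matrix)
  ref <- 1L
  log_scale <- vapply(seq_len(ncol(count_matrix)), function(s) {
    if (s == ref) return(0)
    y_s <- count_matrix[, s]
    y_r <- count_matrix[, ref]
    keep <- y_s > 0 & y_r > 0
    y_s <- y_s[keep]; y_r <- y_r[keep]
    M <- log2(y_s / y_r)
    A <- 0.5 * log2(y_s * y_r)
    in_M <- M >= quantile(M, trim_M) & M <= quantile(M, 1 - trim_M)
    in_A <- A >= quantile(A, trim_A) & A <= quantile(A, 1 - trim_A)
    w <- 1 / ((N[s] - y_s) / (N[s] * y_s) + (N[ref] - y_r) / (N[ref] * y_r))
    use <- in_M & in_A
    sum(w[use] * M[use]) / sum(w[use])
  }, numeric(1))
  f <- 2^(-log_scale)
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(count_matrix))
}

#' Classify a gene's mark status against its input
#'
#' A gene is `"high"` for a mark when its (spike-in-scaled) IP count
#' strictly exceeds its scaled input count, `"low"` otherwise — equality
#' does not exceed the input and is therefore low.
#'
#' @param ip_count,input_count Non-negative scaled counts (vectorized).
#' @return Character vector of `"high"`/`"low"`.
#' @export
classify_high_low <- function(ip_count, input_count) {
  ifelse(ip_count > input_count, "high", "low")
}

#' Call the dual histone-mark signature for every gene
#'
#' Spike-in scales all libraries, classifies each (gene, mark) as
#' high/low with [classify_high_low()], and flags genes that are high for
#' both designated marks as carrying the dual signature.
#'
#' @param table A `gene_mark_table`.
#' @param marks The two marks forming the signature; default the two
#'   marks present in the table.
#' @return A tibble of class `signature_call`: `gene_id`, one status
#'   column per mark, and `dual_high`.
#' @export
classify_signature <- function(table, marks = NULL) {
  stopifnot(inherits(table, "gene_mark_table"))
  marks <- marks %||% sort(unique(table$counts$mark))
  if (length(marks) != 2) abort("a dual signature needs exactly two marks.")
  adj <- normalize_and_subtract(table)
  calls <- adj |>
    filter(.data$mark %in% marks) |>
    mutate(status = classify_high_low(.data$scaled_ip, .data$scaled_input)) |>
    select("gene_id", "mark", "status") |>
    tidyr::pivot_wider(names_from = "mark", values_from = "status")
  calls$dual_high <- calls[[marks[1]]] == "high" & calls[[marks[2]]] == "high"
  class(calls) <- c("signature_call", class(calls))
  calls
}

#' Fraction of a gene set carrying the dual-high signature
#'
#' @param calls A `signature_call` table from [classify_signature()].
#' @param gene_set Nonempty character vector of genes, all present in
#'   `calls`.
#' @return Proportion of `gene_set` with `dual_high = TRUE`.
#' @export
dual_signature_fraction <- function(calls, gene_set) {
  if (length(gene_set) == 0) abort("`gene_set` must be nonempty.")
  if (!all(gene_set %in% calls$gene_id)) {
    abort("`gene_set` contains genes without signature calls.")
  }
  mean(calls$dual_high[match(gene_set, calls$gene_id)])
}

#' Pearson correlation between two per-gene mark signals
#'
#' @param signal_mark1,signal_mark2 Numeric vectors of per-gene signal
#'   (length >= 3, each with nonzero variance).
#' @return Pearson product-moment correlation in \[-1, 1\].
#' @export
mark_correlation <- function(signal_mark1, signal_mark2) {
  if (length(signal_mark1) != length(signal_mark2) ||
      length(signal_mark1) < 3) {
    abort("need two equal-length signals over at least 3 genes.")
  }
  if (var(signal_mark1) == 0 || var(signal_mark2) == 0) {
    abort("signals must have nonzero variance.")
  }
  cor(signal_mark1, signal_mark2)
}
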