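
#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement,
#' returned in the original input order.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) abort("`p_values` must be nonempty.")
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    abort("all p-values must lie in (0, 1].")
  }
  p.adjust(p_values, method = "BH")
}

#' Over-representation of annotation terms in a protein set
#'
#' For each term, tests over-representation of the term's proteins in
#' `member_set` against `background_set` with a one-sided Fisher exact
#' test (hypergeometric upper tail on the 2x2 table), and adjusts across
#' tested terms by Benjamini-Hochberg. Terms with fewer than
#' `min_term_size` proteins in the background are skipped.
#'
#' @param member_set Character vector, a subset of `background_set`.
#' @param background_set Character vector: the background population
#'   (e.g. all proteins present in at least one complex).
#' @param annotation_map Named list mapping term to protein set.
#' @param min_term_size Minimum background-intersected term size.
#' @return Tibble with one row per tested term: `term`, `k_in_set`,
#'   `n_set`, `K_in_background`, `N_background`, `p_raw`, `p_adjusted`.
#' @export
enrich_annotations <- function(member_set, background_set, annotation_map,
                               min_term_size = 2) {
  if (length(background_set) == 0) abort("`background_set` must be nonempty.")
  member_set <- unique(member_set)
  background_set <- unique(background_set)
  if (!all(member_set %in% background_set)) {
    abort("`member_set` must be a subset of `background_set`.")
  }
  N <- length(background_set)
  n <- length(member_set)
  rows <- purrr::imap_dfr(annotation_map, function(members, term) {
    term_bg <- intersect(unique(members), background_set)
    K <- length(term_bg)
    if (K < min_term_size) return(tibble())
    k <- length(intersect(member_set, term_bg))
    tibble(term = term, k_in_set = k, n_set = n,
           K_in_background = K, N_background = N,
           p_raw = phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (nrow(rows) == 0) {
    return(tibble(term = character(0), k_in_set = integer(0),
                  n_set = integer(0), K_in_background = integer(0),
                  N_background = integer(0), p_raw = numeric(0),
                  p_adjusted = numeric(0)))
  }
  mutate(rows, p_adjusted = bh_adjust(.data$p_raw)) |>
    arrange(.data$p_raw)
}
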