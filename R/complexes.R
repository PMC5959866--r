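
#' Iteratively merge redundant protein complexes
#'
#' While any two complexes share strictly more than `threshold` of their
#' proteins — overlap measured by the overlap coefficient
#' `|A n B| / min(|A|, |B|)`, so a complex nested inside a larger one
#' counts as redundant — the pair is merged into its union. Because
#' pairwise merging is order-dependent, the processing order is fixed:
#' complexes are scanned largest first, ties broken by name, and the first
#' offending pair is merged, the union taking the concatenated name.
#'
#' @param db A `complex_db` (see [simulate_complex_db()]; any named list of
#'   member vectors can be wrapped via the same structure).
#' @param threshold Overlap coefficient above which (strictly) two
#'   complexes are considered redundant. Default 0.7: complexes sharing
#'   more than 70% of their proteins are merged, sharing exactly 70% is
#'   kept.
#' @return A `complex_db` with merged complexes.
#' @export
merge_redundant_complexes <- function(db, threshold = 0.7) {
  stopifnot(inherits(db, "complex_db"))
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  complexes <- db$complexes
  repeat {
    ord <- order(-lengths(complexes), names(complexes))
    complexes <- complexes[ord]
    nms <- names(complexes)
    merged <- FALSE
    for (i in seq_along(complexes)) {
      if (merged) break
      for (j in seq_along(complexes)) {
        if (j <= i) next
        if (overlap_coefficient(complexes[[i]], complexes[[j]]) > threshold) {
          union_set <- sort(union(complexes[[i]], complexes[[j]]))
          new_name <- paste(nms[i], nms[j], sep = "+")
          complexes[[nms[i]]] <- NULL
          complexes[[nms[j]]] <- NULL
          complexes[[new_name]] <- union_set
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  new_complex_db(complexes, db$provenance)
}

#' Expand complexes into binary interactions (matrix model)
#'
#' Every complex of n members contributes all `choose(n, 2)` unordered
#' member pairs; the union over complexes is deduplicated. Self-pairs
#' cannot arise because member sets are sets.
#'
#' @param db A `complex_db`.
#' @return A tibble of unordered edges with columns `a` and `b`
#'   (`a < b` lexicographically).
#' @export
complexes_to_pairs <- function(db) {
  stopifnot(inherits(db, "complex_db"))
  pairs <- purrr::map_dfr(db$complexes, function(members) {
    members <- sort(unique(members))
    if (length(members) < 2) {
      return(tibble(a = character(0), b = character(0)))
    }
    cp <- combn(members, 2)
    tibble(a = cp[1, ], b = cp[2, ])
  })
  distinct(pairs)
}
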