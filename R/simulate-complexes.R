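
# overlap coefficient |A n B| / min(|A|, |B|)
overlap_coefficient <- function(a, b) {
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Simulate a redundant protein-complex database
#'
#' Generates named member sets in the style of a curated complex database,
#' in which a known fraction of complexes are near-duplicates (overlap
#' coefficient > 0.7) of another complex. The duplicate pairs are recorded
#' in the provenance table so redundancy-reduction can be tested against
#' ground truth; non-duplicate pairs are guaranteed not to exceed the 0.7
#' overlap rule.
#'
#' @param n_complexes Total number of complexes.
#' @param size_range Length-2 integer range of complex sizes (min >= 2).
#' @param redundancy_rate Fraction of complexes that are near-duplicates.
#' @param seed Integer seed.
#' @param universe_size Number of proteins to draw members from; default
#'   scales with `n_complexes` so accidental overlaps are rare.
#' @return A `complex_db`: list with `complexes` (named list of member
#'   vectors) and `provenance` (tibble of recorded duplicate pairs:
#'   `copy`, `source`).
#' @export
simulate_complex_db <- function(n_complexes, size_range = c(4, 10),
                                redundancy_rate = 0, seed = 1L,
                                universe_size = NULL) {
  n_complexes <- check_count(n_complexes, "n_complexes")
  redundancy_rate <- check_proportion(redundancy_rate, "redundancy_rate")
  if (length(size_range) != 2L || size_range[1] < 2) {
    abort("`size_range` must be c(min, max) with min >= 2.")
  }
  universe_size <- universe_size %||% max(100L, 20L * n_complexes)
  universe <- sprintf("prot_%04d", seq_len(universe_size))

  with_seed(seed, {
    n_dup <- if (n_complexes > 1) {
      min(round(redundancy_rate * n_complexes), floor(n_complexes / 2))
    } else 0L
    n_base <- n_complexes - n_dup
    complexes <- list()
    # rejection-sample base complexes so no accidental pair crosses 0.7
    for (i in seq_len(n_base)) {
      for (try in 1:100) {
        size <- sample(seq(size_range[1], size_range[2]), 1L)
        cand <- sample(universe, size)
        ok <- all(vapply(complexes, function(x) {
          overlap_coefficient(x, cand) <= 0.7
        }, logical(1)))
        if (ok) break
      }
      if (!ok) abort("could not place non-redundant complexes; increase `universe_size`.")
      complexes[[sprintf("complex_%03d", i)]] <- cand
    }
    provenance <- tibble(copy = character(0), source = character(0))
    base_names <- names(complexes)
    dup_sources <- if (n_dup > 0) sample(base_names, n_dup) else character(0)
    for (d in seq_len(n_dup)) {
      src <- dup_sources[d]
      members <- complexes[[src]]
      for (try in 1:100) {
        keep <- sample(members, ceiling(0.75 * length(members)))
        extra <- sample(setdiff(universe, members),
                        length(members) - length(keep))
        cand <- c(keep, extra)
        others <- complexes[setdiff(names(complexes), src)]
        ok <- all(vapply(others, function(x) {
          overlap_coefficient(x, cand) <= 0.7
        }, logical(1)))
        if (ok) break
      }
      if (!ok) abort("could not place duplicate complexes; increase `universe_size`.")
      nm <- sprintf("complex_%03d", n_base + d)
      complexes[[nm]] <- cand
      provenance <- bind_rows(provenance, tibble(copy = nm, source = src))
    }
    new_complex_db(complexes, provenance)
  })
}

new_complex_db <- function(complexes, provenance = NULL) {
  if (length(complexes) == 0 || any(lengths(complexes) == 0)) {
    abort("complexes must be a nonempty list of nonempty member sets.")
  }
  if (is.null(names(complexes)) || anyDuplicated(names(complexes))) {
    abort("complexes must have unique names.")
  }
  structure(list(complexes = lapply(complexes, unique),
                 provenance = provenance %||%
                   tibble(copy = character(0), source = character(0))),
            class = "complex_db")
}

#' @export
print.complex_db <- function(x, ...) {
  cat(sprintf("<complex_db> %d complexes, sizes %d-%d, %d recorded duplicate pairs\n",
              length(x$complexes), min(lengths(x$complexes)),
              max(lengths(x$complexes)), nrow(x$provenance)))
  invisible(x)
}
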