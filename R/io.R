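
#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (name, description, tab-separated
#'   members per line).
#' @return Named list of member vectors.
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE)) {
    return(fgsea::gmtPathways(path))
  }
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[[`, character(1), 1))
}

#' Write complexes or gene sets as GMT
#'
#' @param sets Named list of member vectors, or a `complex_db`.
#' @param path Output path.
#' @param description Description field written per line.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "complex_db")) sets <- sets$complexes
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
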