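
# internal input checks -------------------------------------------------

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_sd <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", name))
  }
  as.numeric(x)
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a proportion in [0, 1].", name))
  }
  as.numeric(x)
}

#' Percentage of a cascade stage, printed the way screen tables print it
#'
#' Computes `100 * k / n` rounded half away from zero to one decimal place,
#' the convention used when reporting filtering-cascade fractions such as
#' "128 of 960 (13.3%)".
#'
#' @param k Number of items passing the stage.
#' @param n Total number of items entering the stage.
#' @return A single number, e.g. `13.3`.
#' @examples
#' cascade_percent(128, 960)
#' cascade_percent(406, 960)
#' @export
cascade_percent <- function(k, n) {
  if (n <= 0) abort("`n` must be positive.")
  x <- 100 * k / n
  sign(x) * floor(abs(x) * 10 + 0.5) / 10
}

# area under the ROC curve via the rank (Mann-Whitney) statistic;
# `score` oriented so larger = more likely positive
rank_auc <- function(score, is_positive) {
  stopifnot(length(score) == length(is_positive))
  pos <- score[is_positive]
  neg <- score[!is_positive]
  if (length(pos) == 0L || length(neg) == 0L) abort("need both classes for AUC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}
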