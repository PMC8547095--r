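# Cognitive-test summary statistics: novel-object-recognition preference
# and Y-maze spontaneous alternation.

#' Novel-object preference
#'
#' Percentage of exploration time spent on the novel object:
#' `100 * novel / (novel + familiar)`.
#'
#' @param novel,familiar exploration times in seconds (non-negative).
#' @return Percent in `[0, 100]`; a zero total is unscoreable (error).
#' @export
nor_percent <- function(novel, familiar) {
  if (any(novel < 0) || any(familiar < 0))
    stop("exploration times must be non-negative")
  total <- novel + familiar
  if (any(total == 0))
    stop("zero total exploration time: trial unscoreable")
  100 * novel / total
}

#' One-sample t-test against chance
#'
#' Tests a vector of preference percentages against a hypothetical chance
#' value (50% for a two-object recognition test). Two-sided by default.
#'
#' @param values numeric observations (n >= 2, nonzero variance).
#' @param mu chance value.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List with `t`, `p`, `df`, `mean`.
#' @export
one_sample_t_vs_chance <- function(values, mu = 50,
                                   alternative = "two.sided") {
  if (length(values) < 2) stop("need at least two observations")
  if (stats::sd(values) == 0)
    stop("zero variance: t-statistic undefined")
  tt <- stats::t.test(values, mu = mu, alternative = alternative)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean = unname(tt$estimate))
}

#' Y-maze spontaneous alternation
#'
#' An alternation is a sliding window of 3 consecutive arm entries visiting
#' all three arms; the percentage divides the alternation count by the
#' number of possible windows (entries - 2).
#'
#' @param entries character vector of consecutive arm entries over the
#'   arms `A`, `B`, `C` (at least 3).
#' @return Percent alternation in `[0, 100]`.
#' @export
alternation_percent <- function(entries) {
  entries <- toupper(as.character(entries))
  if (length(entries) == 1 && nchar(entries) > 1)
    entries <- strsplit(entries, "")[[1]]
  if (!all(entries %in% c("A", "B", "C")))
    stop("arm entries must be from {A, B, C}")
  n <- length(entries)
  if (n < 3) stop("fewer than 3 entries: trial unscoreable")
  windows <- vapply(seq_len(n - 2), function(i)
    length(unique(entries[i:(i + 2)])) == 3, TRUE)
  100 * sum(windows) / (n - 2)
}
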