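#' Summary statistics of a gated lifetime set
#'
#' Reports both median-centered and mean-centered location/dispersion pairs,
#' always labelled: `median_tau_s` with `mad_s` (median absolute deviation,
#' consistency-scaled), and `mean_tau_s` with `sem_s` (standard error of the
#' mean, `sd / sqrt(n)`).
#'
#' @param set A `lifetime_set` from [apply_all_gates()], or any data frame
#'   with `condition` and `tau_s` columns; multiple conditions are
#'   summarized per condition.
#' @return A tibble with one row per condition: `condition`, `n_clusters`,
#'   `median_tau_s`, `mad_s`, `mean_tau_s`, `sd_s`, `sem_s`. An empty input
#'   returns a typed `tcpalm_no_data` object instead.
#' @export
summarize_lifetimes <- function(set) {
  if (nrow(set) == 0L) {
    return(structure(
      list(message = "no gated lifetimes to summarize"),
      class = c("tcpalm_no_data", "condition")
    ))
  }
  dplyr::summarise(
    dplyr::group_by(set, .data$condition),
    n_clusters = dplyr::n(),
    median_tau_s = median(.data$tau_s),
    mad_s = mad(.data$tau_s),
    mean_tau_s = mean(.data$tau_s),
    sd_s = sd(.data$tau_s),
    sem_s = sd(.data$tau_s) / sqrt(dplyr::n()),
    .groups = "drop"
  )
}

#' @export
print.tcpalm_no_data <- function(x, ...) {
  cat("<tcpalm_no_data>", x$message, "\n")
  invisible(x)
}

#' Unpaired two-sided Wilcoxon rank-sum comparison
#'
#' Mann-Whitney/Wilcoxon rank-sum test between two lifetime samples: the
#' exact null distribution is enumerated when the pooled sample is small
#' (`n1 + n2 <= 20`) and tie-free, otherwise the normal approximation with
#' tie correction (and continuity correction) is used. The p-value is
#' invariant under swapping the samples.
#'
#' @param a,b Numeric lifetime vectors (non-empty).
#' @param label_a,label_b Condition labels carried into the result.
#' @return A one-row tibble: `label_a`, `label_b`, `statistic` (the
#'   Mann-Whitney U of `a`), `p_value`, `n1`, `n2`, `method`.
#' @examples
#' wilcoxon_rank_test(c(1, 2, 5), c(4, 6, 8))
#' @export
wilcoxon_rank_test <- function(a, b, label_a = "a", label_b = "b") {
  if (length(a) == 0L || length(b) == 0L) {
    abort("Both samples must be non-empty.", class = "tcpalm_empty_sample")
  }
  has_ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !has_ties && (length(a) + length(b)) <= 20L
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = use_exact,
                       correct = TRUE)
  )
  tibble::tibble(
    label_a = label_a, label_b = label_b,
    statistic = unname(res$statistic),
    p_value = res$p.value,
    n1 = length(a), n2 = length(b),
    method = if (use_exact) "exact" else "normal approximation"
  )
}

#' Empirical cumulative distribution of gated lifetimes
#'
#' Right-continuous ECDF over the distinct lifetime values; the last
#' fraction is exactly 1. With several conditions in the set the ECDF is
#' computed per condition, which is the normalized-cumulative-distribution
#' view used to compare lifetime distributions across genotypes.
#'
#' @param set A `lifetime_set`, a data frame with `condition` and `tau_s`,
#'   or a bare numeric vector.
#' @return A tibble with `condition` (absent for bare vectors), `tau_s`, and
#'   `fraction` = P(lifetime <= tau_s). Empty input returns a typed
#'   `tcpalm_no_data` object.
#' @export
cumulative_distribution <- function(set) {
  one <- function(x) {
    v <- sort(unique(x))
    tibble::tibble(
      tau_s = v,
      fraction = stats::ecdf(x)(v)
    )
  }
  if (is.numeric(set)) {
    if (length(set) == 0L) {
      return(structure(list(message = "no lifetimes"),
                       class = c("tcpalm_no_data", "condition")))
    }
    return(one(set))
  }
  if (nrow(set) == 0L) {
    return(structure(list(message = "no lifetimes"),
                     class = c("tcpalm_no_data", "condition")))
  }
  dplyr::reframe(dplyr::group_by(set, .data$condition), one(.data$tau_s))
}
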