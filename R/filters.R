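#' Lifetime gating configuration
#'
#' The gating ledger applied to raw correlation times before any
#' between-condition comparison: a goodness-of-fit gate, burst-count
#' normalization across conditions, a modal-frequency filter that strips
#' sparse histogram bins (largely photophysics stragglers), and the
#' live/fixed 20-s discrimination rule.
#'
#' @param r2_min Minimum fit R-squared retained (inclusive); default 0.98.
#' @param n_bursts_norm Bursts retained per condition for comparability;
#'   default 2500.
#' @param freq_fraction Histogram bins with fewer counts than this fraction
#'   of the modal bin are removed; default 0.20.
#' @param live_tau_max_s Correlation times below this bound classify as
#'   live-like; default 20 s.
#' @param hist_bin_width_s Bin width of the frequency-filter histogram,
#'   seconds; default 2.
#' @param subsample_seed Seed for the burst-count subsampling.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(r2_min = 0.98,
                          n_bursts_norm = 2500,
                          freq_fraction = 0.20,
                          live_tau_max_s = 20,
                          hist_bin_width_s = 2,
                          subsample_seed = 1L) {
  if (r2_min <= 0 || r2_min > 1) abort("`r2_min` must be in (0, 1].")
  if (n_bursts_norm < 1) abort("`n_bursts_norm` must be >= 1.")
  if (freq_fraction <= 0 || freq_fraction >= 1) {
    abort("`freq_fraction` must be in (0, 1).")
  }
  if (live_tau_max_s <= 0) abort("`live_tau_max_s` must be > 0.")
  if (hist_bin_width_s <= 0) abort("`hist_bin_width_s` must be > 0.")
  structure(
    list(
      r2_min = r2_min,
      n_bursts_norm = as.integer(n_bursts_norm),
      freq_fraction = freq_fraction,
      live_tau_max_s = live_tau_max_s,
      hist_bin_width_s = hist_bin_width_s,
      subsample_seed = as.integer(subsample_seed)
    ),
    class = "filter_config"
  )
}

#' Goodness-of-fit gate
#'
#' Keeps fits with `r_squared >= r2_min` (inclusive), preserving order.
#'
#' @param fits A per-burst fit tibble ([fit_cluster_lifetimes()] output) or
#'   any data frame with an `r_squared` column.
#' @param r2_min Threshold in (0, 1].
#' @return The retained rows of `fits`.
#' @export
gate_by_r2 <- function(fits, r2_min = 0.98) {
  if (r2_min <= 0 || r2_min > 1) abort("`r2_min` must be in (0, 1].")
  fits[fits$r_squared >= r2_min, , drop = FALSE]
}

#' Burst-count normalization by subsampling
#'
#' Draws a uniform random subsample without replacement of `n_target`
#' elements (keeping the original order) so compared conditions carry equal
#' burst counts; if the input is already at or below the target, everything
#' is retained and a warning of class `tcpalm_subsample_short` is emitted.
#'
#' @param taus Numeric vector (or any vector) to subsample.
#' @param n_target Number of elements to retain (>= 1).
#' @param seed Integer seed; the subsample is reproducible.
#' @return The retained elements, in original order.
#' @export
subsample_bursts <- function(taus, n_target = 2500, seed = 1L) {
  if (n_target < 1) abort("`n_target` must be >= 1.")
  n <- length(taus)
  if (n <= n_target) {
    if (n < n_target) {
      warn(
        sprintf("only %d bursts available; target %d retained all.",
                n, as.integer(n_target)),
        class = "tcpalm_subsample_short"
      )
    }
    return(taus)
  }
  idx <- withr::with_seed(as.integer(seed),
                          sort(sample.int(n, as.integer(n_target))))
  taus[idx]
}

#' Modal-frequency filter
#'
#' Histograms the correlation times into left-closed bins
#' `[k*w, (k+1)*w)` and removes every value falling in a bin whose count is
#' strictly smaller than `freq_fraction` of the modal bin's count. The modal
#' bin itself always survives.
#'
#' @param taus Non-negative correlation times, seconds.
#' @param bin_width_s Histogram bin width, seconds (> 0).
#' @param freq_fraction Fraction of the modal count below which a bin is
#'   dropped.
#' @return The retained values, in original order.
#' @export
frequency_filter <- function(taus, bin_width_s = 2, freq_fraction = 0.20) {
  if (bin_width_s <= 0) abort("`bin_width_s` must be > 0.")
  if (length(taus) == 0L) return(taus)
  bin <- floor(taus / bin_width_s)
  counts <- table(bin)
  threshold <- freq_fraction * max(counts)
  keep_bins <- as.numeric(names(counts)[counts >= threshold])
  taus[bin %in% keep_bins]
}

#' Live/fixed discrimination of correlation times
#'
#' Correlation times strictly below `live_tau_max_s` are `live_like`
#' (consistent with a transient cluster); values at or above it are
#' `fixed_like` (indistinguishable from immobile-emitter photophysics, which
#' accumulates detections over the whole movie).
#'
#' @param tau_s Non-negative correlation time(s), seconds; vectorized.
#' @param live_tau_max_s The discrimination bound, seconds (default 20).
#' @return Character vector of `"live_like"` / `"fixed_like"`.
#' @examples
#' classify_live_fixed(c(5.86, 25))
#' @export
classify_live_fixed <- function(tau_s, live_tau_max_s = 20) {
  if (any(tau_s < 0)) abort("`tau_s` must be >= 0.")
  ifelse(tau_s < live_tau_max_s, "live_like", "fixed_like")
}

#' Apply the full gating ledger to per-burst fits
#'
#' Gates are applied in order: R-squared gate, burst-count subsampling,
#' modal-frequency filter, then live/fixed classification. By default the
#' live/fixed stage labels rather than drops (so the composition of a gated
#' set can be inspected); set `class_filter` to `"live_like"` or
#' `"fixed_like"` to retain only that class, as when comparing live-cell
#' conditions. Per-gate drop counts are recorded in the `provenance`
#' attribute and always sum, together with the retained count, to the input
#' size.
#'
#' @param fits Per-burst fit tibble ([fit_cluster_lifetimes()] output) with
#'   `tau_s` and `r_squared` columns.
#' @param cfg A [filter_config()].
#' @param condition Label attached to the output set.
#' @param class_filter `"none"` (label only), `"live_like"` or
#'   `"fixed_like"`.
#' @param n_target Overrides `cfg$n_bursts_norm`, e.g. with the smaller of
#'   two conditions' burst counts.
#' @return A `lifetime_set`: tibble with columns `condition`, `tau_s`,
#'   `r_squared`, `class` and a `provenance` attribute (named list of
#'   counts); see [lifetime_provenance()].
#' @export
apply_all_gates <- function(fits, cfg = filter_config(),
                            condition = "condition",
                            class_filter = c("none", "live_like",
                                             "fixed_like"),
                            n_target = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  class_filter <- match.arg(class_filter)
  n_target <- n_target %||% cfg$n_bursts_norm
  n_input <- nrow(fits)

  kept <- gate_by_r2(fits, cfg$r2_min)
  dropped_r2 <- n_input - nrow(kept)

  if (nrow(kept) > n_target) {
    idx <- withr::with_seed(cfg$subsample_seed,
                            sort(sample.int(nrow(kept), as.integer(n_target))))
    dropped_subsample <- nrow(kept) - length(idx)
    kept <- kept[idx, , drop = FALSE]
  } else {
    dropped_subsample <- 0L
  }

  if (nrow(kept)) {
    bin <- floor(kept$tau_s / cfg$hist_bin_width_s)
    counts <- table(bin)
    keep_bins <- as.numeric(names(counts)[counts >= cfg$freq_fraction *
                                            max(counts)])
    keep <- bin %in% keep_bins
  } else {
    keep <- logical(0)
  }
  dropped_frequency <- sum(!keep)
  kept <- kept[keep, , drop = FALSE]

  cls <- if (nrow(kept)) classify_live_fixed(kept$tau_s, cfg$live_tau_max_s) else character(0)
  if (class_filter != "none") {
    sel <- cls == class_filter
    dropped_class <- sum(!sel)
    kept <- kept[sel, , drop = FALSE]
    cls <- cls[sel]
  } else {
    dropped_class <- 0L
  }

  out <- tibble::tibble(
    condition = rep(condition, nrow(kept)),
    tau_s = if (nrow(kept)) kept$tau_s else numeric(0),
    r_squared = if (nrow(kept)) kept$r_squared else numeric(0),
    class = cls
  )
  attr(out, "provenance") <- list(
    condition = condition,
    n_input = n_input,
    dropped_r2 = dropped_r2,
    dropped_subsample = dropped_subsample,
    dropped_frequency = as.integer(dropped_frequency),
    dropped_class = as.integer(dropped_class),
    n_retained = nrow(out),
    class_filter = class_filter,
    config = unclass(cfg)
  )
  class(out) <- c("lifetime_set", class(out))
  out
}

#' Provenance of a gated lifetime set
#'
#' @param set A `lifetime_set` from [apply_all_gates()].
#' @return The named provenance list (input size, per-gate drop counts,
#'   retained count, config echo).
#' @export
lifetime_provenance <- function(set) {
  attr(set, "provenance")
}
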