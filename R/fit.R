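# Cumulative-trace model:
#   N(t) = amplitude * Phi((t - t0) / width) + baseline_rate * (t - t_first)
# where Phi is the standard Gaussian CDF. The correlation time tau is the
# 10-90% rise time of the fitted sigmoid, tau = 2 * qnorm(0.9) * width.
#
# The background slope is bounded above by 20% of the trace's gross
# detection rate: inside a sub-200-nm ROI genuine background is sparse, and
# an unbounded linear term is collinear with arbitrarily wide sigmoids on
# ramp-like traces (any width fits a constant-rate trace exactly), which
# would make tau unidentifiable.
BASELINE_FRACTION_MAX <- 0.2

# Time below which the trace first reaches fraction p of its final count.
trace_quantile_time <- function(t, y, p) {
  t[which(y >= p * y[length(y)])[1L]]
}

cdf_model <- function(par, t, t_first) {
  par[["A"]] * pnorm((t - par[["t0"]]) / par[["w"]]) +
    par[["b"]] * (t - t_first)
}

new_cdf_fit <- function(amplitude, t0_s, width_s, baseline_rate_hz,
                        r_squared, n_detections, n_points, converged,
                        trace) {
  structure(
    list(
      amplitude = amplitude, t0_s = t0_s, width_s = width_s,
      baseline_rate_hz = baseline_rate_hz, r_squared = r_squared,
      tau_s = RISE_FACTOR * width_s,
      n_detections = n_detections, n_points = n_points,
      converged = converged, trace = trace
    ),
    class = "cdf_fit"
  )
}

#' Fit the cumulative detection trace of a burst
#'
#' Least-squares fit of a Gaussian-CDF sigmoid plus a bounded linear
#' background to a cumulative trace. The correlation time `tau_s` is the
#' 10-90% rise time of the fitted sigmoid (`2 * 1.28155 * width_s`); `tau_s`
#' near zero means an instantaneous step, values comparable to the
#' acquisition length mean steady photophysics-like accumulation.
#'
#' The fit is deterministic: Levenberg-Marquardt refinement from a single
#' start derived from the empirical trace (`t0` = median-crossing time,
#' `width` = empirical 10-90% spread / 2.5631, `amplitude` = final count,
#' zero baseline), with box bounds `amplitude > 0`, `width_s >= 0`,
#' `0 <= baseline_rate_hz <= 0.2 x` gross rate. A trace whose detections all
#' fall in one frame is the exact zero-width step limit and is returned as
#' such without optimization.
#'
#' @param trace A cumulative trace from [cumulative_trace()] (columns
#'   `time_s`, `cum_count`).
#' @param min_burst_detections Bursts with fewer detections are not fitted;
#'   a typed condition object of class `tcpalm_insufficient` is returned
#'   instead (not an error).
#' @return A `cdf_fit` object (fields `amplitude`, `t0_s`, `width_s`,
#'   `baseline_rate_hz`, `r_squared`, `tau_s`, ...) with [tidy()] and
#'   [glance()] methods, or a `tcpalm_insufficient` object.
#' @examples
#' tr <- cumulative_trace(c(0:99), frame_time_s = 0.01)
#' fit <- fit_cumulative_cdf(tr)
#' glance(fit)
#' @export
fit_cumulative_cdf <- function(trace, min_burst_detections = 10) {
  t <- trace$time_s
  y <- trace$cum_count
  n_det <- if (length(y)) y[length(y)] else 0
  if (n_det < min_burst_detections) {
    return(structure(
      list(n_detections = n_det, min_required = min_burst_detections),
      class = c("tcpalm_insufficient", "condition"),
      message = "insufficient detections for a cumulative fit"
    ))
  }

  if (length(t) < 2L || diff(range(t)) == 0) {
    # all detections in one frame: exact zero-width step limit
    return(new_cdf_fit(
      amplitude = n_det, t0_s = t[1L], width_s = 0, baseline_rate_hz = 0,
      r_squared = 1, n_detections = n_det, n_points = length(t),
      converged = TRUE, trace = trace
    ))
  }

  t_first <- t[1L]
  span <- t[length(t)] - t_first
  t10 <- trace_quantile_time(t, y, 0.1)
  t50 <- trace_quantile_time(t, y, 0.5)
  t90 <- trace_quantile_time(t, y, 0.9)
  start <- c(
    A = n_det,
    t0 = t50,
    w = max((t90 - t10) / RISE_FACTOR, span / 100, 1e-6),
    b = 0
  )
  # Identifiability bounds: the burst is fully observed (it ends when
  # detections stop), so the rise's midpoint lies inside the data, its
  # amplitude is commensurate with the final count, and a rise wider than
  # twice the observed span is not distinguishable from background.
  b_max <- BASELINE_FRACTION_MAX * n_det / span
  lower <- c(A = 1e-8, t0 = t_first, w = 1e-6, b = 0)
  upper <- c(A = 1.5 * n_det, t0 = t[length(t)], w = 2 * span, b = b_max)
  start <- pmin(pmax(start, lower), upper)

  fit_par <- NULL
  converged <- FALSE
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * pnorm((t - t0) / w) + b * (t - t_first),
      start = as.list(start), lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                           ptol = 1e-13)
    ),
    error = function(e) NULL
  )
  sse <- function(p) {
    r <- y - cdf_model(p, t, t_first)
    sum(r * r)
  }
  if (!is.null(fit)) {
    fit_par <- stats::coef(fit)
    converged <- TRUE
  } else {
    opt <- tryCatch(
      optim(start, sse, method = "L-BFGS-B", lower = lower, upper = upper),
      error = function(e) NULL
    )
    if (!is.null(opt)) {
      fit_par <- opt$par
      converged <- opt$convergence == 0L
    } else {
      fit_par <- start
    }
  }
  # the SSE valley along width is often very shallow; a deterministic
  # bounded polish from the LM solution settles it
  polish <- tryCatch(
    optim(fit_par, sse, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = 500, factr = 10)),
    error = function(e) NULL
  )
  if (!is.null(polish) && polish$value < sse(fit_par)) {
    fit_par <- polish$par
  }

  resid <- y - cdf_model(fit_par, t, t_first)
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-12) 1 else 0
  } else {
    min(max(1 - ss_res / ss_tot, 0), 1)
  }
  new_cdf_fit(
    amplitude = unname(fit_par[["A"]]), t0_s = unname(fit_par[["t0"]]),
    width_s = unname(fit_par[["w"]]),
    baseline_rate_hz = unname(fit_par[["b"]]),
    r_squared = r2, n_detections = n_det, n_points = length(t),
    converged = converged, trace = trace
  )
}

#' @export
print.cdf_fit <- function(x, ...) {
  cat(sprintf(
    "<cdf_fit> tau = %.3f s (width %.3f s), amplitude %.1f, baseline %.3f Hz, R^2 = %.4f, n = %d\n",
    x$tau_s, x$width_s, x$amplitude, x$baseline_rate_hz, x$r_squared,
    x$n_detections
  ))
  invisible(x)
}

#' @export
print.tcpalm_insufficient <- function(x, ...) {
  cat(sprintf(
    "<tcpalm_insufficient> %g detections (minimum %g): burst not fitted\n",
    x$n_detections, x$min_required
  ))
  invisible(x)
}

#' @rdname fit_cumulative_cdf
#' @param x A `cdf_fit` object.
#' @param ... Unused.
#' @method tidy cdf_fit
#' @export
tidy.cdf_fit <- function(x, ...) {
  tibble::tibble(
    term = c("amplitude", "t0_s", "width_s", "baseline_rate_hz"),
    estimate = c(x$amplitude, x$t0_s, x$width_s, x$baseline_rate_hz)
  )
}

#' @rdname fit_cumulative_cdf
#' @method glance cdf_fit
#' @export
glance.cdf_fit <- function(x, ...) {
  tibble::tibble(
    tau_s = x$tau_s, r.squared = x$r_squared,
    n_detections = x$n_detections, n_points = x$n_points,
    converged = x$converged
  )
}

#' Per-burst lifetimes for every spatial cluster in a table
#'
#' Runs the full temporal analysis for each detected spatial cluster:
#' segments the cluster's detections into temporal bursts at the blinking
#' cutoff, fits the cumulative trace of every burst with at least
#' `min_burst_detections` detections, and collects the fitted correlation
#' times. The raw burst span (`last - first` detection time) is retained
#' alongside the fitted `tau_s` for comparison.
#'
#' @param table A localization table.
#' @param clusters Output of [detect_spatial_clusters()] on `table`.
#' @param cfg A [tcpalm_config()].
#' @return A tibble with one row per fitted burst: `cluster_id`, `burst_id`,
#'   `first_s`, `last_s`, `n_detections`, `amplitude`, `t0_s`, `width_s`,
#'   `baseline_rate_hz`, `r_squared`, `tau_s`, `raw_span_s`, plus the
#'   cluster's `size_class`. The number of bursts rejected for insufficient
#'   detections is in `attr(, "n_insufficient")`.
#' @export
fit_cluster_lifetimes <- function(table, clusters, cfg = tcpalm_config()) {
  stopifnot(inherits(cfg, "tcpalm_config"))
  n_insufficient <- 0L
  rows <- purrr::map(seq_len(nrow(clusters)), function(i) {
    frames <- sort(table$frame[clusters$member_rows[[i]]])
    bursts <- segment_temporal_bursts(frames, cfg$blinking_cutoff_frames)
    purrr::map_dfr(seq_len(nrow(bursts)), function(b) {
      trace <- cumulative_trace(bursts[b, ], cfg$frame_time_s)
      fit <- fit_cumulative_cdf(trace, cfg$min_burst_detections)
      if (inherits(fit, "tcpalm_insufficient")) {
        n_insufficient <<- n_insufficient + 1L
        return(NULL)
      }
      tibble::tibble(
        cluster_id = clusters$cluster_id[i],
        burst_id = bursts$burst_id[b],
        first_s = bursts$first_frame[b] * cfg$frame_time_s,
        last_s = bursts$last_frame[b] * cfg$frame_time_s,
        n_detections = bursts$n_detections[b],
        amplitude = fit$amplitude, t0_s = fit$t0_s, width_s = fit$width_s,
        baseline_rate_hz = fit$baseline_rate_hz,
        r_squared = fit$r_squared, tau_s = fit$tau_s,
        raw_span_s = (bursts$last_frame[b] - bursts$first_frame[b]) *
          cfg$frame_time_s,
        size_class = clusters$size_class[i]
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      cluster_id = integer(0), burst_id = integer(0), first_s = numeric(0),
      last_s = numeric(0), n_detections = integer(0), amplitude = numeric(0),
      t0_s = numeric(0), width_s = numeric(0), baseline_rate_hz = numeric(0),
      r_squared = numeric(0), tau_s = numeric(0), raw_span_s = numeric(0),
      size_class = character(0)
    )
  }
  attr(out, "n_insufficient") <- n_insufficient
  out
}
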