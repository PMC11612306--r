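make_sigmoid_trace <- function(amplitude, t0, width, n_points = 150,
                               from = t0 - 4 * width, to = t0 + 4 * width) {
  t <- seq(from, to, length.out = n_points)
  tibble::tibble(time_s = t,
                 cum_count = amplitude * pnorm((t - t0) / width))
}

test_that("tau is the 10-90% rise time of the fitted width", {
  tr <- make_sigmoid_trace(200, 5, 1)
  fit <- fit_cumulative_cdf(tr)
  expect_equal(fit$tau_s, 2 * 1.2815516 * fit$width_s, tolerance = 1e-6)
  # width of exactly 1 s maps to tau = 2.5631 s
  expect_equal(fit$width_s, 1, tolerance = 0.01)
  expect_equal(fit$tau_s, 2.5631, tolerance = 0.01)
})

test_that("noiseless sigmoid traces are recovered to within 1%", {
  cases <- list(c(A = 150, t0 = 10, w = 0.8),
                c(A = 400, t0 = 40, w = 3),
                c(A = 50, t0 = 2, w = 0.3))
  for (p in cases) {
    tr <- make_sigmoid_trace(p[["A"]], p[["t0"]], p[["w"]])
    fit <- fit_cumulative_cdf(tr)
    expect_equal(fit$amplitude, p[["A"]], tolerance = 0.01)
    expect_equal(fit$t0_s, p[["t0"]], tolerance = 0.01)
    expect_equal(fit$width_s, p[["w"]], tolerance = 0.01)
    expect_gte(fit$r_squared, 0.999)
  }
})

test_that("a single-frame step is the exact zero-width limit", {
  tr <- cumulative_trace(rep(7L, 25), frame_time_s = 0.01)
  fit <- fit_cumulative_cdf(tr)
  expect_equal(fit$width_s, 0)
  expect_equal(fit$tau_s, 0)
  expect_gte(fit$r_squared, 0.98)
  expect_equal(fit$amplitude, 25)
})

test_that("under-populated bursts return a typed insufficient outcome", {
  tr <- cumulative_trace(c(1L, 5L, 9L), frame_time_s = 0.01)
  out <- fit_cumulative_cdf(tr, min_burst_detections = 10)
  expect_s3_class(out, "tcpalm_insufficient")
  expect_identical(out$n_detections, 3)
})

test_that("rescaling time rescales tau proportionally", {
  withr::with_seed(3, {
    frames <- sort(sample.int(800, 120, replace = TRUE))
  })
  tr <- cumulative_trace(frames, frame_time_s = 0.01)
  fit1 <- fit_cumulative_cdf(tr)
  for (c_scale in c(2, 10)) {
    tr_scaled <- tibble::tibble(time_s = tr$time_s * c_scale,
                                cum_count = tr$cum_count)
    fit2 <- fit_cumulative_cdf(tr_scaled)
    expect_equal(fit2$tau_s, c_scale * fit1$tau_s, tolerance = 0.01)
  }
})

test_that("linear-ramp traces match the dense-grid least-squares oracle", {
  # constant-rate recruitment over T = 8 s gives a near-linear cumulative
  # ramp; the fitted rise time must agree with an exhaustive grid search
  tr <- cumulative_trace(seq(2000L, 2800L, by = 4L), frame_time_s = 0.01)
  fit <- fit_cumulative_cdf(tr)
  tau_oracle <- oracle_grid_fit_tau(tr)
  expect_lt(abs(fit$tau_s - tau_oracle) / tau_oracle, 0.15)
})

test_that("tidy and glance expose the fit in broom style", {
  fit <- fit_cumulative_cdf(make_sigmoid_trace(100, 5, 1))
  td <- tidy(fit)
  expect_identical(td$term,
                   c("amplitude", "t0_s", "width_s", "baseline_rate_hz"))
  gl <- glance(fit)
  expect_identical(names(gl)[1:2], c("tau_s", "r.squared"))
  expect_true(gl$converged)
})

test_that("per-cluster lifetime tables carry fits and raw spans", {
  sim <- small_live_table(seed = 13, n_clusters = 4, background_rate_hz = 0)
  cl <- detect_spatial_clusters(sim$table)
  fits <- fit_cluster_lifetimes(sim$table, cl)
  expect_true(all(c("tau_s", "r_squared", "raw_span_s", "size_class") %in%
                    names(fits)))
  expect_true(all(fits$r_squared >= 0 & fits$r_squared <= 1))
  expect_true(all(fits$tau_s >= 0))
  expect_true(all(fits$n_detections >= 10))
  # raw spans cannot exceed the simulated lifetimes by much
  expect_lt(max(fits$raw_span_s), max(sim$specs$lifetime_s) + 1)
})
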