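test_that("default acquisition reproduces a 100-s movie of 10,000 frames", {
  acq <- acquisition_params()
  expect_identical(acq$n_frames, 10000L)
  expect_identical(acq$frame_time_s, 0.01)
  expect_identical(total_time_s(acq), 100)
})

test_that("parameter constructors reject invalid values", {
  expect_error(acquisition_params(n_frames = 0), "n_frames")
  expect_error(acquisition_params(frame_time_s = -1), "frame_time_s")
  expect_error(photophysics_params(mean_dark_frames = 0), "positive")
  expect_error(simulate_fixed_cell(n_molecules = -1), "n_molecules")
})

test_that("cluster specs outside the field or the acquisition are rejected by index", {
  acq <- acquisition_params()
  expect_error(
    cluster_specs(25000, 5000, 60, 10, 5, 10, acq = acq),
    "Cluster 1.*field"
  )
  expect_error(
    cluster_specs(c(5000, 6000), c(5000, 6000), c(60, 60), c(10, 95),
                  c(5, 8), c(10, 10), acq = acq),
    "Cluster 2.*ON-window"
  )
})

test_that("no clusters and no background yields an empty table", {
  acq <- acquisition_params()
  specs <- live_cluster_specs(n_clusters = 0, acq = acq, seed = 1)
  tbl <- simulate_live_cell(acq, live_photophysics(), specs,
                            background_rate_hz = 0, seed = 1)
  expect_identical(nrow(tbl), 0L)
  expect_identical(nrow(simulate_fixed_cell(acq, n_molecules = 0, seed = 1)), 0L)
})

test_that("cluster detections respect the ON-window and carry ground truth", {
  acq <- acquisition_params()
  specs <- cluster_specs(10000, 10000, 60, t_on_s = 20, lifetime_s = 8,
                         n_molecules = 30, acq = acq)
  tbl <- simulate_live_cell(acq, live_photophysics(), specs,
                            background_rate_hz = 0, seed = 5)
  expect_true(all(tbl$truth_cluster_id == 1L))
  times <- tbl$frame * acq$frame_time_s
  expect_gte(min(times), 20)
  expect_lte(max(times), 28)
})

test_that("background detection count matches its Poisson expectation", {
  acq <- acquisition_params()
  specs <- live_cluster_specs(n_clusters = 0, acq = acq, seed = 1)
  lambda <- 50 * total_time_s(acq)
  for (seed in 1:3) {
    tbl <- simulate_live_cell(acq, live_photophysics(), specs,
                              background_rate_hz = 50, seed = seed)
    expect_lt(abs(nrow(tbl) - lambda), 3 * sqrt(lambda))
  }
})

test_that("simulation is reproducible and sorted by frame then x then y", {
  sim <- small_live_table(seed = 9)
  sim2 <- small_live_table(seed = 9)
  expect_identical(sim$table, sim2$table)
  tbl <- sim$table
  ord <- order(tbl$frame, tbl$x_nm, tbl$y_nm)
  expect_identical(ord, seq_len(nrow(tbl)))
  expect_true(all(tbl$frame >= 0 & tbl$frame < 10000))
  expect_true(all(tbl$x_nm >= 0 & tbl$x_nm <= 20000))
})

test_that("a single immobile noiseless emitter keeps one position", {
  acq <- acquisition_params(localization_sigma_nm = 0)
  tbl <- simulate_fixed_cell(acq, fixed_photophysics(), n_molecules = 1,
                             seed = 2)
  expect_gt(nrow(tbl), 0)
  expect_identical(length(unique(tbl$x_nm)), 1L)
  expect_identical(length(unique(tbl$y_nm)), 1L)
})

test_that("fixed-cell emitters span most of the acquisition", {
  acq <- acquisition_params()
  tbl <- simulate_fixed_cell(acq, fixed_photophysics(), n_molecules = 200,
                             seed = 3)
  spans <- tapply(tbl$frame, tbl$truth_cluster_id,
                  function(f) diff(range(f)) * acq$frame_time_s)
  expect_gte(mean(spans > 0.5 * total_time_s(acq)), 0.9)
})

test_that("live cluster detection spans are shorter than fixed-cell spans", {
  acq <- acquisition_params()
  for (seed in 1:3) {
    live <- small_live_table(seed = seed, background_rate_hz = 0)$table
    fixed <- simulate_fixed_cell(acq, fixed_photophysics(), 50, seed = seed)
    span_of <- function(tbl) {
      unname(tapply(tbl$frame, tbl$truth_cluster_id,
                    function(f) diff(range(f)) * acq$frame_time_s))
    }
    expect_lt(median(span_of(live)), median(span_of(fixed)))
  }
})
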