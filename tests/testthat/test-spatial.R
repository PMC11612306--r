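test_that("an empty table yields no clusters", {
  tbl <- tibble::tibble(frame = integer(0), x_nm = numeric(0),
                        y_nm = numeric(0))
  expect_identical(nrow(detect_spatial_clusters(tbl)), 0L)
})

test_that("two well-separated point masses give two full clusters", {
  tbl <- tibble::tibble(
    frame = rep(0:49, 2),
    x_nm = rep(c(1000, 11000), each = 50),
    y_nm = rep(c(1000, 11000), each = 50)
  )
  cl <- detect_spatial_clusters(
    tbl, spatial_config(neighborhood_radius_nm = 100, min_localizations = 10)
  )
  expect_identical(nrow(cl), 2L)
  expect_identical(cl$n, c(50L, 50L))
  expect_identical(sort(unlist(cl$member_rows)), 1:100)
})

test_that("size classification follows the 200-nm boundary", {
  expect_identical(classify_cluster_size(150, 200), "small")
  expect_identical(classify_cluster_size(350, 200), "large")
  expect_identical(classify_cluster_size(200, 200), "large")
  expect_error(classify_cluster_size(-1), "diameter")
})

test_that("cluster counts add up and handle empty input", {
  expect_identical(
    summarize_cluster_counts(tibble::tibble(size_class = character(0))),
    tibble::tibble(n_small = 0L, n_large = 0L, n_total = 0L)
  )
  counts <- summarize_cluster_counts(
    tibble::tibble(size_class = c("small", "small", "large"))
  )
  expect_identical(counts$n_small, 2L)
  expect_identical(counts$n_large, 1L)
  expect_identical(counts$n_total, counts$n_small + counts$n_large)
})

test_that("memberships partition the assigned detections and survive row shuffles", {
  sim <- small_live_table(seed = 21)
  cl <- detect_spatial_clusters(sim$table)
  members <- unlist(cl$member_rows)
  expect_identical(anyDuplicated(members), 0L)

  perm <- withr::with_seed(1, sample.int(nrow(sim$table)))
  shuffled <- sim$table[perm, ]
  cl2 <- detect_spatial_clusters(shuffled)
  sets1 <- lapply(cl$member_rows, function(r) {
    sort(paste(sim$table$frame[r], round(sim$table$x_nm[r], 6)))
  })
  sets2 <- lapply(cl2$member_rows, function(r) {
    sort(paste(shuffled$frame[r], round(shuffled$x_nm[r], 6)))
  })
  expect_setequal(sapply(sets1, paste, collapse = "|"),
                  sapply(sets2, paste, collapse = "|"))
})

test_that("raising the size threshold never decreases the small-cluster count", {
  sim <- small_live_table(seed = 4)
  cl <- detect_spatial_clusters(sim$table)
  thresholds <- c(50, 100, 200, 400, 800)
  n_small <- sapply(thresholds, function(th) {
    sum(classify_cluster_size(cl$diameter_nm, th) == "small")
  })
  expect_true(all(diff(n_small) >= 0))
})

test_that("simulated clusters are recovered from the localizations", {
  hits <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    sim <- small_live_table(seed = seed, n_clusters = 8)
    cl <- detect_spatial_clusters(sim$table)
    rec <- recovered_truth_clusters(sim$table, cl)
    if (length(rec) == nrow(sim$specs)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("small and large simulated clusters are counted within 10%", {
  acq <- acquisition_params()
  n_small_true <- 6L
  n_large_true <- 3L
  # well-separated centers on a grid; 20-nm-sigma clusters sit safely below
  # the 200-nm boundary, 120-nm-sigma clusters safely above it
  centers <- expand.grid(x = c(4000, 10000, 16000),
                         y = c(4000, 10000, 16000))
  got_small <- integer(0)
  for (seed in 1:8) {
    specs <- withr::with_seed(seed, cluster_specs(
      center_x_nm = centers$x + runif(9, -500, 500),
      center_y_nm = centers$y + runif(9, -500, 500),
      radius_nm = c(rep(20, n_small_true), rep(120, n_large_true)),
      t_on_s = runif(9, 5, 80),
      lifetime_s = runif(9, 6, 12),
      n_molecules = c(rep(30, n_small_true), rep(150, n_large_true)),
      acq = acq
    ))
    tbl <- simulate_live_cell(acq, live_photophysics(), specs,
                              background_rate_hz = 50, seed = seed)
    # linking radius and minimum count sized to the sparser 120-nm clusters
    # so their fringes are not split off as spurious small clusters
    cl <- detect_spatial_clusters(
      tbl, spatial_config(neighborhood_radius_nm = 75,
                          min_localizations = 30)
    )
    got_small <- c(got_small, summarize_cluster_counts(cl)$n_small)
  }
  expect_lt(abs(mean(got_small) - n_small_true) / n_small_true, 0.1)
})
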