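fake_fits <- function(tau, r2 = rep(0.99, length(tau))) {
  tibble::tibble(tau_s = tau, r_squared = r2)
}

test_that("the R-squared gate is inclusive at its threshold and monotone", {
  fits <- fake_fits(c(1, 2, 3), r2 = c(0.98, 0.97, 0.999))
  kept <- gate_by_r2(fits, 0.98)
  expect_identical(kept$tau_s, c(1, 3))

  withr::with_seed(5, {
    for (rep in 1:25) {
      fits <- fake_fits(runif(50), r2 = runif(50, 0.9, 1))
      n_loose <- nrow(gate_by_r2(fits, 0.9))
      n_tight <- nrow(gate_by_r2(fits, 0.98))
      expect_gte(n_loose, n_tight)
    }
  })
})

test_that("burst-count subsampling is seeded, order-preserving, and warns when short", {
  x <- seq_len(3000)
  s1 <- subsample_bursts(x, 2500, seed = 4)
  s2 <- subsample_bursts(x, 2500, seed = 4)
  expect_identical(s1, s2)
  expect_length(s1, 2500)
  expect_true(!is.unsorted(s1))

  expect_warning(out <- subsample_bursts(1:100, 2500, seed = 1),
                 class = "tcpalm_subsample_short")
  expect_identical(out, 1:100)
})

test_that("the frequency filter prunes sparse bins but never the modal bin", {
  # bin counts 10 / 50 / 8 / 2 with 20% threshold: keep the 10 and 50 bins
  taus <- c(runif(10, 0, 2), runif(50, 2, 4), runif(8, 4, 6), runif(2, 6, 8))
  kept <- frequency_filter(taus, bin_width_s = 2, freq_fraction = 0.2)
  expect_length(kept, 60)
  expect_true(all(kept < 4))

  expect_length(frequency_filter(runif(5, 0, 1), 2, 0.2), 5)
  expect_length(frequency_filter(numeric(0), 2, 0.2), 0)

  withr::with_seed(8, {
    for (rep in 1:100) {
      taus <- rexp(sample(5:200, 1), rate = 1 / 8)
      got <- frequency_filter(taus, 2, 0.2)
      expect_identical(got, oracle_frequency_filter(taus, 2, 0.2))
      modal <- as.numeric(names(which.max(table(floor(taus / 2)))))
      expect_true(any(floor(got / 2) == modal))
    }
  })
})

test_that("live/fixed discrimination is strict at 20 s", {
  expect_identical(classify_live_fixed(5.86), "live_like")
  expect_identical(classify_live_fixed(25), "fixed_like")
  expect_identical(classify_live_fixed(20), "fixed_like")
  expect_error(classify_live_fixed(-1), "tau")
})

test_that("the gate ledger conserves counts and is idempotent", {
  withr::with_seed(31, {
    fits <- fake_fits(c(rexp(400, 1 / 6), runif(50, 30, 90)),
                      r2 = runif(450, 0.9, 1))
  })
  cfg <- filter_config(n_bursts_norm = 300, subsample_seed = 2)
  set1 <- apply_all_gates(fits, cfg, condition = "demo")
  prov <- lifetime_provenance(set1)
  expect_identical(
    prov$n_input,
    prov$dropped_r2 + prov$dropped_subsample + prov$dropped_frequency +
      prov$dropped_class + prov$n_retained
  )
  # a second pass through the ledger must drop nothing
  set2 <- apply_all_gates(
    dplyr::select(tibble::as_tibble(set1), -"class"), cfg, condition = "demo"
  )
  expect_equal(set2$tau_s, set1$tau_s)

  # class filtering drops exactly the other class
  live_only <- apply_all_gates(fits, cfg, condition = "demo",
                               class_filter = "live_like")
  expect_true(all(live_only$tau_s < 20))
  prov2 <- lifetime_provenance(live_only)
  expect_identical(prov2$n_retained + prov2$dropped_class, prov$n_retained)
})

test_that("empty input yields an empty set with zero provenance", {
  set <- apply_all_gates(fake_fits(numeric(0)), filter_config(),
                         condition = "none")
  expect_identical(nrow(set), 0L)
  prov <- lifetime_provenance(set)
  expect_identical(prov$n_input, 0L)
  expect_identical(prov$n_retained, 0L)
})
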