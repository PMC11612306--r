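# Independent oracles used to validate the package's implementations.
# Each is written as plainly as possible (explicit loops, exhaustive
# enumeration, dense grids) and shares no code path with the package.

# Gap splitter: walk the frame list and start a new burst whenever the gap
# to the previous detection exceeds the cutoff.
oracle_segment_bursts <- function(frames, cutoff) {
  if (length(frames) == 0L) return(list())
  bursts <- list()
  cur <- frames[1L]
  for (f in frames[-1L]) {
    if (f - cur[length(cur)] > cutoff) {
      bursts[[length(bursts) + 1L]] <- cur
      cur <- f
    } else {
      cur <- c(cur, f)
    }
  }
  bursts[[length(bursts) + 1L]] <- cur
  bursts
}

# Exhaustive rank-assignment enumeration for the two-sided rank-sum p-value
# (tie-free inputs only).
oracle_wilcoxon_p <- function(a, b) {
  n1 <- length(a)
  n <- n1 + length(b)
  r <- rank(c(a, b))
  obs_u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(utils::combn(n, n1), 2L, function(idx) {
    sum(r[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(us <= obs_u), mean(us >= obs_u)))
}

# Dense-grid least-squares fit of the same cumulative-trace model
# (sigmoid + bounded linear background, amplitude/baseline profiled by
# linear least squares at each grid node); returns the 10-90% rise time.
oracle_grid_fit_tau <- function(trace, n_grid = 120) {
  t <- trace$time_s
  y <- trace$cum_count
  t1 <- t[1L]
  span <- diff(range(t))
  n <- max(y)
  b_max <- 0.2 * n / span
  best <- c(Inf, NA, NA)
  for (t0 in seq(min(t), max(t), length.out = n_grid)) {
    for (w in exp(seq(log(span / 300), log(2 * span),
                      length.out = n_grid))) {
      phi <- pnorm((t - t0) / w)
      tt <- t - t1
      cf <- tryCatch(qr.solve(cbind(phi, tt), y),
                     error = function(e) c(0, 0))
      bb <- min(max(cf[2L], 0), b_max)
      amp <- min(max(sum(phi * (y - bb * tt)) / sum(phi * phi), 1e-8),
                 1.5 * n)
      sse <- sum((y - amp * phi - bb * tt)^2)
      if (sse < best[1L]) best <- c(sse, t0, w)
    }
  }
  2 * qnorm(0.9) * best[3L]
}

# Loop-based histogram prune for the modal-frequency filter.
oracle_frequency_filter <- function(taus, bin_width, frac) {
  if (length(taus) == 0L) return(taus)
  bins <- floor(taus / bin_width)
  counts <- sapply(unique(bins), function(b) sum(bins == b))
  names(counts) <- unique(bins)
  threshold <- frac * max(counts)
  keep <- logical(length(taus))
  for (i in seq_along(taus)) {
    keep[i] <- counts[[as.character(bins[i])]] >= threshold
  }
  taus[keep]
}

# Small live-cell table for tests that do not need the full preset.
small_live_table <- function(seed, n_clusters = 5, lifetime_range_s = c(4, 12),
                             background_rate_hz = 50,
                             acq = acquisition_params()) {
  specs <- live_cluster_specs(n_clusters = n_clusters,
                              lifetime_range_s = lifetime_range_s,
                              acq = acq, seed = seed)
  list(
    specs = specs,
    table = simulate_live_cell(acq, live_photophysics(), specs,
                               background_rate_hz = background_rate_hz,
                               seed = seed)
  )
}

# Fraction of true clusters recovered: a truth cluster counts as recovered
# when some detected cluster's members are mostly that cluster's detections.
recovered_truth_clusters <- function(table, clusters) {
  hits <- integer(0)
  for (i in seq_len(nrow(clusters))) {
    ids <- table$truth_cluster_id[clusters$member_rows[[i]]]
    ids <- ids[ids > 0]
    if (length(ids) == 0L) next
    major <- as.integer(names(which.max(table(ids))))
    if (sum(ids == major) > 0.5 * clusters$n[i]) hits <- c(hits, major)
  }
  unique(hits)
}
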