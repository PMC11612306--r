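# End-to-end orchestration: (simulate | read) -> spatial clusters ->
# temporal bursts + cumulative fits -> gating ledger -> summaries and
# pairwise rank tests. Everything is seeded and echoed for provenance.

# Small deterministic fingerprint of the serialized config (polynomial hash
# mod 2^31 - 1), referenced by every output file.
config_fingerprint <- function(config) {
  s <- as.character(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                                     force = TRUE, null = "null"))
  h <- 0
  m <- 2147483647
  for (code in utf8ToInt(s)) {
    h <- (h * 131 + code) %% m
  }
  sprintf("%08x", as.integer(h))
}

#' Assemble a pipeline run configuration
#'
#' @param conditions A named list; each element describes one condition's
#'   data source as `list(type = "simulate_live", n_clusters =,
#'   lifetime_range_s =, n_molecules =, background_rate_hz =)`,
#'   `list(type = "simulate_fixed", n_molecules =)`, or
#'   `list(type = "file", path =)`. Unset simulation fields fall back to the
#'   presets.
#' @param acquisition An [acquisition_params()].
#' @param spatial A [spatial_config()].
#' @param tcpalm A [tcpalm_config()].
#' @param filter A [filter_config()].
#' @param class_filter Passed to [apply_all_gates()]; use `"live_like"` when
#'   comparing live-cell conditions.
#' @param comparisons List of label pairs to compare; `NULL` compares all
#'   pairs in order.
#' @param seed Global integer seed; per-condition seeds are derived from it.
#' @param output_dir Optional directory the report bundle is written to.
#' @return An object of class `tcpalm_run_config`.
#' @seealso [run_tcpalm_pipeline()], [read_run_config()]
#' @export
run_config <- function(conditions,
                       acquisition = acquisition_params(),
                       spatial = spatial_config(),
                       tcpalm = tcpalm_config(),
                       filter = filter_config(),
                       class_filter = "none",
                       comparisons = NULL,
                       seed = 1L,
                       output_dir = NULL) {
  if (length(conditions) == 0L || is.null(names(conditions)) ||
      any(names(conditions) == "")) {
    abort("`conditions` must be a non-empty named list.")
  }
  stopifnot(inherits(acquisition, "acquisition_params"),
            inherits(spatial, "spatial_config"),
            inherits(tcpalm, "tcpalm_config"),
            inherits(filter, "filter_config"))
  structure(
    list(
      conditions = conditions,
      acquisition = acquisition,
      spatial = spatial,
      tcpalm = tcpalm,
      filter = filter,
      class_filter = class_filter,
      comparisons = comparisons,
      seed = as.integer(seed),
      output_dir = output_dir
    ),
    class = "tcpalm_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Section and key names match the constructor arguments of
#' [acquisition_params()], [spatial_config()], [tcpalm_config()] and
#' [filter_config()] verbatim; omitted keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `tcpalm_run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build <- function(ctor, section) {
    do.call(ctor, raw[[section]] %||% list())
  }
  run_config(
    conditions = raw$conditions,
    acquisition = build(acquisition_params, "acquisition"),
    spatial = build(spatial_config, "spatial"),
    tcpalm = build(tcpalm_config, "tcpalm"),
    filter = build(filter_config, "filter"),
    class_filter = raw$class_filter %||% "none",
    comparisons = raw$comparisons,
    seed = raw$seed %||% 1L,
    output_dir = raw$output_dir
  )
}

materialize_condition <- function(src, cfg, seed) {
  acq <- cfg$acquisition
  type <- src$type %||% "simulate_live"
  if (type == "file") {
    return(read_localizations(src$path))
  }
  if (type == "simulate_fixed") {
    phot <- src$photophysics %||% fixed_photophysics()
    return(simulate_fixed_cell(acq, phot,
                               n_molecules = src$n_molecules %||% 200,
                               seed = seed))
  }
  phot <- src$photophysics %||% live_photophysics()
  clusters <- src$clusters %||% live_cluster_specs(
    n_clusters = src$n_clusters %||% 10,
    lifetime_range_s = src$lifetime_range_s %||% c(4, 12),
    radius_nm = src$radius_nm %||% 60,
    n_molecules = src$n_molecules %||% 30,
    acq = acq,
    seed = seed
  )
  simulate_live_cell(acq, phot, clusters,
                     background_rate_hz = src$background_rate_hz %||% 50,
                     seed = seed)
}

#' Run the full tcPALM pipeline
#'
#' For every condition: materialize its localization table (simulation or
#' file), detect spatial clusters, segment and fit temporal bursts, and
#' apply the gating ledger; then summarize per condition and run the
#' unpaired two-sided Wilcoxon rank-sum test for each requested comparison.
#' Burst-count normalization uses the smaller of the configured target and
#' the smallest per-condition post-R-squared burst count, so compared
#' conditions always carry equal weight. Identical config and seed reproduce
#' the report (and its serialized bundle) exactly.
#'
#' @param cfg A `tcpalm_run_config` from [run_config()] or
#'   [read_run_config()].
#' @return A `tcpalm_report`: list with `clusters`, `fits`, `lifetimes` (a
#'   bound `lifetime_set`), `provenance` (per condition), `summaries`,
#'   `comparisons`, `config_hash`, `seed`. If `cfg$output_dir` is set the
#'   bundle is also written there via [write_report_bundle()].
#' @export
run_tcpalm_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "tcpalm_run_config"))
  labels <- names(cfg$conditions)
  seeds <- cfg$seed + 7919L * seq_along(labels)

  tables <- purrr::map2(cfg$conditions, seeds,
                        function(src, s) materialize_condition(src, cfg, s))

  clusters <- purrr::map(tables, detect_spatial_clusters, cfg = cfg$spatial)
  fits <- purrr::map2(tables, clusters, fit_cluster_lifetimes,
                      cfg = cfg$tcpalm)

  post_r2 <- vapply(fits, function(f) nrow(gate_by_r2(f, cfg$filter$r2_min)),
                    integer(1))
  nonzero <- post_r2[post_r2 > 0L]
  n_target <- min(cfg$filter$n_bursts_norm,
                  if (length(nonzero)) min(nonzero) else cfg$filter$n_bursts_norm)

  gated <- purrr::map2(fits, labels, function(f, lab) {
    apply_all_gates(f, cfg$filter, condition = lab,
                    class_filter = cfg$class_filter, n_target = n_target)
  })
  provenance <- purrr::map(gated, lifetime_provenance)
  lifetimes <- dplyr::bind_rows(gated)
  class(lifetimes) <- c("lifetime_set", class(tibble::tibble()))

  summaries <- summarize_lifetimes(lifetimes)
  if (inherits(summaries, "tcpalm_no_data")) {
    summaries <- tibble::tibble(
      condition = character(0), n_clusters = integer(0),
      median_tau_s = numeric(0), mad_s = numeric(0), mean_tau_s = numeric(0),
      sd_s = numeric(0), sem_s = numeric(0)
    )
  }

  pairs <- cfg$comparisons
  if (is.null(pairs) && length(labels) >= 2L) {
    pairs <- utils::combn(labels, 2L, simplify = FALSE)
  }
  comparisons <- purrr::map_dfr(pairs, function(p) {
    a <- lifetimes$tau_s[lifetimes$condition == p[[1L]]]
    b <- lifetimes$tau_s[lifetimes$condition == p[[2L]]]
    if (length(a) == 0L || length(b) == 0L) return(NULL)
    wilcoxon_rank_test(a, b, label_a = p[[1L]], label_b = p[[2L]])
  })

  cluster_table <- purrr::imap_dfr(clusters, function(cl, lab) {
    if (nrow(cl) == 0L) return(NULL)
    dplyr::mutate(dplyr::select(cl, -"member_rows"), condition = lab,
                  .before = 1L)
  })
  fit_table <- purrr::imap_dfr(fits, function(f, lab) {
    if (nrow(f) == 0L) return(NULL)
    dplyr::mutate(f, condition = lab, .before = 1L)
  })

  config_echo <- list(
    conditions = purrr::map(cfg$conditions, function(s) {
      s$clusters <- NULL # spec tibbles are echoed via the sidecar instead
      s
    }),
    acquisition = unclass(cfg$acquisition),
    spatial = unclass(cfg$spatial),
    tcpalm = unclass(cfg$tcpalm),
    filter = unclass(cfg$filter),
    class_filter = cfg$class_filter,
    seed = cfg$seed
  )

  report <- structure(
    list(
      clusters = cluster_table,
      fits = fit_table,
      lifetimes = lifetimes,
      provenance = provenance,
      summaries = summaries,
      comparisons = comparisons,
      config = config_echo,
      config_hash = config_fingerprint(config_echo),
      seed = cfg$seed
    ),
    class = "tcpalm_report"
  )
  if (!is.null(cfg$output_dir)) {
    write_report_bundle(report, cfg$output_dir)
  }
  report
}

#' @export
print.tcpalm_report <- function(x, ...) {
  cat(sprintf("<tcpalm_report> seed %d, config %s\n", x$seed, x$config_hash))
  cat(sprintf("  %d spatial clusters, %d fitted bursts, %d gated lifetimes\n",
              nrow(x$clusters), nrow(x$fits), nrow(x$lifetimes)))
  if (nrow(x$summaries)) {
    print(x$summaries)
  }
  if (nrow(x$comparisons)) {
    print(x$comparisons)
  }
  invisible(x)
}

#' @rdname run_tcpalm_pipeline
#' @param x A `tcpalm_report`.
#' @param ... Unused.
#' @method tidy tcpalm_report
#' @export
tidy.tcpalm_report <- function(x, ...) {
  x$summaries
}

#' @rdname run_tcpalm_pipeline
#' @method glance tcpalm_report
#' @export
glance.tcpalm_report <- function(x, ...) {
  tibble::tibble(
    n_conditions = length(x$provenance),
    n_clusters = nrow(x$clusters),
    n_fitted_bursts = nrow(x$fits),
    n_gated = nrow(x$lifetimes),
    config_hash = x$config_hash,
    seed = x$seed
  )
}

#' Serialize a pipeline report to disk
#'
#' Writes `clusters.tsv`, `bursts.tsv`, `lifetimes.tsv` and `summary.json`
#' (summaries, comparisons, per-condition gate provenance, config echo,
#' seed, config hash) into `dir`. Rewriting the same report produces
#' byte-identical files.
#'
#' @param report A `tcpalm_report`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(report, dir) {
  stopifnot(inherits(report, "tcpalm_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    dplyr::mutate(df, config_hash = report$config_hash, seed = report$seed)
  }
  readr::write_tsv(stamp(report$clusters), file.path(dir, "clusters.tsv"),
                   progress = FALSE)
  readr::write_tsv(stamp(report$fits), file.path(dir, "bursts.tsv"),
                   progress = FALSE)
  readr::write_tsv(stamp(tibble::as_tibble(report$lifetimes)),
                   file.path(dir, "lifetimes.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(
      config_hash = report$config_hash,
      seed = report$seed,
      summaries = report$summaries,
      comparisons = report$comparisons,
      gate_provenance = report$provenance,
      config = report$config
    ),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE
  )
  invisible(dir)
}
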