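# Synthetic localization-data generator.
#
# Live mode: transient clusters with finite ON-windows recruit immobile
# molecules that blink; plus spatially/temporally uniform background.
# Fixed mode: immobile emitters blinking over the whole movie, the
# photophysics-only control.

# Detection frames for one molecule alternating geometric bursts and dark
# gaps between first_frame and last_frame (inclusive). `lead_dark` prepends
# a dark gap so emitters do not all light up at their recruitment frame.
blink_train <- function(first_frame, last_frame, phot, frame_time_s,
                        lead_dark = FALSE) {
  if (last_frame < first_frame) return(integer(0))
  p_burst <- 1 / phot$mean_burst_frames
  p_dark <- 1 / phot$mean_dark_frames
  p_detect <- min(1, phot$detection_rate_hz * frame_time_s)

  span <- last_frame - first_frame + 1L
  n_bursts <- 1L + rgeom(1L, min(1, 1 / phot$bursts_per_molecule_mean))
  # each burst+gap cycle takes >= 2 frames; never draw more than can fit
  n_bursts <- min(n_bursts, span %/% 2L + 1L)
  if (n_bursts < 1L) return(integer(0))

  lens <- 1L + rgeom(n_bursts, p_burst)
  gaps <- 1L + rgeom(n_bursts, p_dark)
  offset <- if (lead_dark) gaps[n_bursts] else 0L # reuse last (unused) gap
  starts <- first_frame + offset +
    cumsum(c(0L, (lens + gaps)[-n_bursts]))
  keep <- starts <= last_frame
  if (!any(keep)) return(integer(0))
  starts <- starts[keep]
  lens <- pmin(lens[keep], last_frame - starts + 1L)

  frames <- sequence(lens, from = starts)
  if (p_detect < 1) {
    frames <- frames[runif(length(frames)) < p_detect]
  }
  as.integer(frames)
}

new_localization_table <- function(frame, x_nm, y_nm, uncertainty_nm,
                                   truth_cluster_id, acq) {
  tbl <- tibble::tibble(
    frame = as.integer(frame),
    x_nm = pmin(pmax(x_nm, 0), acq$field_size_nm),
    y_nm = pmin(pmax(y_nm, 0), acq$field_size_nm),
    uncertainty_nm = uncertainty_nm,
    truth_cluster_id = as.integer(truth_cluster_id)
  )
  dplyr::arrange(tbl, .data$frame, .data$x_nm, .data$y_nm)
}

#' Simulate a live-cell tcPALM localization table
#'
#' Generates one detection per table row (frame, x, y) for a field containing
#' transient clusters. Each cluster recruits `n_molecules` immobile emitters
#' at times uniform over its ON-window; molecule positions are Gaussian
#' around the cluster center with sigma `radius_nm`, every detection adds
#' independent localization error, and each molecule emits geometric
#' burst/dark blink trains truncated to the ON-window. Background detections
#' are uniform in space and time. The `truth_cluster_id` column carries the
#' ground truth (`-1` for background) and is absent from real data files.
#'
#' @param acq An [acquisition_params()] object.
#' @param phot A [photophysics_params()] object.
#' @param clusters A cluster spec tibble from [cluster_specs()] or
#'   [live_cluster_specs()]; may have zero rows.
#' @param background_rate_hz Expected background detections per second over
#'   the whole field (>= 0).
#' @param seed Integer seed; identical inputs and seed give an identical
#'   table.
#'
#' @return A localization table: tibble with columns `frame` (0-based),
#'   `x_nm`, `y_nm`, `uncertainty_nm`, `truth_cluster_id`, sorted by frame
#'   then x then y.
#' @seealso [simulate_fixed_cell()], [write_localizations()]
#' @examples
#' acq <- acquisition_params()
#' tbl <- simulate_live_cell(acq, live_photophysics(),
#'                           live_cluster_specs(n_clusters = 2, acq = acq),
#'                           background_rate_hz = 10, seed = 7)
#' dplyr::count(tbl, truth_cluster_id)
#' @export
simulate_live_cell <- function(acq = acquisition_params(),
                               phot = live_photophysics(),
                               clusters = live_cluster_specs(acq = acq),
                               background_rate_hz = 50,
                               seed = 1L) {
  stopifnot(inherits(acq, "acquisition_params"),
            inherits(phot, "photophysics_params"))
  if (!is.numeric(background_rate_hz) || background_rate_hz < 0) {
    abort("`background_rate_hz` must be >= 0.")
  }
  validate_cluster_specs(clusters, acq)
  dt <- acq$frame_time_s

  withr::with_seed(as.integer(seed), {
    parts <- purrr::pmap(clusters, function(cluster_id, center_x_nm,
                                            center_y_nm, radius_nm, t_on_s,
                                            lifetime_s, n_molecules, ...) {
      f_lo <- as.integer(ceiling(t_on_s / dt))
      f_hi <- as.integer(floor((t_on_s + lifetime_s) / dt))
      f_hi <- min(f_hi, acq$n_frames - 1L)
      if (n_molecules == 0L || f_hi < f_lo) {
        return(NULL)
      }
      recruit <- sort(sample.int(f_hi - f_lo + 1L, n_molecules,
                                 replace = TRUE)) + f_lo - 1L
      mol_x <- center_x_nm + rnorm(n_molecules, sd = radius_nm)
      mol_y <- center_y_nm + rnorm(n_molecules, sd = radius_nm)
      frames <- purrr::map(seq_len(n_molecules), function(m) {
        blink_train(recruit[m], f_hi, phot, dt)
      })
      n_per <- lengths(frames)
      frames <- unlist(frames, use.names = FALSE)
      if (length(frames) == 0L) return(NULL)
      tibble::tibble(
        frame = frames,
        x_nm = rep(mol_x, n_per) + rnorm(length(frames),
                                         sd = acq$localization_sigma_nm),
        y_nm = rep(mol_y, n_per) + rnorm(length(frames),
                                         sd = acq$localization_sigma_nm),
        truth_cluster_id = cluster_id
      )
    })

    n_bg <- rpois(1L, background_rate_hz * total_time_s(acq))
    bg <- tibble::tibble(
      frame = sample.int(acq$n_frames, n_bg, replace = TRUE) - 1L,
      x_nm = runif(n_bg, 0, acq$field_size_nm),
      y_nm = runif(n_bg, 0, acq$field_size_nm),
      truth_cluster_id = -1L
    )
    all <- dplyr::bind_rows(c(parts, list(bg)))
    new_localization_table(
      all$frame, all$x_nm, all$y_nm,
      uncertainty_nm = rep(acq$localization_sigma_nm, nrow(all)),
      truth_cluster_id = all$truth_cluster_id, acq = acq
    )
  })
}

#' Simulate a fixed-cell (photophysics-only) localization table
#'
#' Places `n_molecules` immobile emitters uniformly in the field; each blinks
#' per the photophysics parameters across the whole acquisition, with no
#' ON-window truncation. Apparent temporal structure in the result is purely
#' single-molecule photophysics, which is the control used to calibrate the
#' live/fixed correlation-time threshold.
#'
#' @inheritParams simulate_live_cell
#' @param n_molecules Number of emitters (>= 0).
#' @return A localization table (see [simulate_live_cell()]); each molecule's
#'   rows carry `truth_cluster_id` = molecule index.
#' @export
simulate_fixed_cell <- function(acq = acquisition_params(),
                                phot = fixed_photophysics(),
                                n_molecules = 200,
                                seed = 1L) {
  stopifnot(inherits(acq, "acquisition_params"),
            inherits(phot, "photophysics_params"))
  n_molecules <- as.integer(n_molecules)
  if (is.na(n_molecules) || n_molecules < 0L) {
    abort("`n_molecules` must be >= 0.")
  }
  dt <- acq$frame_time_s
  withr::with_seed(as.integer(seed), {
    mol_x <- runif(n_molecules, 0, acq$field_size_nm)
    mol_y <- runif(n_molecules, 0, acq$field_size_nm)
    frames <- purrr::map(seq_len(n_molecules), function(m) {
      blink_train(0L, acq$n_frames - 1L, phot, dt, lead_dark = TRUE)
    })
    n_per <- lengths(frames)
    frames <- unlist(frames, use.names = FALSE)
    n <- length(frames)
    new_localization_table(
      frames,
      rep(mol_x, n_per) + rnorm(n, sd = acq$localization_sigma_nm),
      rep(mol_y, n_per) + rnorm(n, sd = acq$localization_sigma_nm),
      uncertainty_nm = rep(acq$localization_sigma_nm, n),
      truth_cluster_id = rep(seq_len(n_molecules), n_per),
      acq = acq
    )
  })
}
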