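#' Acquisition parameters
#'
#' Describes a PALM movie: number of camera frames, exposure (frame) time,
#' size of the square field of view, and the localization precision of the
#' detection step. The defaults reproduce a standard live-cell tcPALM
#' acquisition: 10,000 frames at 10 ms exposure, i.e. 100 s total.
#'
#' @param n_frames Number of camera frames (>= 1).
#' @param frame_time_s Seconds per frame (> 0); 0.01 corresponds to 10 ms
#'   exposure.
#' @param field_size_nm Side length of the square imaging field, in nm.
#' @param localization_sigma_nm Standard deviation of the (isotropic)
#'   localization error, in nm.
#'
#' @return An object of class `acquisition_params` (a validated list).
#'   `total_time_s(acq)` gives the acquisition duration
#'   `n_frames * frame_time_s`.
#' @examples
#' acq <- acquisition_params()
#' total_time_s(acq) # 100 s
#' @export
acquisition_params <- function(n_frames = 10000L,
                               frame_time_s = 0.01,
                               field_size_nm = 20000,
                               localization_sigma_nm = 15) {
  n_frames <- as.integer(n_frames)
  if (length(n_frames) != 1L || is.na(n_frames) || n_frames < 1L) {
    abort("`n_frames` must be a single integer >= 1.")
  }
  if (!is.numeric(frame_time_s) || length(frame_time_s) != 1L || frame_time_s <= 0) {
    abort("`frame_time_s` must be a single positive number.")
  }
  if (!is.numeric(field_size_nm) || field_size_nm <= 0) {
    abort("`field_size_nm` must be positive.")
  }
  if (!is.numeric(localization_sigma_nm) || localization_sigma_nm < 0) {
    abort("`localization_sigma_nm` must be non-negative.")
  }
  structure(
    list(
      n_frames = n_frames,
      frame_time_s = frame_time_s,
      field_size_nm = field_size_nm,
      localization_sigma_nm = localization_sigma_nm
    ),
    class = "acquisition_params"
  )
}

#' @rdname acquisition_params
#' @param acq An `acquisition_params` object.
#' @export
total_time_s <- function(acq) {
  stopifnot(inherits(acq, "acquisition_params"))
  acq$n_frames * acq$frame_time_s
}

#' @export
print.acquisition_params <- function(x, ...) {
  cat(sprintf(
    "<acquisition_params> %d frames x %g s = %g s; field %g nm; sigma_loc %g nm\n",
    x$n_frames, x$frame_time_s, total_time_s(x), x$field_size_nm,
    x$localization_sigma_nm
  ))
  invisible(x)
}

#' Single-fluorophore photophysics parameters
#'
#' Parameterizes Dendra2-like blinking: an activated emitter alternates
#' between fluorescent bursts and dark gaps (both geometrically distributed
#' in frames, i.e. memoryless), re-activating a geometric number of times
#' before irreversible bleaching. While fluorescent, detections are thinned
#' to `detection_rate_hz`.
#'
#' `live_photophysics()` and `fixed_photophysics()` return the presets used
#' by the simulator: live-cell emitters blink briefly against cluster
#' lifetimes of several seconds, while fixed-cell emitters re-activate
#' essentially without bleaching so their detections span the whole
#' acquisition (the photophysics-only control).
#'
#' @param mean_burst_frames Mean length of one fluorescent burst, frames (> 0).
#' @param mean_dark_frames Mean dark gap between bursts of one emitter,
#'   frames (> 0).
#' @param bursts_per_molecule_mean Mean number of bursts before bleaching
#'   (> 0).
#' @param detection_rate_hz Expected detections per second from an emitter
#'   while it is fluorescent; at 10 ms frames, 100 Hz means every burst frame
#'   yields a detection.
#'
#' @return An object of class `photophysics_params`.
#' @export
photophysics_params <- function(mean_burst_frames = 3,
                                mean_dark_frames = 30,
                                bursts_per_molecule_mean = 3,
                                detection_rate_hz = 100) {
  vals <- c(mean_burst_frames, mean_dark_frames, bursts_per_molecule_mean,
            detection_rate_hz)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All photophysics parameters must be finite positive numbers.")
  }
  structure(
    list(
      mean_burst_frames = mean_burst_frames,
      mean_dark_frames = mean_dark_frames,
      bursts_per_molecule_mean = bursts_per_molecule_mean,
      detection_rate_hz = detection_rate_hz
    ),
    class = "photophysics_params"
  )
}

#' @rdname photophysics_params
#' @export
live_photophysics <- function() {
  photophysics_params(
    mean_burst_frames = 3,
    mean_dark_frames = 30,
    bursts_per_molecule_mean = 3,
    detection_rate_hz = 100
  )
}

#' @rdname photophysics_params
#' @export
fixed_photophysics <- function() {
  # Dark gaps kept well under the 100-frame blinking cutoff so that a fixed
  # emitter's detections merge into one temporal burst spanning the movie;
  # bleaching is effectively negligible over 10,000 frames.
  photophysics_params(
    mean_burst_frames = 1,
    mean_dark_frames = 10,
    bursts_per_molecule_mean = 2e4,
    detection_rate_hz = 100
  )
}

#' @export
print.photophysics_params <- function(x, ...) {
  cat(sprintf(
    "<photophysics_params> burst %g fr; dark %g fr; %g bursts/molecule; %g Hz in-burst\n",
    x$mean_burst_frames, x$mean_dark_frames, x$bursts_per_molecule_mean,
    x$detection_rate_hz
  ))
  invisible(x)
}

#' Cluster specifications for the live-cell simulator
#'
#' A cluster spec table has one row per transient cluster: its center, its
#' spatial extent (the Gaussian sigma of member molecule positions), the
#' start and duration of its ON-window (the ground-truth lifetime), and the
#' number of molecules recruited during the window.
#'
#' `cluster_specs()` builds and validates such a table against an
#' acquisition; `live_cluster_specs()` draws the default live preset:
#' `n_clusters` clusters of 60 nm sigma placed uniformly in the field (away
#' from the edges), with lifetimes uniform on `lifetime_range_s` and
#' ON-windows placed uniformly within the movie.
#'
#' @param center_x_nm,center_y_nm Cluster center coordinates, nm.
#' @param radius_nm Gaussian sigma of member positions, nm (> 0).
#' @param t_on_s ON-window start, seconds from acquisition start.
#' @param lifetime_s ON-window duration (ground-truth lifetime), seconds (> 0).
#' @param n_molecules Molecules recruited during the ON-window.
#' @param acq An `acquisition_params` object the specs must fit inside.
#'
#' @return A tibble with columns `cluster_id`, `center_x_nm`, `center_y_nm`,
#'   `radius_nm`, `t_on_s`, `lifetime_s`, `n_molecules`.
#' @export
cluster_specs <- function(center_x_nm, center_y_nm, radius_nm, t_on_s,
                          lifetime_s, n_molecules,
                          acq = acquisition_params()) {
  specs <- tibble::tibble(
    cluster_id = seq_along(center_x_nm),
    center_x_nm = as.numeric(center_x_nm),
    center_y_nm = as.numeric(center_y_nm),
    radius_nm = as.numeric(radius_nm),
    t_on_s = as.numeric(t_on_s),
    lifetime_s = as.numeric(lifetime_s),
    n_molecules = as.integer(n_molecules)
  )
  validate_cluster_specs(specs, acq)
  specs
}

validate_cluster_specs <- function(specs, acq) {
  t_total <- total_time_s(acq)
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    if (s$radius_nm <= 0 || s$lifetime_s <= 0 || s$n_molecules < 0) {
      abort(sprintf(
        "Cluster %d: radius_nm and lifetime_s must be > 0, n_molecules >= 0.", i
      ))
    }
    if (s$center_x_nm < 0 || s$center_x_nm > acq$field_size_nm ||
        s$center_y_nm < 0 || s$center_y_nm > acq$field_size_nm) {
      abort(sprintf("Cluster %d: center lies outside the imaging field.", i))
    }
    if (s$t_on_s < 0 || s$t_on_s + s$lifetime_s > t_total + 1e-9) {
      abort(sprintf(
        "Cluster %d: ON-window [%g, %g] s exceeds the acquisition (%g s).",
        i, s$t_on_s, s$t_on_s + s$lifetime_s, t_total
      ))
    }
  }
  invisible(specs)
}

#' @rdname cluster_specs
#' @param n_clusters Number of clusters in the preset.
#' @param lifetime_range_s Range the preset lifetimes are drawn from
#'   (uniformly); a single value gives constant lifetimes.
#' @param seed Integer seed; the preset is deterministic given the seed.
#' @export
live_cluster_specs <- function(n_clusters = 10,
                               lifetime_range_s = c(4, 12),
                               radius_nm = 60,
                               n_molecules = 30,
                               acq = acquisition_params(),
                               seed = 1L) {
  stopifnot(n_clusters >= 0)
  if (length(lifetime_range_s) == 1L) {
    lifetime_range_s <- rep(lifetime_range_s, 2L)
  }
  t_total <- total_time_s(acq)
  margin <- 5 * radius_nm + 200
  withr::with_seed(seed, {
    lifetime <- runif(n_clusters, lifetime_range_s[1], lifetime_range_s[2])
    t_on <- runif(n_clusters, 0, pmax(t_total - lifetime, 0))
    cluster_specs(
      center_x_nm = runif(n_clusters, margin, acq$field_size_nm - margin),
      center_y_nm = runif(n_clusters, margin, acq$field_size_nm - margin),
      radius_nm = rep(radius_nm, n_clusters),
      t_on_s = t_on,
      lifetime_s = lifetime,
      n_molecules = rep(n_molecules, n_clusters),
      acq = acq
    )
  })
}
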