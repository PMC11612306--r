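#' tcPALM temporal-analysis configuration
#'
#' @param blinking_cutoff_frames Maximum inter-detection gap (frames) merged
#'   into one temporal burst; gaps up to and including the cutoff merge. The
#'   conventional value is 100 frames: shorter cutoffs fragment traces into
#'   too few usable bursts for a reliable cumulative fit.
#' @param frame_time_s Seconds per frame.
#' @param min_burst_detections Minimum detections for a burst to be fitted.
#' @return An object of class `tcpalm_config`.
#' @export
tcpalm_config <- function(blinking_cutoff_frames = 100,
                          frame_time_s = 0.01,
                          min_burst_detections = 10) {
  if (blinking_cutoff_frames < 1) abort("`blinking_cutoff_frames` must be >= 1.")
  if (frame_time_s <= 0) abort("`frame_time_s` must be > 0.")
  if (min_burst_detections < 1) abort("`min_burst_detections` must be >= 1.")
  structure(
    list(
      blinking_cutoff_frames = as.integer(blinking_cutoff_frames),
      frame_time_s = frame_time_s,
      min_burst_detections = as.integer(min_burst_detections)
    ),
    class = "tcpalm_config"
  )
}

#' Segment a cluster's detection frames into temporal bursts
#'
#' A temporal burst is a maximal run of detections whose adjacent
#' inter-detection gaps are all at most `cutoff_frames` (inclusive: a gap
#' exactly equal to the cutoff still merges, because the cutoff is the
#' largest gap attributable to fluorophore blinking rather than cluster
#' disassembly).
#'
#' @param frames Sorted (ascending) integer detection frames of one spatial
#'   cluster.
#' @param cutoff_frames Maximum merged gap, frames (>= 1).
#' @return A tibble with one row per burst, ordered by `first_frame`:
#'   `burst_id`, `first_frame`, `last_frame`, `n_detections`, and
#'   `detection_frames` (list-column). The concatenation of
#'   `detection_frames` reproduces the input.
#' @examples
#' segment_temporal_bursts(c(0, 50, 151, 200), cutoff_frames = 100)
#' @export
segment_temporal_bursts <- function(frames, cutoff_frames = 100) {
  if (cutoff_frames < 1) abort("`cutoff_frames` must be >= 1.")
  empty <- tibble::tibble(
    burst_id = integer(0), first_frame = integer(0), last_frame = integer(0),
    n_detections = integer(0), detection_frames = list()
  )
  if (length(frames) == 0L) return(empty)
  if (is.unsorted(frames)) abort("`frames` must be sorted ascending.")
  frames <- as.integer(frames)

  burst <- cumsum(c(1L, as.integer(diff(frames) > cutoff_frames)))
  runs <- split(frames, burst)
  tibble::tibble(
    burst_id = seq_along(runs),
    first_frame = purrr::map_int(runs, 1L),
    last_frame = purrr::map_int(runs, function(r) r[length(r)]),
    n_detections = lengths(runs),
    detection_frames = unname(runs)
  )
}

#' Cumulative detection trace of a temporal burst
#'
#' Converts detection frames into the monotone step function "number of
#' detections up to time t", with t = 0 at acquisition start. Detections
#' sharing a frame are collapsed into a single step, so times are strictly
#' increasing and the final count equals the burst's detection count.
#'
#' @param burst A one-row tibble from [segment_temporal_bursts()], or a bare
#'   sorted integer vector of detection frames.
#' @param frame_time_s Seconds per frame.
#' @return A tibble with columns `time_s`, `cum_count`.
#' @examples
#' cumulative_trace(c(0, 1, 2), frame_time_s = 0.01)
#' @export
cumulative_trace <- function(burst, frame_time_s = 0.01) {
  frames <- if (is.data.frame(burst)) {
    stopifnot(nrow(burst) == 1L)
    burst$detection_frames[[1L]]
  } else {
    burst
  }
  if (length(frames) == 0L) {
    return(tibble::tibble(time_s = numeric(0), cum_count = numeric(0)))
  }
  if (is.unsorted(frames)) abort("detection frames must be sorted ascending.")
  counts <- cumsum(tabulate(match(frames, unique(frames))))
  tibble::tibble(
    time_s = unique(frames) * frame_time_s,
    cum_count = as.numeric(counts)
  )
}

#' Burst-count summary
#'
#' @param bursts A burst tibble ([segment_temporal_bursts()] output, possibly
#'   row-bound over clusters).
#' @return A one-row tibble with `n_bursts` and `total_detections`.
#' @export
burst_statistics <- function(bursts) {
  tibble::tibble(
    n_bursts = nrow(bursts),
    total_detections = if (nrow(bursts)) sum(bursts$n_detections) else 0L
  )
}
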