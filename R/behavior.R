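# Behavioral state segmentation, lap extraction, pupil preprocessing and state
# statistics, event-triggered averaging, and the object-discrimination index.

#' Segment locomotion and immobility epochs
#'
#' Splits a speed trace into locomotion ("run") and immobility ("rest")
#' epochs. A run epoch is a maximal interval of frames with speed at or above
#' `run_threshold` lasting at least `min_run_s`; a rest epoch is a maximal
#' interval with speed below the threshold. Supra-threshold bouts shorter than
#' `min_run_s` qualify as neither state: they fail the run duration criterion
#' but are not immobility either, so their frames are excluded from both
#' states (set `rest_includes_short_bouts = TRUE` to fold them into rest
#' instead).
#'
#' @param speed numeric vector of running speed per frame (cm/s).
#' @param frame_rate frames per second.
#' @param run_threshold speed threshold in cm/s (default 4).
#' @param min_run_s minimal run-epoch duration in seconds (default 2.5).
#' @param rest_includes_short_bouts logical; see above.
#' @return a data.frame with columns `start`, `end` (inclusive frame indices)
#'   and `state` (`"run"` or `"rest"`), sorted and non-overlapping.
#' @export
segment_locomotion <- function(speed, frame_rate, run_threshold = 4,
                               min_run_s = 2.5,
                               rest_includes_short_bouts = FALSE) {
  if (length(speed) == 0L) stop("empty speed vector")
  above <- speed >= run_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_frames <- ceiling(min_run_s * frame_rate)
  state <- ifelse(r$values,
                  ifelse(r$lengths >= min_frames, "run",
                         if (rest_includes_short_bouts) "rest" else "excluded"),
                  "rest")
  ep <- data.frame(start = starts, end = ends, state = state,
                   stringsAsFactors = FALSE)
  ep <- ep[ep$state != "excluded", , drop = FALSE]
  # merge adjacent same-state epochs (arises when short bouts fold into rest)
  if (nrow(ep) > 1L) {
    out <- ep[1L, , drop = FALSE]
    for (i in seq_len(nrow(ep))[-1L]) {
      j <- nrow(out)
      if (ep$state[i] == out$state[j] && ep$start[i] == out$end[j] + 1L) {
        out$end[j] <- ep$end[i]
      } else {
        out <- rbind(out, ep[i, , drop = FALSE])
      }
    }
    ep <- out
  }
  rownames(ep) <- NULL
  ep
}

#' Lap index from belt position
#'
#' Assigns a lap number to every frame. The lap counter starts at 0 and
#' increments at each wrap of the circular belt position from high to low
#' (detected as a negative position jump larger than half the belt).
#'
#' @param position numeric vector of belt position (cm, in `[0, belt_length)`).
#' @param belt_length belt length in cm.
#' @return a data.frame with per-frame columns `lap` (integer, from 0) and
#'   `pos` (within-lap position, cm).
#' @export
laps_from_position <- function(position, belt_length) {
  d <- diff(position)
  wraps <- c(FALSE, d < -belt_length / 2)
  data.frame(lap = cumsum(wraps), pos = position)
}

#' Preprocess a raw pupil-diameter trace
#'
#' Blink-contaminated frames are linearly interpolated, the trace is low-pass
#' filtered (zero-phase, 4th order) at `cutoff_hz`, resampled from the camera
#' rate to the imaging rate by linear interpolation, and normalized to its
#' mean (output mean = 1).
#'
#' @param pupil raw pupil diameter per camera frame.
#' @param blink binary vector marking blink/saccade frames to remove.
#' @param native_rate camera frame rate in Hz (must be >= 2 * cutoff).
#' @param target_rate output rate in Hz (default 15, the imaging rate).
#' @param cutoff_hz low-pass cutoff in Hz (default 4).
#' @return numeric vector of length `floor(length(pupil) * target_rate /
#'   native_rate)` with mean 1.
#' @export
preprocess_pupil <- function(pupil, blink = NULL, native_rate,
                             target_rate = 15, cutoff_hz = 4) {
  n <- length(pupil)
  if (n == 0L) stop("empty pupil trace")
  if (native_rate < 2 * cutoff_hz)
    stop("native_rate must be at least twice the low-pass cutoff")
  if (is.null(blink)) blink <- numeric(n)
  bad <- blink > 0 | !is.finite(pupil)
  if (all(bad)) stop("all pupil frames are blink-masked")
  if (mean(bad) > 0.5)
    warning("more than 50% of pupil frames are blink-masked")
  if (any(bad)) {
    ok <- which(!bad)
    pupil[bad] <- stats::approx(ok, pupil[ok], xout = which(bad),
                                rule = 2)$y
  }
  y <- lowpass_zerophase(pupil, cutoff_hz, native_rate)
  m <- floor(n * target_rate / native_rate)
  t_in <- (seq_len(n) - 1L) / native_rate
  t_out <- (seq_len(m) - 1L) / target_rate
  out <- stats::approx(t_in, y, xout = t_out, rule = 2)$y
  mu <- mean(out)
  if (mu == 0) stop("pupil trace has zero mean; cannot normalize")
  out / mu
}

#' Event-triggered average of a signal
#'
#' Averages `signal` in windows of `[-window_frames, +window_frames]` around
#' each event frame. Events whose window does not fit inside the recording are
#' dropped.
#'
#' @param signal numeric vector per frame.
#' @param event_frames integer frames to align on.
#' @param window_frames half-window in frames.
#' @return list with `lags` (frames, -w..w), `mean`, `sem` (zeros when n = 1),
#'   and `n` (events used).
#' @export
event_triggered_average <- function(signal, event_frames, window_frames) {
  nf <- length(signal)
  w <- as.integer(window_frames)
  ev <- event_frames[event_frames - w >= 1L & event_frames + w <= nf]
  if (length(ev) == 0L) stop("no events with a full window inside the recording")
  mat <- vapply(ev, function(f) signal[(f - w):(f + w)], numeric(2L * w + 1L))
  mat <- matrix(mat, nrow = 2L * w + 1L)
  mu <- rowMeans(mat)
  n <- length(ev)
  sem <- if (n > 1L) apply(mat, 1L, stats::sd) / sqrt(n) else numeric(2L * w + 1L)
  list(lags = -w:w, mean = mu, sem = sem, n = n)
}

#' Pupil diameter statistics by behavioral state
#'
#' Mean normalized pupil diameter and mean rate of diameter change during
#' locomotion epochs, during immobility epochs, and at network-event frames.
#' The network-event frame is the single frame of peak summed granule-cell
#' activity within the event window when `gc_activity` is supplied, otherwise
#' the event peak frame itself. The rate of change is the first difference
#' scaled by the frame rate, averaged per state.
#'
#' @param pupil preprocessed pupil trace (one sample per imaging frame).
#' @param epochs run/rest epochs from [segment_locomotion()].
#' @param ne_frames network-event peak frames.
#' @param frame_rate imaging rate in Hz.
#' @param gc_activity optional per-frame summed granule-cell activity; used to
#'   refine the event frame within `ne_window` frames around each event.
#' @param ne_window half-window (frames) for the peak-activity refinement.
#' @return data.frame with rows (run, rest, ne) and columns `state`,
#'   `mean_diameter`, `mean_rate`, `n_frames`.
#' @export
pupil_state_stats <- function(pupil, epochs, ne_frames, frame_rate,
                              gc_activity = NULL, ne_window = 1L) {
  if (is.null(pupil)) stop("pupil channel is absent")
  nf <- length(pupil)
  rate <- c(NA, diff(pupil)) * frame_rate
  ne_at <- as.integer(ne_frames)
  if (!is.null(gc_activity) && length(ne_at)) {
    ne_at <- vapply(ne_at, function(f) {
      idx <- max(1L, f - ne_window):min(nf, f + ne_window)
      idx[which.max(gc_activity[idx])]
    }, integer(1L))
  }
  one <- function(frames, label) {
    frames <- frames[frames >= 1L & frames <= nf]
    data.frame(state = label,
               mean_diameter = if (length(frames)) mean(pupil[frames]) else NA_real_,
               mean_rate = if (length(frames)) mean(rate[frames], na.rm = TRUE) else NA_real_,
               n_frames = length(frames))
  }
  rbind(one(frames_in_epochs(epochs, "run"), "run"),
        one(frames_in_epochs(epochs, "rest"), "rest"),
        one(ne_at, "ne"))
}

#' Object-exploration discrimination index
#'
#' `DI = (t_displaced - t_stationary) / (t_displaced + t_stationary)`, in
#' `[-1, 1]`; 0 indicates equal exploration of the two objects. Trials with
#' total exploration time below `min_total_s` are excluded rather than scored.
#'
#' @param t_displaced time exploring the displaced object (s).
#' @param t_stationary time exploring the non-displaced object (s).
#' @param min_total_s exclusion threshold on the total exploration time
#'   (default 4 s).
#' @return list with `di` (NA when excluded) and `excluded` (logical).
#' @export
discrimination_index <- function(t_displaced, t_stationary, min_total_s = 4) {
  if (t_displaced < 0 || t_stationary < 0) stop("exploration times must be >= 0")
  total <- t_displaced + t_stationary
  if (total < min_total_s)
    return(list(di = NA_real_, excluded = TRUE))
  list(di = (t_displaced - t_stationary) / total, excluded = FALSE)
}
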