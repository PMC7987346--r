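# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
derive_seed <- function(seed, offset) {
  # deterministic per-stage seed expansion; stays below 2^31 - 1
  as.integer((as.numeric(seed) * 48271 + offset * 104729) %% 2147483629 + 1)
}

#' Zero-phase Butterworth low-pass filter
#'
#' Forward-backward (zero-phase) recursive low-pass filtering with
#' odd-reflection padding at both ends to suppress the edge transients of the
#' filter's zero initial conditions. Padding length is three filter time
#' constants (3 * fs / cutoff_hz), capped at the signal length.
#'
#' @param x numeric vector.
#' @param cutoff_hz cutoff frequency in Hz; must be below fs/2.
#' @param fs sampling rate in Hz.
#' @param order filter order (default 4).
#' @return filtered vector, same length as `x`.
#' @keywords internal
#' @noRd
lowpass_zerophase <- function(x, cutoff_hz, fs, order = 4L) {
  stopifnot(is.numeric(x), cutoff_hz > 0, fs > 0, cutoff_hz < fs / 2)
  n <- length(x)
  if (n < 4L) return(x)
  bf <- signal::butter(order, cutoff_hz / (fs / 2))
  pad <- min(n - 1L, ceiling(3 * fs / cutoff_hz))
  xm <- mean(x)
  xc <- x - xm
  left <- 2 * xc[1L] - xc[(pad + 1L):2L]
  right <- 2 * xc[n] - xc[(n - 1L):(n - pad)]
  yp <- signal::filtfilt(bf, c(left, xc, right))
  yp[(pad + 1L):(pad + n)] + xm
}

#' @keywords internal
#' @noRd
is_binary_matrix <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}

#' @keywords internal
#' @noRd
frames_in_epochs <- function(epochs, state = NULL) {
  # expand an epochs data.frame to the sorted vector of frames it covers
  if (!is.null(state)) epochs <- epochs[epochs$state %in% state, , drop = FALSE]
  if (nrow(epochs) == 0L) return(integer(0))
  sort(unlist(mapply(seq.int, epochs$start, epochs$end, SIMPLIFY = FALSE)))
}

#' @keywords internal
#' @noRd
epoch_durations <- function(epochs, frame_rate) {
  (epochs$end - epochs$start + 1L) / frame_rate
}
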