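# Bulk MPP (medial perforant path) input-signal conditioning, transient
# deconvolution, state statistics, cross-correlation and Granger test against
# summed granule-cell activity, and NE-aligned timing.

#' Relative fluorescence change of the bulk signal
#'
#' The baseline is the zero-phase low-pass filtered raw trace (cutoff
#' default 0.01 Hz); dff = (raw - baseline) / baseline.
#'
#' @param mpp_raw raw bulk fluorescence trace (must stay positive).
#' @param frame_rate sampling rate in Hz.
#' @param baseline_cutoff baseline low-pass cutoff in Hz (default 0.01).
#' @param order filter order (default 4).
#' @return dff vector, same length as the input.
#' @export
bulk_dff <- function(mpp_raw, frame_rate, baseline_cutoff = 0.01, order = 4L) {
  base <- lowpass_zerophase(mpp_raw, baseline_cutoff, frame_rate, order)
  if (any(base <= 0))
    stop("non-positive baseline; raw fluorescence must be positive")
  (mpp_raw - base) / base
}

#' Deconvolve bulk transients from a dff trace
#'
#' Inverts the single-exponential calcium forward model (instantaneous rise,
#' decay time constant tau): with g = exp(-1/(frame_rate * tau)) the activity
#' proxy is s[t] = dff[t] - g * dff[t-1], clipped at zero. Events are local
#' maxima of the proxy above a noise-scaled floor (`sparsity` times a robust
#' noise estimate of the proxy, its median absolute deviation). Amplitudes
#' are reported both raw (proxy height) and normalized to the proxy standard
#' deviation.
#'
#' @param dff bulk dF/F trace.
#' @param frame_rate sampling rate in Hz.
#' @param tau decay time constant in seconds (default 1.5).
#' @param sparsity noise floor in robust-noise units (default 3).
#' @return an object of class `dg_bulk_events`: list with `frames`,
#'   `amplitudes` (sd-normalized), `amplitudes_raw`, `tau`, `amp_mean`,
#'   `amp_sd`, and the full `proxy` trace.
#' @export
deconvolve_bulk <- function(dff, frame_rate, tau = 1.5, sparsity = 3) {
  stopifnot(tau > 0)
  n <- length(dff)
  g <- exp(-1 / (frame_rate * tau))
  s <- c(dff[1L], dff[-1L] - g * dff[-n])
  s[s < 0] <- 0
  if (all(s == 0))
    return(structure(list(frames = integer(0), amplitudes = numeric(0),
                          amplitudes_raw = numeric(0), tau = tau,
                          amp_mean = NA_real_, amp_sd = NA_real_, proxy = s),
                     class = "dg_bulk_events"))
  eps <- 1e-8 * max(s)
  s[s < eps] <- 0                      # drop float residues of exact decays
  pos <- s[s > 0]
  # a near-noiseless trace has isolated spikes only; its robust "noise" would
  # be the spikes themselves, so the floor falls back to the epsilon scale
  noise <- if (length(pos) < 0.01 * n) 0 else stats::mad(pos, center = 0)
  floor_val <- max(sparsity * noise, eps)
  supra <- s > floor_val
  is_peak <- supra &
    s >= c(-Inf, s[-n]) & s > c(s[-1L], -Inf)     # left-closed local maxima
  frames <- which(is_peak)
  amp_raw <- s[frames]
  sd_s <- stats::sd(s)
  amp <- if (sd_s > 0) amp_raw / sd_s else amp_raw
  structure(list(frames = frames, amplitudes = amp, amplitudes_raw = amp_raw,
                 tau = tau, amp_mean = mean(amp), amp_sd = stats::sd(amp),
                 proxy = s),
            class = "dg_bulk_events")
}

#' @export
print.dg_bulk_events <- function(x, ...) {
  cat(sprintf("<dg_bulk_events>: %d deconvolved transients (tau %g s)\n",
              length(x$frames), x$tau))
  invisible(x)
}

#' Bulk-event statistics by behavioral state
#'
#' Per-state frequencies and amplitude distributions of deconvolved bulk
#' events, plus frequencies of "large" events, defined as amplitudes above
#' the mean plus `sd_factor` standard deviations of all event amplitudes.
#'
#' @param events a `dg_bulk_events`.
#' @param epochs run/rest epochs.
#' @param frame_rate Hz.
#' @param sd_factor large-event criterion (default 2).
#' @return list with `freq_per_s`, `large_freq_per_s` (named run/rest; NA for
#'   zero-duration states), `amplitudes` (list per state), and
#'   `large_cutoff`.
#' @export
bulk_event_state_stats <- function(events, epochs, frame_rate, sd_factor = 2) {
  amps <- events$amplitudes
  cutoff <- if (length(amps) > 1L) mean(amps) + sd_factor * stats::sd(amps)
            else Inf
  large <- amps > cutoff
  out_f <- c(run = NA_real_, rest = NA_real_)
  out_lf <- out_f
  out_amp <- list(run = numeric(0), rest = numeric(0))
  for (st in c("run", "rest")) {
    fr <- frames_in_epochs(epochs, st)
    dur <- length(fr) / frame_rate
    if (dur <= 0) next
    inside <- events$frames %in% fr
    out_f[st] <- sum(inside) / dur
    out_lf[st] <- sum(inside & large) / dur
    out_amp[[st]] <- amps[inside]
  }
  list(freq_per_s = out_f, large_freq_per_s = out_lf, amplitudes = out_amp,
       large_cutoff = cutoff)
}

#' Cross-correlation of MPP and granule-cell signals during rest
#'
#' Pearson correlation between the two signals at integer frame lags over
#' rest frames only (the two rest-restricted series are lag-shifted against
#' each other; the overlap is correlated at each lag). Positive lags mean the
#' first signal leads.
#'
#' @param mpp_dff bulk dff per frame.
#' @param gc_sum summed granule-cell activity per frame.
#' @param epochs run/rest epochs; rest frames are used (pass NULL to use all
#'   frames).
#' @param max_lag_s maximal lag in seconds.
#' @param frame_rate Hz.
#' @return data.frame with `lag_frames`, `lag_s`, `cc`.
#' @export
mpp_gc_crosscorr <- function(mpp_dff, gc_sum, epochs, max_lag_s, frame_rate) {
  fr <- if (is.null(epochs)) seq_along(mpp_dff)
        else frames_in_epochs(epochs, "rest")
  x <- mpp_dff[fr]; y <- gc_sum[fr]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant signal; cross-correlation undefined")
  max_lag <- min(floor(max_lag_s * frame_rate), length(x) - 2L)
  lags <- -max_lag:max_lag
  n <- length(x)
  cc <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(x[seq_len(n - k)], y[seq_len(n - k) + k])
    else stats::cor(x[seq_len(n + k) - k], y[seq_len(n + k)])
  }, numeric(1L))
  data.frame(lag_frames = lags, lag_s = lags / frame_rate, cc = cc)
}

#' Bivariate Granger F-test
#'
#' Tests whether lagged values of `x` improve the prediction of `y` beyond
#' y's own history (nested autoregression F-test). The lag order is chosen by
#' an information criterion (BIC by default) on the unrestricted model over
#' 1..`max_order`, fit on a common sample.
#'
#' @param x putative driving series.
#' @param y driven series.
#' @param max_order maximal lag order considered (default 15).
#' @param order_rule `"BIC"` or `"AIC"`.
#' @return list with `order`, `F`, `p`, and `ic` (criterion value per order).
#' @export
granger_test <- function(x, y, max_order = 15L, order_rule = c("BIC", "AIC")) {
  order_rule <- match.arg(order_rule)
  n <- length(y)
  if (length(x) != n) stop("series lengths differ")
  if (n <= 10L * max_order)
    stop("series too short for the requested maximal order")
  lagmat <- function(v, p) {
    # rows t = (max_order+1)..n, columns v[t-1]..v[t-p]
    sapply(seq_len(p), function(k) v[(max_order + 1L - k):(n - k)])
  }
  yy <- y[(max_order + 1L):n]
  ic <- vapply(seq_len(max_order), function(p) {
    X <- cbind(lagmat(y, p), lagmat(x, p))
    fit <- stats::lm.fit(cbind(1, X), yy)
    rss <- sum(fit$residuals^2)
    k <- ncol(X) + 1L
    m <- length(yy)
    pen <- if (order_rule == "BIC") log(m) else 2
    m * log(rss / m) + pen * k
  }, numeric(1L))
  p_sel <- which.min(ic)
  gt <- lmtest::grangertest(x, y, order = p_sel)
  list(order = p_sel, F = gt$F[2L], p = gt$`Pr(>F)`[2L], ic = ic)
}

#' Delay of network events to the closest bulk MPP event
#'
#' For each network event, the signed delay in seconds to the nearest
#' deconvolved MPP event; positive when the MPP event precedes (leads) the
#' network event.
#'
#' @param ne_frames network-event peak frames.
#' @param events a `dg_bulk_events`.
#' @param frame_rate Hz.
#' @return numeric vector of delays (s), one per network event.
#' @export
ne_mpp_delay <- function(ne_frames, events, frame_rate) {
  if (length(events$frames) == 0L) stop("empty bulk event set")
  vapply(ne_frames, function(f) {
    j <- which.min(abs(events$frames - f))
    (f - events$frames[j]) / frame_rate
  }, numeric(1L))
}
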