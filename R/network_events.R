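# Synchronous network-event (NE) detection against shuffle-derived nulls, and
# state-dependent NE statistics.
#
# A network event is a transient synchronous activation of multiple granule
# cells within a ~200 ms moving window (3 frames at 15 Hz). Because granule
# cell activity is sparse, a per-session size threshold is calibrated from
# shuffled rasters: the minimal number of synchronously active cells at which
# less than a fraction alpha (default 0.001) of detected events could be
# explained by chance.

#' Per-frame synchronous-cell counts
#'
#' For each frame t, the number of distinct cells with at least one event
#' onset within the centered window of `window_frames` frames around t
#' (truncated at the recording edges). Multiple onsets of one cell within a
#' window count once.
#'
#' @param raster binary matrix (n_cells x n_frames) of event onsets.
#' @param window_frames odd window width in frames (default 3, i.e. 200 ms at
#'   15 Hz: center frame plus/minus one).
#' @return integer vector of length n_frames.
#' @export
window_counts <- function(raster, window_frames = 3L) {
  window_frames <- as.integer(window_frames)
  if (window_frames %% 2L == 0L)
    stop("window_frames must be odd (centered window)")
  if (!is_binary_matrix(raster)) stop("raster must be a binary matrix")
  half <- (window_frames - 1L) %/% 2L
  nfr <- ncol(raster); ncl <- nrow(raster)
  active <- raster > 0
  if (half > 0L && nfr > 1L) {
    acc <- active
    for (k in seq_len(half)) {
      if (k >= nfr) break
      sl <- cbind(active[, -seq_len(k), drop = FALSE],
                  matrix(FALSE, ncl, k))        # onsets k frames ahead
      sr <- cbind(matrix(FALSE, ncl, k),
                  active[, seq_len(nfr - k), drop = FALSE])  # k frames back
      acc <- acc | sl | sr
    }
    active <- acc
  }
  as.integer(colSums(active))
}

#' Shuffle an event-onset raster
#'
#' Three surrogate constructions, each conserving every cell's onset count
#' exactly:
#' \describe{
#'   \item{redistribute}{each cell's onset times are redistributed to uniform
#'     random frames (without replacement), destroying all temporal
#'     correlations.}
#'   \item{trace_shift}{each cell's onset trace is circularly shifted by an
#'     independent random offset, preserving within-cell inter-onset structure
#'     while destroying between-cell correlations.}
#'   \item{state_constrained}{onsets are redistributed uniformly but only
#'     within their own behavioral state (run frames among run frames, rest
#'     among rest, excluded-bout frames among themselves), conserving per-cell
#'     onset counts per state.}
#' }
#'
#' @param raster binary matrix (n_cells x n_frames).
#' @param method one of `"redistribute"`, `"trace_shift"`,
#'   `"state_constrained"`.
#' @param epochs run/rest epochs (required for `state_constrained`).
#' @param seed optional integer seed.
#' @return shuffled binary matrix of the same dimensions.
#' @export
shuffle_raster <- function(raster,
                           method = c("redistribute", "trace_shift",
                                      "state_constrained"),
                           epochs = NULL, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  ncl <- nrow(raster); nfr <- ncol(raster)
  out <- matrix(0, ncl, nfr)
  if (method == "redistribute") {
    for (i in seq_len(ncl)) {
      k <- sum(raster[i, ])
      if (k > 0L) out[i, sample.int(nfr, k)] <- 1
    }
  } else if (method == "trace_shift") {
    for (i in seq_len(ncl)) {
      sh <- sample.int(nfr, 1L) - 1L
      if (sh == 0L) out[i, ] <- raster[i, ]
      else out[i, ] <- raster[i, c((nfr - sh + 1L):nfr, 1L:(nfr - sh))]
    }
  } else {
    if (is.null(epochs)) stop("state_constrained shuffling requires epochs")
    run_f <- frames_in_epochs(epochs, "run")
    rest_f <- frames_in_epochs(epochs, "rest")
    other_f <- setdiff(seq_len(nfr), c(run_f, rest_f))
    for (i in seq_len(ncl)) {
      for (fr in list(run_f, rest_f, other_f)) {
        if (length(fr) == 0L) next
        k <- sum(raster[i, fr])
        if (k > 0L) out[i, fr[sample.int(length(fr), k)]] <- 1
      }
    }
  }
  out
}

# Sparse path used by the shuffle loop: per-frame synchronous-cell counts
# from per-cell onset frame lists. Each onset covers the frames of its
# centered window; a cell contributes at most once per frame.
#' @keywords internal
#' @noRd
counts_from_onsets <- function(onsets, nfr, half) {
  counts <- integer(nfr)
  for (fr in onsets) {
    if (length(fr) == 0L) next
    cov <- unique(unlist(lapply(-half:half, function(k) fr + k)))
    cov <- cov[cov >= 1L & cov <= nfr]
    counts[cov] <- counts[cov] + 1L
  }
  counts
}

# Shuffled per-cell onset lists (same surrogate constructions as
# shuffle_raster, in onset space).
#' @keywords internal
#' @noRd
shuffle_onsets <- function(onsets, nfr, method, run_f = NULL, rest_f = NULL,
                           other_f = NULL) {
  lapply(onsets, function(fr) {
    k <- length(fr)
    if (k == 0L) return(fr)
    switch(method,
      redistribute = sample.int(nfr, k),
      trace_shift = (fr - 1L + sample.int(nfr, 1L) - 1L) %% nfr + 1L,
      state_constrained = {
        out <- integer(0)
        for (ff in list(run_f, rest_f, other_f)) {
          kk <- sum(fr %in% ff)
          if (kk > 0L) out <- c(out, ff[sample.int(length(ff), kk)])
        }
        out
      })
  })
}

# Number of candidate events (maximal supra-threshold runs of the count
# trace) for every size threshold 2..max_size.
#' @keywords internal
#' @noRd
event_counts_by_size <- function(counts, max_size) {
  vapply(2:max_size, function(s) {
    r <- rle(counts >= s)
    sum(r$values)
  }, integer(1L))
}

#' Shuffle-calibrated network-event size threshold
#'
#' Calibrates the per-session minimal NE size. For each candidate size s, the
#' fraction of detected events explainable by chance is estimated as the
#' pooled number of size >= s events across shuffled rasters divided by
#' (n_shuffles x the number of size >= s events in the real raster). The
#' threshold is the smallest s at which this fraction falls below `alpha`
#' (`threshold_rule = "count_ratio"`, the default). The alternative rule
#' `"per_shuffle"` uses the fraction of shuffles containing at least one
#' event of size >= s. For alpha >= 1 the chance criterion is vacuous and the
#' threshold degenerates to the minimum event size, 2.
#'
#' @param raster binary matrix (n_cells x n_frames) with at least one onset.
#' @param epochs run/rest epochs (needed for the state-constrained null).
#' @param n_shuffles shuffles per null (default 1000).
#' @param alpha chance-fraction criterion (default 0.001).
#' @param method shuffle method used for thresholding (default
#'   `"redistribute"`).
#' @param window_frames NE window width (default 3).
#' @param threshold_rule `"count_ratio"` or `"per_shuffle"`; see above.
#' @param null_methods shuffle methods for which mean null curves are
#'   reported alongside (default: the thresholding method; pass all three to
#'   reproduce the full null-curve comparison).
#' @param seed integer seed.
#' @return list with `threshold` (integer, or `Inf` with a warning when no
#'   size qualifies), `sizes`, `real_counts` (events vs size in the real
#'   raster), `chance_fraction`, and `null_curves` (per-method mean and sd of
#'   shuffle event counts vs size).
#' @export
size_threshold <- function(raster, epochs = NULL, n_shuffles = 1000L,
                           alpha = 0.001, method = "redistribute",
                           window_frames = 3L,
                           threshold_rule = c("count_ratio", "per_shuffle"),
                           null_methods = method, seed = 1L) {
  threshold_rule <- match.arg(threshold_rule)
  if (sum(raster) == 0L) stop("raster has no onsets")
  counts <- window_counts(raster, window_frames)
  # headroom above the observed maximum so the search can settle at a size
  # the shuffles no longer reach
  max_size <- max(max(counts) + 5L, 2L)
  sizes <- 2:max_size
  real <- event_counts_by_size(counts, max_size)
  half <- (as.integer(window_frames) - 1L) %/% 2L
  nfr <- ncol(raster)
  onsets <- apply(raster, 1L, function(x) which(x > 0), simplify = FALSE)
  run_f <- if (!is.null(epochs)) frames_in_epochs(epochs, "run") else integer(0)
  rest_f <- if (!is.null(epochs)) frames_in_epochs(epochs, "rest") else integer(0)
  other_f <- setdiff(seq_len(nfr), c(run_f, rest_f))
  null_curves <- list()
  pooled <- NULL; any_event <- NULL
  for (m in unique(c(method, null_methods))) {
    if (m == "state_constrained" && is.null(epochs))
      stop("state_constrained shuffling requires epochs")
    tot <- matrix(0, n_shuffles, length(sizes))
    set.seed(derive_seed(seed, match(m, c("redistribute", "trace_shift",
                                          "state_constrained"))))
    for (b in seq_len(n_shuffles)) {
      so <- shuffle_onsets(onsets, nfr, m, run_f, rest_f, other_f)
      cs <- counts_from_onsets(so, nfr, half)
      ec <- event_counts_by_size(cs, max_size)
      tot[b, ] <- ec
    }
    null_curves[[m]] <- data.frame(size = sizes,
                                   mean = colMeans(tot),
                                   sd = apply(tot, 2L, stats::sd))
    if (m == method) {
      pooled <- colSums(tot)
      any_event <- colMeans(tot > 0)
    }
  }
  chance_fraction <- if (threshold_rule == "count_ratio") {
    # no real events at size >= s: nothing is explained by chance (0) unless
    # the shuffles still produce such events (then chance fully accounts for
    # anything that could appear: Inf)
    ifelse(real > 0, pooled / (n_shuffles * real),
           ifelse(pooled > 0, Inf, 0))
  } else {
    any_event
  }
  if (alpha >= 1) {
    thr <- 2L
  } else {
    ok <- which(chance_fraction < alpha)
    if (length(ok) == 0L) {
      warning("no event size satisfies the chance criterion; threshold = Inf")
      thr <- Inf
    } else {
      thr <- sizes[min(ok)]
    }
  }
  list(threshold = thr, sizes = sizes, real_counts = real,
       chance_fraction = chance_fraction, null_curves = null_curves,
       alpha = alpha, method = method, threshold_rule = threshold_rule)
}

#' Detect network events at a size threshold
#'
#' Maximal runs of frames whose synchronous-cell count is at or above the
#' threshold are merged into one network event. The event's peak frame is the
#' count argmax within the run (earliest on ties); its members are all cells
#' with an onset within the run's span extended by the half-window.
#'
#' @param raster binary matrix (n_cells x n_frames).
#' @param threshold minimal synchronous-cell count (>= 2).
#' @param window_frames NE window width (default 3).
#' @return an object of class `dg_ne_set`: list with `ne_frames` (peak
#'   frames, strictly increasing), `ne_members` (list of integer cell-id
#'   vectors), `ne_spans` (start/end frames of each supra-threshold run),
#'   `size_threshold`, `window_frames`, `n_cells`, `n_frames`.
#' @export
detect_network_events <- function(raster, threshold, window_frames = 3L) {
  if (threshold < 2) stop("threshold must be >= 2")
  counts <- window_counts(raster, window_frames)
  half <- (as.integer(window_frames) - 1L) %/% 2L
  nfr <- ncol(raster)
  r <- rle(counts >= threshold)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  ne_frames <- integer(0); ne_members <- list(); spans <- NULL
  for (j in idx) {
    a <- starts[j]; b <- ends[j]
    peak <- a + which.max(counts[a:b]) - 1L
    lo <- max(1L, a - half); hi <- min(nfr, b + half)
    members <- which(rowSums(raster[, lo:hi, drop = FALSE]) > 0)
    ne_frames <- c(ne_frames, peak)
    ne_members <- c(ne_members, list(as.integer(members)))
    spans <- rbind(spans, c(a, b))
  }
  structure(list(ne_frames = ne_frames, ne_members = ne_members,
                 ne_spans = spans, size_threshold = threshold,
                 window_frames = as.integer(window_frames),
                 n_cells = nrow(raster), n_frames = nfr),
            class = "dg_ne_set")
}

#' @export
print.dg_ne_set <- function(x, ...) {
  cat(sprintf("<dg_ne_set>: %d network events (size threshold %s) over %d cells x %d frames\n",
              length(x$ne_frames), format(x$size_threshold), x$n_cells,
              x$n_frames))
  invisible(x)
}

#' State-dependent network-event statistics
#'
#' Counts and per-minute frequencies of network events during locomotion and
#' immobility; duration-equalized frequencies obtained by truncating the
#' longer state's timeline to the shorter's total duration via a seeded random
#' contiguous subsample; cumulative occurrence curves over session time and
#' over normalized within-rest-period time (rest periods of at least
#' `min_rest_s` seconds only).
#'
#' @param ne_set a `dg_ne_set`.
#' @param epochs run/rest epochs.
#' @param frame_rate imaging rate in Hz.
#' @param min_rest_s minimal rest-period length for the normalized curve
#'   (default 5).
#' @param seed seed for the contiguous subsample.
#' @return list with `counts` (per state), `freq_per_min`,
#'   `freq_equalized_per_min`, `frac_rest`, `cum_session` (event times as a
#'   fraction of the session), `cum_rest_norm` (event positions normalized to
#'   their rest period's length).
#' @export
ne_state_stats <- function(ne_set, epochs, frame_rate, min_rest_s = 5,
                           seed = 1L) {
  frames <- ne_set$ne_frames
  run_f <- frames_in_epochs(epochs, "run")
  rest_f <- frames_in_epochs(epochs, "rest")
  in_run <- frames %in% run_f
  in_rest <- frames %in% rest_f
  dur_run <- length(run_f) / frame_rate
  dur_rest <- length(rest_f) / frame_rate
  freq <- function(n, dur) if (dur > 0) n / (dur / 60) else NA_real_
  # duration equalization: contiguous subsample of the longer state's frames
  eq <- c(run = NA_real_, rest = NA_real_)
  if (dur_run > 0 && dur_rest > 0) {
    set.seed(seed)
    need <- min(length(run_f), length(rest_f))
    sub <- function(fr) {
      if (length(fr) == need) return(fr)
      start <- sample.int(length(fr) - need + 1L, 1L)
      fr[start:(start + need - 1L)]
    }
    eq["run"] <- freq(sum(frames %in% sub(run_f)), need / frame_rate)
    eq["rest"] <- freq(sum(frames %in% sub(rest_f)), need / frame_rate)
  }
  # cumulative curves
  cum_session <- sort(frames) / ne_set$n_frames
  rest_ep <- epochs[epochs$state == "rest", , drop = FALSE]
  len <- (rest_ep$end - rest_ep$start + 1L) / frame_rate
  rest_ep <- rest_ep[len >= min_rest_s, , drop = FALSE]
  cum_rest <- numeric(0)
  for (i in seq_len(nrow(rest_ep))) {
    a <- rest_ep$start[i]; b <- rest_ep$end[i]
    f <- frames[frames >= a & frames <= b]
    if (length(f)) cum_rest <- c(cum_rest, (f - a) / (b - a + 1L))
  }
  list(counts = c(run = sum(in_run), rest = sum(in_rest)),
       freq_per_min = c(run = freq(sum(in_run), dur_run),
                        rest = freq(sum(in_rest), dur_rest)),
       freq_equalized_per_min = eq,
       frac_rest = if (length(frames)) mean(in_rest) else NA_real_,
       cum_session = cum_session,
       cum_rest_norm = sort(cum_rest))
}
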