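# Independent brute-force oracles and shared fixtures.

# Brute-force synchronous-cell counts: direct enumeration over every frame's
# truncated window, independent of the package's implementation.
brute_force_window_counts <- function(raster, window_frames = 3L) {
  half <- (window_frames - 1L) %/% 2L
  nfr <- ncol(raster)
  vapply(seq_len(nfr), function(t) {
    lo <- max(1L, t - half); hi <- min(nfr, t + half)
    sum(vapply(seq_len(nrow(raster)), function(i)
      any(raster[i, lo:hi] > 0), logical(1L)))
  }, integer(1L))
}

# Brute-force event detection from a count trace: maximal supra-threshold
# runs, peak = earliest argmax, members = onsets within span +- half window.
brute_force_detect <- function(raster, threshold, window_frames = 3L) {
  counts <- brute_force_window_counts(raster, window_frames)
  half <- (window_frames - 1L) %/% 2L
  nfr <- ncol(raster)
  above <- counts >= threshold
  frames <- integer(0); members <- list()
  t <- 1L
  while (t <= nfr) {
    if (above[t]) {
      a <- t
      while (t <= nfr && above[t]) t <- t + 1L
      b <- t - 1L
      peak <- a + which.max(counts[a:b]) - 1L
      lo <- max(1L, a - half); hi <- min(nfr, b + half)
      mem <- which(vapply(seq_len(nrow(raster)), function(i)
        any(raster[i, lo:hi] > 0), logical(1L)))
      frames <- c(frames, peak)
      members <- c(members, list(mem))
    } else t <- t + 1L
  }
  list(frames = frames, members = members)
}

# A tiny fully specified session for IO and plumbing tests.
make_mini_session <- function(n_cells = 4L, n_frames = 60L, seed = 1L,
                              with_optional = TRUE) {
  set.seed(seed)
  raster <- matrix(rbinom(n_cells * n_frames, 1L, 0.1), n_cells, n_frames)
  dff <- matrix(rnorm(n_cells * n_frames, 0, 0.1), n_cells, n_frames)
  speed <- abs(rnorm(n_frames, 5, 3))
  position <- (cumsum(speed) / 15) %% 150
  new_session(raster, dff, speed, position, frame_rate = 15,
              belt_length = 150,
              mpp = if (with_optional) 100 + rnorm(n_frames) else NULL,
              pupil = if (with_optional) 1 + 0.1 * rnorm(n_frames) else NULL,
              blink = if (with_optional) rbinom(n_frames, 1L, 0.05) else NULL,
              session_id = "mini")
}
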