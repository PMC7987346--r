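# Window counts, shuffles, size threshold, and event detection.

test_that("window counts match the definition on hand-built cases", {
  r <- matrix(0, 3L, 20L)
  expect_identical(window_counts(r), integer(20L))
  # multiple onsets of one cell within a window count once
  r[1L, 10:11] <- 1
  counts <- window_counts(r)
  expect_identical(counts[10L], 1L)
  expect_identical(counts[11L], 1L)
  expect_identical(counts[9L], 1L)     # truncated window reaches frame 10
  expect_identical(counts[13L], 0L)
  # two distinct cells in one window
  r[2L, 9L] <- 1
  expect_identical(window_counts(r)[10L], 2L)
  expect_error(window_counts(r, window_frames = 4L), "odd")
})

test_that("window counts and detection agree with brute force on random rasters", {
  set.seed(21)
  for (i in 1:30) {
    ncl <- sample(2:20, 1L)
    nfr <- sample(50:300, 1L)
    r <- matrix(rbinom(ncl * nfr, 1L, runif(1, 0.01, 0.1)), ncl, nfr)
    expect_identical(window_counts(r), brute_force_window_counts(r))
    thr <- sample(2:4, 1L)
    ne <- detect_network_events(r, thr)
    bf <- brute_force_detect(r, thr)
    expect_identical(ne$ne_frames, bf$frames)
    expect_identical(ne$ne_members, lapply(bf$members, as.integer))
  }
})

test_that("all three shuffles conserve per-cell onset counts", {
  set.seed(3)
  r <- matrix(rbinom(30L * 400L, 1L, 0.05), 30L, 400L)
  ep <- data.frame(start = c(1L, 201L), end = c(200L, 400L),
                   state = c("run", "rest"))
  for (m in c("redistribute", "trace_shift", "state_constrained")) {
    sh <- shuffle_raster(r, m, epochs = ep, seed = 4)
    expect_identical(rowSums(sh), rowSums(r))
    expect_true(all(sh %in% c(0, 1)))
    # all-zero raster stays all-zero
    expect_true(all(shuffle_raster(matrix(0, 5L, 400L), m, epochs = ep) == 0))
  }
  # state-constrained conservation holds per state
  sh <- shuffle_raster(r, "state_constrained", epochs = ep, seed = 5)
  for (st in c("run", "rest")) {
    f <- dgnet:::frames_in_epochs(ep, st)
    expect_identical(rowSums(sh[, f]), rowSums(r[, f]))
  }
  expect_error(shuffle_raster(r, "state_constrained"), "epochs")
  # trace_shift preserves each cell's inter-onset structure (circularly)
  sh <- shuffle_raster(r, "trace_shift", seed = 6)
  n <- ncol(r)
  for (i in 1:5) {
    a <- as.numeric(r[i, ]); b <- as.numeric(sh[i, ])
    rots <- vapply(0:(n - 1L), function(k)
      identical(b, a[((seq_len(n) - 1L - k) %% n) + 1L]), logical(1L))
    expect_true(any(rots))
  }
})

test_that("the sparse shuffle path matches the dense implementation", {
  set.seed(10)
  r <- matrix(rbinom(15L * 200L, 1L, 0.08), 15L, 200L)
  on <- apply(r, 1L, function(x) which(x > 0), simplify = FALSE)
  expect_identical(dgnet:::counts_from_onsets(on, 200L, 1L), window_counts(r))
})

test_that("size threshold follows the chance-fraction rule", {
  set.seed(30)
  # very sparse independent raster: chance coincidences die out by size 3
  r <- matrix(rbinom(200L * 2000L, 1L, 2e-5), 200L, 2000L)
  r[1L, 10L] <- 1                            # ensure at least one onset
  thr <- size_threshold(r, n_shuffles = 50L, seed = 1)
  expect_lte(thr$threshold, 3)
  # alpha = 1: any coincidence passes
  expect_identical(size_threshold(r, n_shuffles = 5L, alpha = 1,
                                  seed = 1)$threshold, 2L)
  expect_error(size_threshold(matrix(0, 3L, 10L)), "no onsets")
})

test_that("a planted-synchrony raster is thresholded at or below its event size", {
  set.seed(31)
  r <- matrix(rbinom(100L * 6000L, 1L, 0.0005), 100L, 6000L)
  frames <- seq(100L, 5900L, length.out = 30L)
  for (f in frames) r[sample.int(100L, 10L), round(f)] <- 1
  thr <- size_threshold(r, n_shuffles = 100L, seed = 2)
  expect_lte(thr$threshold, 10)
  expect_gte(thr$threshold, 3)
  ne <- detect_network_events(r, thr$threshold)
  expect_gte(length(ne$ne_frames), 25L)
})

test_that("detection merges runs, breaks at gaps, and is order-invariant", {
  r <- matrix(0, 6L, 60L)
  r[1:5, 20L] <- 1                      # one clear synchronous event
  r[1:5, 40L] <- 1                      # another, separated
  ne <- detect_network_events(r, 4L)
  expect_length(ne$ne_frames, 2L)
  # the 3-frame window spreads a single-frame event over frames 19-21 with
  # equal counts; the earliest-argmax rule puts the peak at 19
  expect_identical(ne$ne_frames, c(19L, 39L))
  expect_identical(ne$ne_members, list(1:5, 1:5))
  # a contiguous supra-threshold run is one event, peak earliest on ties
  r2 <- matrix(0, 6L, 60L)
  r2[1:4, 20L] <- 1; r2[1:4, 21L] <- 1
  ne2 <- detect_network_events(r2, 4L)
  expect_length(ne2$ne_frames, 1L)
  expect_identical(ne2$ne_frames, 19L)  # counts tie across the run; earliest
  # permuting rows permutes members only
  perm <- c(3L, 1L, 2L, 6L, 5L, 4L)
  ne3 <- detect_network_events(r[perm, ], 4L)
  expect_identical(ne3$ne_frames, ne$ne_frames)
  expect_identical(lapply(ne3$ne_members, function(m) sort(match(perm[m], seq_len(6L)))),
                   lapply(ne$ne_members, sort))
  expect_error(detect_network_events(r, 1L), ">= 2")
})

test_that("state statistics separate run and rest occurrences", {
  ep <- data.frame(start = c(1L, 301L), end = c(300L, 900L),
                   state = c("run", "rest"))
  ne <- structure(list(ne_frames = c(400L, 500L, 700L),
                       ne_members = list(1:5, 1:5, 1:5),
                       ne_spans = NULL, size_threshold = 5L,
                       window_frames = 3L, n_cells = 10L, n_frames = 900L),
                  class = "dg_ne_set")
  st <- ne_state_stats(ne, ep, frame_rate = 15)
  expect_identical(unname(st$counts), c(0L, 3L))
  expect_equal(unname(st$freq_per_min["run"]), 0)
  expect_equal(st$frac_rest, 1)
  expect_gt(st$freq_per_min["rest"], 0)
  # equalized frequencies are computed on matched durations
  expect_false(any(is.na(st$freq_equalized_per_min)))
})

test_that("uniform placement gives a near-diagonal normalized rest curve", {
  set.seed(33)
  ep <- data.frame(start = 1L, end = 3000L, state = "rest")
  frames <- sort(sample(1:3000, 200L))
  ne <- structure(list(ne_frames = frames,
                       ne_members = rep(list(1:5), 200L), ne_spans = NULL,
                       size_threshold = 5L, window_frames = 3L,
                       n_cells = 10L, n_frames = 3000L),
                  class = "dg_ne_set")
  st <- ne_state_stats(ne, ep, 15)
  u <- st$cum_rest_norm
  ks <- max(abs(seq_along(u) / length(u) - u))
  expect_lt(ks, 0.1)
})

test_that("synthetic sessions put network events in immobility", {
  gs <- cached_session(2)
  s <- gs$session
  ep <- segment_locomotion(s$speed, s$frame_rate)
  thr <- size_threshold(s$raster, ep, n_shuffles = 100L, seed = 1)
  ne <- detect_network_events(s$raster, thr$threshold)
  st <- ne_state_stats(ne, ep, s$frame_rate)
  expect_gt(st$freq_per_min["rest"], st$freq_per_min["run"])
  expect_gt(st$frac_rest, 0.9)
})
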