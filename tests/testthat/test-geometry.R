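# PCA bases, state matrices, subspace-similarity measures, shuffle tests,
# and lap-periodicity of component weights.

orthonormal_basis <- function(n, k, seed = 1L) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(n * k), n, k)))
}

test_that("row z-scoring standardizes and drops constant rows", {
  X <- rbind(c(1, 2, 3), c(5, 5, 5), c(0, -1, 4))
  expect_warning(Z <- zscore_rows(X), "constant row")
  expect_identical(attr(Z, "kept"), c(1L, 3L))
  expect_equal(rowMeans(Z), c(0, 0), tolerance = 1e-12)
  expect_equal(apply(Z, 1L, sd), c(1, 1), tolerance = 1e-12)
  expect_error(zscore_rows(matrix(1, 2L, 5L)), "all rows")
})

test_that("the PCA basis is orthonormal and reconstructs the data", {
  set.seed(30)
  X <- matrix(rnorm(20L * 300L), 20L, 300L)
  pb <- pca_basis(X)
  expect_equal(crossprod(pb$V), diag(ncol(pb$V)), tolerance = 1e-8)
  expect_true(all(diff(pb$eigenvalues) <= 1e-10))
  # full-rank reconstruction: X = V W + row means
  expect_equal(pb$V %*% pb$W + pb$row_means, X, tolerance = 1e-8)
  frac <- cumsum(pb$eigenvalues) / sum(pb$eigenvalues)
  expect_gte(frac[pb$k], 0.5)
  if (pb$k > 1L) expect_lt(frac[pb$k - 1L], 0.5)
  # a single nonzero direction gives one component with all the variance
  X1 <- outer(rnorm(20L), rnorm(300L))
  pb1 <- pca_basis(X1)
  expect_identical(pb1$k, 1L)
  expect_equal(pb1$eigenvalues[1L] / sum(pb1$eigenvalues), 1,
               tolerance = 1e-8)
})

test_that("isotropic noise needs about half the components for half the variance", {
  set.seed(31)
  X <- matrix(rnorm(50L * 10000L), 50L, 10000L)
  pb <- pca_basis(X)
  expect_gte(pb$k, 20L)
  expect_lte(pb$k, 30L)
})

test_that("state matrices concatenate run frames and deduplicated NE windows", {
  X <- matrix(seq_len(2L * 600L), 2L, 600L)
  ep <- data.frame(start = c(1L, 101L), end = c(100L, 600L),
                   state = c("run", "rest"))
  # two events 10 s apart: 31 frames per window at 15 Hz
  sm <- extract_state_matrices(X, ep, c(200L, 350L), frame_rate = 15)
  expect_identical(ncol(sm$X_run), 100L)
  expect_identical(ncol(sm$X_net), 62L)
  expect_identical(sm$net_frames, c(185:215, 335:365))
  # overlapping windows share frames once
  sm2 <- extract_state_matrices(X, ep, c(200L, 210L), frame_rate = 15)
  expect_identical(sm2$net_frames, 185:225)
  expect_error(extract_state_matrices(X, ep, integer(0), 15), "no network")
  ep_rest <- data.frame(start = 1L, end = 600L, state = "rest")
  expect_error(extract_state_matrices(X, ep_rest, 200L, 15), "no run")
})

test_that("the projected variance ratio matches identities and an oracle", {
  set.seed(32)
  X_run <- matrix(rnorm(30L * 500L), 30L, 500L)
  V_run <- pca_basis(X_run)$V[, 1:5]
  expect_equal(projected_variance_ratio(X_run, V_run, V_run), 1,
               tolerance = 1e-12)
  # a basis spanning directions absent from the data projects nothing
  U <- diag(30L)[, 1:4]
  X0 <- U %*% matrix(rnorm(4L * 500L), 4L, 500L)    # data lives in first 4 axes
  V_perp <- diag(30L)[, 10:12]
  V_top <- pca_basis(X0)$V[, 1:3]
  expect_equal(projected_variance_ratio(X0, V_top, V_perp), 0,
               tolerance = 1e-10)
  # oracle: explicit covariance computation for an arbitrary basis
  V_b <- orthonormal_basis(30L, 5L, seed = 33)
  C <- cov(t(X_run))
  oracle <- sum(diag(t(V_b) %*% C %*% V_b)) /
    sum(diag(t(V_run) %*% C %*% V_run))
  expect_equal(projected_variance_ratio(X_run, V_run, V_b), oracle,
               tolerance = 1e-10)
  # invariance under rotation of the basis within its span
  R <- qr.Q(qr(matrix(rnorm(25L), 5L, 5L)))
  expect_equal(projected_variance_ratio(X_run, V_run, V_b %*% R),
               projected_variance_ratio(X_run, V_run, V_b),
               tolerance = 1e-8)
  expect_error(projected_variance_ratio(X_run, V_run[1:10, ], V_b),
               "dimensions")
})

test_that("S_PCA matches its closed-form values and an independent path", {
  V <- orthonormal_basis(10L, 3L, seed = 34)
  expect_equal(spca(V, V)$s_pca, 3, tolerance = 1e-12)
  expect_equal(spca(V, V)$angles, rep(0, 3L), tolerance = 1e-6)
  # mutually orthogonal subspaces
  A <- diag(6L)[, 1:2]; B <- diag(6L)[, 3:4]
  expect_equal(spca(A, B)$s_pca, 0, tolerance = 1e-12)
  # 1-D bases at 45 degrees
  a <- matrix(c(1, 0), 2L); b <- matrix(c(1, 1) / sqrt(2), 2L)
  expect_equal(spca(a, b)$s_pca, 0.5, tolerance = 1e-12)
  expect_equal(spca(a, b)$angles, pi / 4, tolerance = 1e-9)
  # independent computation: sum of squared singular values of V_a' V_b
  W <- orthonormal_basis(10L, 3L, seed = 35)
  expect_equal(spca(V, W)$s_pca, sum(svd(t(V) %*% W)$d^2), tolerance = 1e-12)
})

test_that("EROS matches its weighted-cosine definition", {
  V <- orthonormal_basis(8L, 3L, seed = 36)
  ev <- c(3, 2, 1)
  expect_equal(eros(V, V, ev, ev), 1, tolerance = 1e-12)
  A <- diag(6L)[, 1:2]; B <- diag(6L)[, 3:4]
  expect_equal(eros(A, B, c(2, 1), c(2, 1)), 0, tolerance = 1e-12)
  # hand-built two-component case: weights (0.7, 0.3), angles (0, 90) deg
  A2 <- diag(4L)[, 1:2]
  B2 <- diag(4L)[, c(1L, 3L)]
  expect_equal(eros(A2, B2, c(0.7, 0.3), c(0.7, 0.3)), 0.7,
               tolerance = 1e-12)
})

test_that("NE-block shuffles conserve their stated marginals", {
  set.seed(37)
  arr <- array(rnorm(10L * 7L * 6L), dim = c(10L, 7L, 6L))
  a2 <- dgnet:::permute_ne_blocks(arr, "within_ne_identity")
  for (e in 1:6) {
    # each window keeps its multiset of cell traces (total activity conserved)
    expect_equal(sort(rowSums(a2[, , e])), sort(rowSums(arr[, , e])),
                 tolerance = 1e-12)
    expect_equal(colSums(a2[, , e]), colSums(arr[, , e]), tolerance = 1e-12)
  }
  a3 <- dgnet:::permute_ne_blocks(arr, "per_cell_ne_reassign")
  for (i in 1:10) {
    # each cell keeps its multiset of window segments
    expect_equal(sort(colSums(a3[i, , ])), sort(colSums(arr[i, , ])),
                 tolerance = 1e-12)
  }
})

test_that("the shuffle test flags planted replay and stays quiet on noise", {
  fr <- 15
  set.seed(38)
  ncl <- 30L; nf <- 3000L; kf <- 6L
  ep <- data.frame(start = c(1L, 1001L), end = c(1000L, nf),
                   state = c("run", "rest"))
  ne_frames <- seq(1100L, 2900L, by = 180L)
  # planted replay: NE windows re-express the run-epoch factor structure
  L <- orthonormal_basis(ncl, kf, seed = 39) %*%
    diag(c(3, 2.5, 2, 1.5, 1.2, 1))
  X <- matrix(rnorm(ncl * nf, 0, 1), ncl, nf)
  X[, 1:1000] <- X[, 1:1000] + L %*% matrix(rnorm(kf * 1000L), kf)
  for (f in ne_frames) {
    idx <- (f - 15L):(f + 15L)
    X[, idx] <- X[, idx] + L %*% matrix(rnorm(kf * 31L), kf)
  }
  for (m in c("time_shift", "within_ne_identity", "per_cell_ne_reassign")) {
    g <- geometry_shuffle_test(X, ep, ne_frames, fr, method = m,
                               n_shuffles = 100L, seed = 3)
    # the ratio's per-shuffle component-count re-selection makes its
    # per-cell-reassignment null conservative on sharp toy spectra; the
    # basis-similarity measures keep full power there
    if (m != "per_cell_ne_reassign")
      expect_lt(g$p[["projected_variance_ratio"]], 0.05)
    expect_lt(g$p[["s_pca"]], 0.05)
    expect_lt(g$p[["eros"]], 0.05)
    expect_gte(g$projected_variance_ratio, 0)
    expect_lte(g$projected_variance_ratio, 1 + 1e-8)
    expect_gte(g$s_pca, 0); expect_lte(g$s_pca, min(g$k_run, g$k_net) + 1e-8)
    expect_gte(g$eros, 0); expect_lte(g$eros, 1 + 1e-8)
  }
  expect_error(geometry_shuffle_test(X, ep, ne_frames, fr, method = "bogus"),
               "arg")
})

test_that("isotropic noise keeps the shuffle test near its nominal level", {
  fr <- 15
  ncl <- 15L; nf <- 1500L
  ep <- data.frame(start = c(1L, 501L), end = c(500L, nf),
                   state = c("run", "rest"))
  ne_frames <- seq(550L, 1450L, by = 100L)
  hits <- vapply(1:100, function(i) {
    set.seed(400 + i)
    X <- matrix(rnorm(ncl * nf), ncl, nf)
    g <- geometry_shuffle_test(X, ep, ne_frames, fr, method = "time_shift",
                               n_shuffles = 60L, seed = i)
    g$p[["projected_variance_ratio"]] < 0.05
  }, logical(1L))
  # binomial 99.9% envelope around the nominal 5% over 100 runs
  expect_gte(mean(hits), 0)
  expect_lte(mean(hits), 0.13)
})

test_that("lap autocorrelation separates periodic from noise weights", {
  pos_bins <- 150L
  n_laps <- 10L
  position <- rep(seq(0.5, 149.5, by = 1), n_laps)
  lap <- rep(seq_len(n_laps) - 1L, each = 150L)
  # perfectly lap-periodic weights autocorrelate at exactly 1
  Wp <- matrix(rep(sin(2 * pi * seq_len(150L) / 150), n_laps), 1L)
  res <- weight_lap_autocorr(Wp, position, lap, 150, n_components = 1L,
                             pos_bins = pos_bins)
  expect_equal(res$peak, 1, tolerance = 1e-9)
  expect_identical(res$n_laps, n_laps)
  # white-noise weights stay low
  set.seed(40)
  Wn <- matrix(rnorm(5L * length(position)), 5L)
  resn <- weight_lap_autocorr(Wn, position, lap, 150, n_components = 5L,
                              pos_bins = pos_bins)
  expect_lt(resn$peak, 0.2)
  expect_error(weight_lap_autocorr(Wp[, 1:300, drop = FALSE], position[1:300],
                                   lap[1:300], 150), "3 complete laps")
})
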