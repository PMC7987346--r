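# PCA of population activity, run-vs-network-event subspace similarity with
# three shuffle nulls (projected variance ratio, S_PCA, EROS), and
# lap-periodicity of component weights.

#' Z-score the rows of an activity matrix
#'
#' Rows (cells) are centered and scaled to unit standard deviation. Constant
#' rows carry no signal and are dropped with a warning naming them.
#'
#' @param dff numeric matrix (n_cells x n_frames).
#' @return matrix with row means 0 and row sds 1; attribute `kept` gives the
#'   original indices of the retained rows.
#' @export
zscore_rows <- function(dff) {
  mu <- rowMeans(dff)
  sd_ <- apply(dff, 1L, stats::sd)
  keep <- sd_ > 0
  if (!any(keep)) stop("all rows are constant")
  if (any(!keep))
    warning("dropping constant row(s): ",
            paste(which(!keep), collapse = ", "))
  X <- (dff[keep, , drop = FALSE] - mu[keep]) / sd_[keep]
  attr(X, "kept") <- which(keep)
  X
}

#' Principal-component basis of population activity
#'
#' Decomposes the (row-centered) activity matrix as X = V W with orthonormal
#' columns in V (principal directions over cells) and weights W. Eigenvalues
#' are the variances per component; `k` is the smallest component count whose
#' cumulative eigenvalue fraction reaches `var_frac` (default 0.5, i.e. half
#' the variance). The sign of each component is fixed by making its
#' largest-magnitude loading positive.
#'
#' @param X activity matrix (n_cells x n_frames), typically from
#'   [zscore_rows()].
#' @param var_frac variance fraction defining `k` (default 0.5).
#' @return an object of class `dg_pca`: list with `V` (n_cells x r), `W`
#'   (r x n_frames), `eigenvalues` (length r, non-increasing), `k`,
#'   `var_frac`, `row_means`.
#' @export
pca_basis <- function(X, var_frac = 0.5) {
  n <- nrow(X); T_ <- ncol(X)
  if (T_ < 2L) stop("need at least 2 frames")
  mu <- rowMeans(X)
  Xc <- X - mu
  if (T_ >= n) {
    C <- tcrossprod(Xc) / (T_ - 1L)
    eg <- eigen(C, symmetric = TRUE)
    ev <- pmax(eg$values, 0)
    V <- eg$vectors
  } else {
    sv <- svd(Xc)
    ev <- sv$d^2 / (T_ - 1L)
    V <- sv$u
  }
  r <- max(1L, sum(ev > max(ev) * 1e-12))
  V <- V[, seq_len(r), drop = FALSE]
  ev <- ev[seq_len(r)]
  # deterministic sign: largest-magnitude loading positive
  for (j in seq_len(r)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  frac <- cumsum(ev) / sum(ev)
  k <- which(frac >= var_frac)[1L]
  structure(list(V = V, W = crossprod(V, Xc), eigenvalues = ev, k = k,
                 var_frac = var_frac, row_means = mu),
            class = "dg_pca")
}

#' @export
print.dg_pca <- function(x, ...) {
  cat(sprintf("<dg_pca>: %d x %d basis; k = %d components for %.0f%% variance\n",
              nrow(x$V), ncol(x$V), x$k, 100 * x$var_frac))
  invisible(x)
}

#' Extract locomotion and network-event activity matrices
#'
#' `X_run` concatenates all run-epoch columns; `X_net` concatenates the
#' frames of windows of `ne_window_s` seconds centered on the network-event
#' peak frames (half-window each side), clipped at the recording edges, with
#' frames shared by overlapping windows appearing once.
#'
#' @param X activity matrix (n_cells x n_frames).
#' @param epochs run/rest epochs.
#' @param ne_frames network-event peak frames.
#' @param frame_rate Hz.
#' @param ne_window_s full window length in seconds (default 2, i.e. peak
#'   plus/minus 1 s).
#' @return list with `X_run`, `X_net`, and the frame indices used
#'   (`run_frames`, `net_frames`).
#' @export
extract_state_matrices <- function(X, epochs, ne_frames, frame_rate,
                                   ne_window_s = 2) {
  run_f <- frames_in_epochs(epochs, "run")
  if (length(run_f) == 0L) stop("no run frames")
  if (length(ne_frames) == 0L) stop("no network events")
  half <- round(ne_window_s / 2 * frame_rate)
  nf <- ncol(X)
  net_f <- sort(unique(unlist(lapply(ne_frames, function(f)
    max(1L, f - half):min(nf, f + half)))))
  list(X_run = X[, run_f, drop = FALSE], X_net = X[, net_f, drop = FALSE],
       run_frames = run_f, net_frames = net_f)
}

#' @keywords internal
#' @noRd
cov_rows <- function(X) {
  Xc <- X - rowMeans(X)
  tcrossprod(Xc) / (ncol(X) - 1L)
}

#' Projected-variance ratio between two principal spaces
#'
#' The covariance of the locomotion activity is projected into the principal
#' space of the network activity; the trace of the projection is normalized
#' by the trace of the same covariance in the locomotion principal space:
#' `trace(V_net' cov(X_run) V_net) / trace(V_run' cov(X_run) V_run)`.
#'
#' @param X_run locomotion activity matrix (cells x frames).
#' @param V_run locomotion principal directions (cells x k_run,
#'   column-orthonormal).
#' @param V_net network-event principal directions (cells x k_net).
#' @return scalar ratio in `[0, 1]` (up to numerical tolerance).
#' @export
projected_variance_ratio <- function(X_run, V_run, V_net) {
  if (nrow(V_run) != nrow(X_run) || nrow(V_net) != nrow(X_run))
    stop("cell dimensions of bases and data do not match")
  C <- cov_rows(X_run)
  num <- sum(diag(crossprod(V_net, C %*% V_net)))
  den <- sum(diag(crossprod(V_run, C %*% V_run)))
  num / den
}

#' S_PCA subspace similarity
#'
#' Krzanowski's similarity between two principal subspaces:
#' `S_PCA = trace(V_a' V_b V_b' V_a) = sum(cos^2 theta_i)` over the principal
#' angles theta_i between the subspaces. Bases are truncated to the smaller
#' component count.
#'
#' @param V_a,V_b column-orthonormal bases over the same cells.
#' @return list with `s_pca` (in `[0, k]`) and `angles` (principal angles,
#'   radians).
#' @export
spca <- function(V_a, V_b) {
  k <- min(ncol(V_a), ncol(V_b))
  if (k < 1L) stop("zero components")
  A <- V_a[, seq_len(k), drop = FALSE]
  B <- V_b[, seq_len(k), drop = FALSE]
  M <- crossprod(A, B)
  d <- svd(M)$d
  list(s_pca = sum(d^2), angles = acos(pmin(1, d)))
}

#' EROS similarity between two principal bases
#'
#' Eigenvalue-weighted similarity of paired principal directions:
#' `sum(w_i * |cos theta_i|)` where theta_i is the angle between the i-th
#' directions of the two bases (paired, not subspace angles) and w_i averages
#' the two bases' normalized eigenvalue fractions, renormalized to sum 1 over
#' the first k components.
#'
#' @param V_a,V_b column-orthonormal bases over the same cells.
#' @param eig_a,eig_b eigenvalue vectors of the two decompositions.
#' @return scalar in `[0, 1]`.
#' @export
eros <- function(V_a, V_b, eig_a, eig_b) {
  k <- min(ncol(V_a), ncol(V_b))
  if (k < 1L) stop("zero components")
  fa <- eig_a / sum(eig_a); fb <- eig_b / sum(eig_b)
  w <- (fa[seq_len(k)] + fb[seq_len(k)]) / 2
  w <- w / sum(w)
  cosines <- abs(colSums(V_a[, seq_len(k), drop = FALSE] *
                         V_b[, seq_len(k), drop = FALSE]))
  sum(w * pmin(1, cosines))
}

# Full equal-length NE window blocks (clipped windows dropped); used by the
# shuffle test so that all three shuffles act on a common block structure.
#' @keywords internal
#' @noRd
ne_window_blocks <- function(X, ne_frames, half) {
  nf <- ncol(X)
  ok <- ne_frames[ne_frames - half >= 1L & ne_frames + half <= nf]
  lapply(ok, function(f) X[, (f - half):(f + half), drop = FALSE])
}

# Within-window permutations of the concatenated NE blocks (cells x frames x
# events). "within_ne_identity" permutes cell identities inside each window;
# "per_cell_ne_reassign" permutes each cell's window segments across events.
#' @keywords internal
#' @noRd
permute_ne_blocks <- function(arr, method) {
  ncl <- dim(arr)[1L]; B <- dim(arr)[3L]
  if (method == "within_ne_identity") {
    for (e in seq_len(B)) arr[, , e] <- arr[sample.int(ncl), , e]
  } else {
    for (i in seq_len(ncl)) arr[i, , ] <- arr[i, , sample.int(B)]
  }
  arr
}

#' Subspace-similarity shuffle test
#'
#' Compares the observed similarity between locomotion activity and
#' network-event activity (projected variance ratio, S_PCA, EROS) with nulls
#' from three shuffle constructions:
#' \describe{
#'   \item{time_shift}{each cell's immobility time series is circularly
#'     shifted by an independent random offset of at least `min_shift_s`;
#'     the original network-event times are then applied to the shifted
#'     traces, giving a random network principal space.}
#'   \item{within_ne_identity}{within each network-event window, cell
#'     identities are permuted; every event keeps its total activity but the
#'     identity of the active cells is randomized.}
#'   \item{per_cell_ne_reassign}{each cell's window segments are permuted
#'     across network events; how many events each cell participates in is
#'     maintained while between-cell co-occurrence is randomized.}
#' }
#' The run basis and run data are never shuffled. All measures and shuffles
#' use the matrix of concatenated full network-event windows (edge-clipped
#' events dropped). p-values are one-sided: the fraction of shuffles whose
#' measure is at least the observed one.
#'
#' @param X activity matrix (cells x frames), typically z-scored dF/F.
#' @param epochs run/rest epochs.
#' @param ne_frames network-event peak frames.
#' @param frame_rate Hz.
#' @param method one of `"time_shift"`, `"within_ne_identity"`,
#'   `"per_cell_ne_reassign"`.
#' @param n_shuffles number of shuffles (default 1000).
#' @param ne_window_s full window length in seconds (default 2).
#' @param var_frac variance fraction for the component counts (default 0.5).
#' @param min_shift_s minimum circular shift in seconds (default 5).
#' @param seed integer seed.
#' @return an object of class `dg_similarity`: observed measures
#'   (`projected_variance_ratio`, `s_pca`, `eros`), principal `angles`,
#'   component counts `k_run` and `k_net`, null distributions (`null`), and
#'   one-sided `p` per measure.
#' @export
geometry_shuffle_test <- function(X, epochs, ne_frames, frame_rate,
                                  method = c("time_shift",
                                             "within_ne_identity",
                                             "per_cell_ne_reassign"),
                                  n_shuffles = 1000L, ne_window_s = 2,
                                  var_frac = 0.5, min_shift_s = 5,
                                  seed = 1L) {
  method <- match.arg(method)
  half <- round(ne_window_s / 2 * frame_rate)
  run_f <- frames_in_epochs(epochs, "run")
  if (length(run_f) == 0L) stop("no run frames")
  X_run <- X[, run_f, drop = FALSE]
  blocks <- ne_window_blocks(X, ne_frames, half)
  if (length(blocks) == 0L) stop("no network-event window fits the recording")
  ncl <- nrow(X); L <- 2L * half + 1L; B <- length(blocks)
  run_pca <- pca_basis(X_run, var_frac)
  V_run <- run_pca$V[, seq_len(run_pca$k), drop = FALSE]
  C_run <- cov_rows(X_run)                       # fixed across all shuffles
  den <- sum(diag(crossprod(V_run, C_run %*% V_run)))
  measures <- function(Xnet) {
    net_pca <- pca_basis(Xnet, var_frac)
    V_net <- net_pca$V[, seq_len(net_pca$k), drop = FALSE]
    sp <- spca(V_run, V_net)
    c(projected_variance_ratio =
        sum(diag(crossprod(V_net, C_run %*% V_net))) / den,
      s_pca = sp$s_pca,
      eros = eros(V_run, V_net, run_pca$eigenvalues, net_pca$eigenvalues),
      k_net = net_pca$k)
  }
  X_net <- do.call(cbind, blocks)
  obs <- measures(X_net)
  # precomputed indexing for the time-shift null: window frames that fall in
  # immobility are re-read from each cell's circularly shifted rest series
  rest_f <- frames_in_epochs(epochs, "rest")
  nr <- length(rest_f)
  min_shift <- ceiling(min_shift_s * frame_rate)
  ok_ne <- ne_frames[ne_frames - half >= 1L & ne_frames + half <= ncol(X)]
  win_f <- unlist(lapply(ok_ne, function(f) (f - half):(f + half)))
  idx_rest <- match(win_f, rest_f)
  in_rest <- !is.na(idx_rest)
  S <- X[, rest_f, drop = FALSE]
  if (method == "time_shift" && nr <= 2L * min_shift)
    stop("immobility series too short for the minimum shift")
  set.seed(seed)
  null <- matrix(NA_real_, n_shuffles, 3L,
                 dimnames = list(NULL, c("projected_variance_ratio",
                                         "s_pca", "eros")))
  arr <- array(unlist(blocks), dim = c(ncl, L, B))
  for (b in seq_len(n_shuffles)) {
    Xs <- switch(method,
      time_shift = {
        Xs_ <- X_net
        src <- idx_rest[in_rest]
        for (i in seq_len(ncl)) {
          sh <- sample(min_shift:(nr - min_shift), 1L)
          Xs_[i, in_rest] <- S[i, ((src - sh - 1L) %% nr) + 1L]
        }
        Xs_
      },
      within_ne_identity = matrix(permute_ne_blocks(arr, method), ncl, L * B),
      per_cell_ne_reassign = matrix(permute_ne_blocks(arr, method), ncl, L * B))
    null[b, ] <- measures(Xs)[1:3]
  }
  p <- vapply(colnames(null), function(nm) mean(null[, nm] >= obs[[nm]]),
              numeric(1L))
  structure(list(method = method,
                 projected_variance_ratio = obs[["projected_variance_ratio"]],
                 s_pca = obs[["s_pca"]], eros = obs[["eros"]],
                 k_run = run_pca$k, k_net = obs[["k_net"]],
                 null = null, p = p, n_shuffles = n_shuffles),
            class = "dg_similarity")
}

#' @export
print.dg_similarity <- function(x, ...) {
  cat(sprintf("<dg_similarity> (%s, %d shuffles)\n", x$method, x$n_shuffles))
  cat(sprintf("  projected variance ratio %.3f (p = %.4g)\n",
              x$projected_variance_ratio, x$p["projected_variance_ratio"]))
  cat(sprintf("  S_PCA %.3f (p = %.4g); EROS %.3f (p = %.4g)\n",
              x$s_pca, x$p["s_pca"], x$eros, x$p["eros"]))
  invisible(x)
}

#' Lap-periodicity of principal-component weights
#'
#' The weight series of the leading components are resampled onto a uniform
#' position grid per lap (bin means, linear interpolation across empty bins),
#' concatenated across complete laps, and autocorrelated; the normalized
#' autocorrelation at a lag of exactly one lap (`pos_bins` samples) is
#' averaged over components. Spatially stable population activity yields a
#' large peak at one lap.
#'
#' @param W weight matrix (components x frames), aligned with `position`.
#' @param position belt position per frame (cm).
#' @param lap per-frame lap index, e.g. from [laps_from_position()].
#' @param belt_length belt length (cm).
#' @param n_components number of leading components to average (default 5).
#' @param pos_bins position bins per lap (default 150, 1 cm on a 150 cm
#'   belt).
#' @param min_coverage minimal fraction of bins a lap must visit to count as
#'   complete (default 0.75).
#' @return list with `peak` (mean autocorrelation at one lap),
#'   `per_component` peaks, and `n_laps` used.
#' @export
weight_lap_autocorr <- function(W, position, lap, belt_length,
                                n_components = 5L, pos_bins = 150L,
                                min_coverage = 0.75) {
  k <- min(n_components, nrow(W))
  breaks <- seq(0, belt_length, length.out = pos_bins + 1L)
  bin <- pmin(findInterval(position, breaks, rightmost.closed = TRUE),
              pos_bins)
  laps <- sort(unique(lap))
  cover <- vapply(laps, function(l)
    length(unique(bin[lap == l])) / pos_bins, numeric(1L))
  laps <- laps[cover >= min_coverage]
  if (length(laps) < 3L) stop("need at least 3 complete laps")
  ac1 <- function(series) {
    n <- length(series)
    stats::cor(series[seq_len(n - pos_bins)],
               series[seq_len(n - pos_bins) + pos_bins])
  }
  peaks <- vapply(seq_len(k), function(j) {
    series <- unlist(lapply(laps, function(l) {
      sel <- lap == l
      m <- tapply(W[j, sel], factor(bin[sel], levels = seq_len(pos_bins)),
                  mean)
      m <- as.numeric(m)
      if (anyNA(m)) {
        ok <- which(!is.na(m))
        m <- stats::approx(ok, m[ok], xout = seq_len(pos_bins), rule = 2)$y
      }
      m
    }))
    ac1(series)
  }, numeric(1L))
  list(peak = mean(peaks), per_component = peaks, n_laps = length(laps))
}
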