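# Participation vectors, cosine orthogonality, and sub-ensemble clustering.

make_ne_set <- function(members, n_cells) {
  structure(list(ne_frames = seq(10L, by = 50L,
                                 length.out = length(members)),
                 ne_members = members, ne_spans = NULL,
                 size_threshold = if (length(members))
                   min(lengths(members)) else 0L,
                 window_frames = 3L, n_cells = n_cells,
                 n_frames = 50L * length(members) + 10L),
            class = "dg_ne_set")
}

test_that("the participation matrix encodes event membership", {
  ne <- make_ne_set(list(c(1L, 3L)), 3L)
  P <- participation_matrix(ne)
  expect_equal(P, matrix(c(1, 0, 1), 3L, 1L))
  expect_identical(ncol(participation_matrix(make_ne_set(list(), 3L))), 0L)
  gs <- cached_session(4)
  det <- detect_network_events(gs$session$raster, 8L)
  P <- participation_matrix(det)
  expect_identical(unname(colSums(P)), as.numeric(lengths(det$ne_members)))
})

test_that("cosine similarity reproduces its analytic values", {
  P <- cbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(1, 0, 1))
  sim <- cosine_similarity_pairs(P)
  n <- attr(sim, "n")
  expect_identical(n, 4L)
  get <- function(i, j) {   # condensed lower-triangle lookup
    G <- matrix(NA_real_, n, n); G[lower.tri(G)] <- sim; G[j, i]
  }
  expect_equal(get(1, 2), 1)          # identical member sets
  expect_equal(get(1, 3), 0)          # disjoint member sets
  expect_equal(get(1, 4), 0.5)        # (1,1,0) vs (1,0,1)
  expect_true(all(sim >= 0 & sim <= 1))
  expect_error(cosine_similarity_pairs(P[, 1L, drop = FALSE]), "2 network")
})

test_that("the orthogonal-fraction test matches brute force and preserves sizes", {
  # structured design: 20 half-overlapping events over 100 cells
  set.seed(14)
  members <- lapply(1:20, function(e) ((e - 1L) * 4L + 1L):((e - 1L) * 4L + 8L))
  P <- participation_matrix(make_ne_set(members, 100L))
  res <- orthogonal_fraction_test(P, n_shuffles = 50L, seed = 2)
  # brute-force pair enumeration
  bf <- mean(combn(20L, 2L, function(ij)
    sum(P[, ij[1L]] * P[, ij[2L]]) == 0))
  expect_equal(res$observed, bf)
  expect_gte(res$p, 0); expect_lte(res$p, 1)
  # identical events: no orthogonal pair; disjoint events: all orthogonal
  P_id <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(orthogonal_fraction_test(P_id, 10L)$observed, 0)
  P_dis <- diag(4)
  expect_equal(orthogonal_fraction_test(P_dis, 10L)$observed, 1)
  # null draws preserve each event's participant count exactly
  set.seed(7)
  for (i in 1:20) {
    sizes <- sample(1:30, 5L)
    M <- dgnet:::orth_null_matrix(40L, sizes)
    expect_identical(unname(colSums(M)), as.numeric(sizes))
    expect_true(all(M %in% c(0, 1)))
  }
})

test_that("the clustering null preserves per-cell participation counts", {
  set.seed(15)
  P <- matrix(rbinom(30L * 12L, 1L, 0.3), 30L, 12L)
  for (i in 1:10) {
    M <- dgnet:::permute_participation_rows(P)
    expect_identical(rowSums(M), rowSums(P))
  }
  expect_error(cluster_threshold_null(P[, 1L, drop = FALSE]), "2 network")
})

test_that("the permutation r-threshold calibrates the pair pass-rate near 5%", {
  set.seed(16)
  P <- matrix(rbinom(40L * 15L, 1L, 0.3), 40L, 15L)
  thr <- cluster_threshold_null(P, n_shuffles = 200L, seed = 3)
  R <- suppressWarnings(cor(t(P)))
  pr <- R[lower.tri(R)]
  pr <- pr[!is.na(pr)]
  pass <- mean(pr > thr$r_threshold)
  # P is itself structureless, so ~5% of its pairs exceed the 95th percentile
  expect_gt(pass, 0.01)
  expect_lt(pass, 0.12)
})

test_that("clustering recovers planted ensembles and collapses degenerate input", {
  # identical rows: a single cluster containing every cell
  P_id <- matrix(rep(c(1, 0, 1, 0, 1), 6L), 6L, 5L, byrow = TRUE)
  cl <- hierarchical_clusters(P_id, r_threshold = 0.5)
  expect_length(cl$clusters, 1L)
  expect_identical(sort(cl$clusters[[1L]]), 1:6)
  expect_equal(cl$mean_intra_r, 1)

  # planted ensembles of sizes 5-9 co-active in >= 5 events
  set.seed(17)
  sizes <- c(5L, 7L, 9L)
  n_cl_cells <- sum(sizes)
  ncl <- 60L; ne <- 24L
  P <- matrix(rbinom(ncl * ne, 1L, 0.04), ncl, ne)
  truth <- split(seq_len(n_cl_cells), rep(seq_along(sizes), sizes))
  for (k in seq_along(sizes)) {
    evs <- seq(k, ne, by = length(sizes))         # 8 events per ensemble
    for (e in evs) P[truth[[k]], e] <- rbinom(sizes[k], 1L, 0.9)
  }
  thr <- cluster_threshold_null(P, n_shuffles = 200L, seed = 4)
  cl <- hierarchical_clusters(P, thr$r_threshold)
  jac <- vapply(truth, function(g)
    max(vapply(cl$clusters, function(h)
      length(intersect(g, h)) / length(union(g, h)), numeric(1L))),
    numeric(1L))
  expect_true(all(jac >= 0.7))
  expect_gte(mean(lengths(cl$clusters)), 5)
  expect_lte(mean(lengths(cl$clusters)), 9)
  expect_true(all(cl$mean_intra_r > thr$r_threshold))
  expect_true(all(lengths(cl$clusters) >= 2L))

  # structureless rows: clustered pairs stay near the 5% false-positive
  # budget implied by the 95th-percentile threshold
  set.seed(18)
  P0 <- matrix(rbinom(40L * 20L, 1L, 0.25), 40L, 20L)
  thr0 <- cluster_threshold_null(P0, n_shuffles = 200L, seed = 5)
  cl0 <- hierarchical_clusters(P0, thr0$r_threshold)
  pairs_in_clusters <- sum(choose(lengths(cl0$clusters), 2L))
  expect_lte(pairs_in_clusters, 2 * 0.05 * choose(40L, 2L))
})

test_that("cluster / tuned-cell overlap fractions follow set arithmetic", {
  cl <- structure(list(clusters = list(c(1L, 2L, 3L), c(4L, 5L)),
                       labels = c(1L, 1L, 1L, 2L, 2L, NA),
                       mean_intra_r = c(0.8, 0.9), r_threshold = 0.3,
                       tree = NULL), class = "dg_clusters")
  ov <- cluster_tuning_overlap(cl, place_ids = c(2L, 4L), speed_ids = 4L)
  expect_equal(ov$frac_place, 1)
  expect_equal(ov$frac_speed, 0.5)
  expect_equal(ov$frac_both, 0.5)
  expect_equal(ov$frac_neither, 0)
  expect_equal(ov$mean_place_per_cluster, 1)
  ov0 <- cluster_tuning_overlap(cl, integer(0), integer(0))
  expect_equal(ov0$frac_place, 0)
  empty <- structure(list(clusters = list(), labels = NA, mean_intra_r = numeric(0),
                          r_threshold = 0.3, tree = NULL), class = "dg_clusters")
  expect_true(is.na(cluster_tuning_overlap(empty, 1L, 2L)$frac_place))
})

test_that("cosine similarity is invariant to cell relabeling", {
  set.seed(19)
  P <- matrix(rbinom(25L * 8L, 1L, 0.3), 25L, 8L)
  P <- P[, colSums(P) > 0, drop = FALSE]
  perm <- sample.int(25L)
  expect_equal(as.numeric(cosine_similarity_pairs(P)),
               as.numeric(cosine_similarity_pairs(P[perm, ])))
})
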