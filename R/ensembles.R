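# Orthogonality of network events via cosine similarity with a permutation
# null, and discovery of correlated granule-cell sub-ensembles via
# null-thresholded agglomerative clustering.

#' Cell-by-event participation matrix
#'
#' `P[c, e] = 1` iff cell c is a member of network event e. The columns are
#' the population vectors of the individual network events.
#'
#' @param ne_set a `dg_ne_set` from [detect_network_events()].
#' @param n_cells number of cells (defaults to the NE set's).
#' @return binary matrix (n_cells x n_events).
#' @export
participation_matrix <- function(ne_set, n_cells = ne_set$n_cells) {
  ne <- length(ne_set$ne_frames)
  P <- matrix(0, n_cells, ne)
  for (e in seq_len(ne)) P[ne_set$ne_members[[e]], e] <- 1
  P
}

#' Pairwise cosine similarity between network events
#'
#' Normalized vector product between all pairs of NE population vectors. For
#' binary vectors the similarity lies in `[0, 1]`; identical member sets give
#' 1, disjoint sets give exactly 0.
#'
#' @param P participation matrix (cells x events).
#' @return condensed vector of similarities over event pairs, ordered as the
#'   lower triangle of the pair matrix (attribute `n` gives the number of
#'   events).
#' @export
cosine_similarity_pairs <- function(P) {
  ne <- ncol(P)
  if (ne < 2L) stop("need at least 2 network events")
  n2 <- colSums(P^2)
  zero <- n2 == 0
  if (any(zero)) {
    warning("excluding ", sum(zero), " empty population vector(s)")
    P <- P[, !zero, drop = FALSE]
    n2 <- n2[!zero]
    ne <- ncol(P)
    if (ne < 2L) stop("fewer than 2 non-empty population vectors")
  }
  # sqrt of the product (not product of sqrt) keeps identical columns at
  # exactly 1 in floating point
  G <- crossprod(P) / sqrt(outer(n2, n2))
  sim <- G[lower.tri(G)]
  attr(sim, "n") <- ne
  sim
}

#' Orthogonal-fraction test for network events
#'
#' The observed fraction of NE pairs with cosine similarity exactly 0
#' (disjoint member sets) is compared with a null built by redrawing each
#' event's members uniformly at random among all cells, preserving every
#' event's participant count. The one-sided p-value asks whether the real
#' events are more orthogonal than chance.
#'
#' @param P participation matrix (cells x events).
#' @param n_shuffles number of null draws (default 1000).
#' @param seed integer seed.
#' @return list with `observed` (fraction of zero-similarity pairs),
#'   `null` (vector of null fractions), `p` (fraction of null >= observed).
#' @export
orthogonal_fraction_test <- function(P, n_shuffles = 1000L, seed = 1L) {
  ncl <- nrow(P); ne <- ncol(P)
  if (ne < 2L) stop("need at least 2 network events")
  sizes <- colSums(P)
  orth_frac <- function(M) {
    G <- crossprod(M)
    mean(G[lower.tri(G)] == 0)
  }
  observed <- orth_frac(P)
  set.seed(seed)
  null <- vapply(seq_len(n_shuffles), function(b)
    orth_frac(orth_null_matrix(ncl, sizes)), numeric(1L))
  list(observed = observed, null = null, p = mean(null >= observed))
}

# One draw of the orthogonality null: every event's members are redrawn
# uniformly without replacement, preserving each event's participant count.
#' @keywords internal
#' @noRd
orth_null_matrix <- function(ncl, sizes) {
  M <- matrix(0, ncl, length(sizes))
  for (e in seq_along(sizes)) M[sample.int(ncl, sizes[e]), e] <- 1
  M
}

# One draw of the clustering null: each cell's participations are reassigned
# to uniformly chosen events (row-wise permutation across columns).
#' @keywords internal
#' @noRd
permute_participation_rows <- function(P) {
  ne <- ncol(P)
  t(apply(P, 1L, function(row) row[sample.int(ne)]))
}

# Pairwise Pearson r over participation rows; rows with zero variance give NA
# and are skipped by callers.
#' @keywords internal
#' @noRd
row_correlations <- function(P) {
  v <- apply(P, 1L, stats::var)
  R <- suppressWarnings(stats::cor(t(P)))
  R[v == 0, ] <- NA_real_
  R[, v == 0] <- NA_real_
  R
}

#' Permutation threshold for cluster correlations
#'
#' For each shuffle, every cell's NE participations are reassigned to
#' uniformly chosen events (independent permutation of each row of P across
#' columns), conserving per-cell participation counts. All pairwise Pearson r
#' values between cells are pooled across shuffles and the 95th percentile of
#' the pooled null is returned as the cluster-significance threshold.
#'
#' @param P participation matrix (cells x events).
#' @param n_shuffles number of shuffles (default 1000).
#' @param probs percentile of the null (default 0.95).
#' @param seed integer seed.
#' @return list with `r_threshold` and `null_r` (pooled null values).
#' @export
cluster_threshold_null <- function(P, n_shuffles = 1000L, probs = 0.95,
                                   seed = 1L) {
  if (ncol(P) < 2L) stop("need at least 2 network events for correlations")
  act <- rowSums(P) > 0
  P <- P[act, , drop = FALSE]
  if (nrow(P) < 2L) stop("need at least 2 participating cells")
  ne <- ncol(P)
  set.seed(seed)
  null_r <- vector("list", n_shuffles)
  for (b in seq_len(n_shuffles)) {
    R <- row_correlations(permute_participation_rows(P))
    null_r[[b]] <- R[lower.tri(R)]
  }
  null_r <- unlist(null_r)
  null_r <- null_r[!is.na(null_r)]
  list(r_threshold = unname(stats::quantile(null_r, probs)), null_r = null_r)
}

#' Sub-ensemble discovery by thresholded agglomerative clustering
#'
#' Cells are clustered on their NE-participation row vectors using a
#' standardized Euclidean distance (each coordinate scaled by its standard
#' deviation across cells) and weighted average linkage (WPGMA). Under the
#' default rule (`"maximal_subtree"`), the reported clusters are the maximal
#' nodes of the dendrogram whose mean internal pairwise Pearson r exceeds
#' `r_threshold`: agglomeration within such a node proceeds until adding
#' further cells would drop the cluster's internal mean below significance.
#' The alternative `"global_mean"` rule applies merges sequentially in tree
#' order while the pooled mean within-cluster r over all multi-member
#' clusters stays at or above the threshold, then reports the clusters whose
#' own mean exceeds it.
#'
#' Cells with fewer than `min_participations` event participations are
#' excluded beforehand: a correlation estimated from a single participation
#' is degenerate (any two single-event cells sharing that event correlate at
#' exactly 1). Reported clusters have at least 2 members and mean
#' intra-correlation above the threshold; identical nonconstant rows
#' correlate at 1.
#'
#' @param P participation matrix (cells x events).
#' @param r_threshold correlation threshold, typically from
#'   [cluster_threshold_null()].
#' @param merge_stop_rule `"maximal_subtree"` (default) or `"global_mean"`.
#' @param min_participations minimal event participations for a cell to
#'   enter the clustering (default 2).
#' @return an object of class `dg_clusters`: list with `clusters` (list of
#'   integer cell-id vectors, original indexing), `labels` (per-cell cluster
#'   id, NA when unclustered), `mean_intra_r` per cluster, `r_threshold`,
#'   and the `hclust` tree.
#' @export
hierarchical_clusters <- function(P, r_threshold,
                                  merge_stop_rule = c("maximal_subtree",
                                                      "global_mean"),
                                  min_participations = 2L) {
  merge_stop_rule <- match.arg(merge_stop_rule)
  act <- which(rowSums(P) >= max(1L, min_participations))
  M <- P[act, , drop = FALSE]
  n <- nrow(M)
  empty <- function() structure(list(clusters = list(),
                                     labels = rep(NA_integer_, nrow(P)),
                                     mean_intra_r = numeric(0),
                                     r_threshold = r_threshold, tree = NULL),
                                class = "dg_clusters")
  if (n < 3L) return(empty())
  # standardized Euclidean distance on participation rows
  sds <- apply(M, 2L, stats::sd)
  keep <- sds > 0
  Ms <- if (any(keep)) sweep(M[, keep, drop = FALSE], 2L, sds[keep], "/")
        else matrix(0, n, 1L)
  d <- stats::dist(Ms)
  tree <- stats::hclust(d, method = "mcquitty")
  R <- row_correlations(M)
  mean_intra <- function(members) {
    if (length(members) < 2L) return(NA_real_)
    rr <- R[members, members][lower.tri(matrix(0, length(members),
                                               length(members)))]
    rr <- rr[!is.na(rr)]
    if (length(rr) == 0L) return(NA_real_)
    mean(rr)
  }
  nm <- nrow(tree$merge)
  node_members <- vector("list", nm)      # leaves under each dendrogram node
  for (m in seq_len(nm)) {
    a <- tree$merge[m, 1L]; b <- tree$merge[m, 2L]
    node_members[[m]] <- c(if (a < 0) -a else node_members[[a]],
                           if (b < 0) -b else node_members[[b]])
  }
  if (merge_stop_rule == "maximal_subtree") {
    sig <- vapply(node_members, function(g) {
      mi <- mean_intra(g)
      !is.na(mi) && mi > r_threshold
    }, logical(1L))
    # top-down: report a significant node and do not descend into it
    groups <- list()
    stack <- nm                            # root is the last merge
    while (length(stack)) {
      m <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (sig[m]) {
        groups <- c(groups, list(node_members[[m]]))
      } else {
        for (child in tree$merge[m, ]) if (child > 0) stack <- c(stack, child)
      }
    }
  } else {
    # sequential walk in tree order; the pooled within-cluster pair mean is
    # maintained incrementally (a merge adds the cross pairs between groups)
    cur <- stats::setNames(as.list(seq_len(n)), paste0("s", seq_len(n)))
    pair_sum <- 0; pair_n <- 0L
    key <- function(code) if (code < 0) paste0("s", -code) else paste0("n", code)
    for (m in seq_len(nm)) {
      ka <- key(tree$merge[m, 1L]); kb <- key(tree$merge[m, 2L])
      ga <- cur[[ka]]; gb <- cur[[kb]]
      cross <- R[ga, gb]
      cross <- cross[!is.na(cross)]
      ns <- pair_sum + sum(cross); nn <- pair_n + length(cross)
      if (!(nn > 0L && ns / nn >= r_threshold)) break
      pair_sum <- ns; pair_n <- nn
      cur[[ka]] <- NULL; cur[[kb]] <- NULL
      cur[[paste0("n", m)]] <- c(ga, gb)
    }
    groups <- unname(cur)
  }
  groups <- Filter(function(g) length(g) >= 2L, groups)
  mi <- vapply(groups, mean_intra, numeric(1L))
  sel <- !is.na(mi) & mi > r_threshold
  groups <- groups[sel]; mi <- mi[sel]
  labels <- rep(NA_integer_, nrow(P))
  clusters <- lapply(groups, function(g) act[g])
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  structure(list(clusters = clusters, labels = labels, mean_intra_r = mi,
                 r_threshold = r_threshold, tree = tree),
            class = "dg_clusters")
}

#' @export
print.dg_clusters <- function(x, ...) {
  cat(sprintf("<dg_clusters>: %d significant cluster(s), r threshold %.3f\n",
              length(x$clusters), x$r_threshold))
  if (length(x$clusters))
    cat("  sizes:", paste(lengths(x$clusters), collapse = ", "), "\n")
  invisible(x)
}

#' Overlap of clusters with tuned cells
#'
#' Fractions of significant clusters containing at least one place cell, at
#' least one speed cell, or both, and the mean number of place/speed cells
#' per cluster.
#'
#' @param clusters a `dg_clusters`.
#' @param place_ids integer ids of place cells.
#' @param speed_ids integer ids of speed cells.
#' @return list with `frac_place`, `frac_speed`, `frac_both`, `frac_neither`,
#'   `mean_place_per_cluster`, `mean_speed_per_cluster`, `n_clusters`
#'   (fractions NA when there are no clusters).
#' @export
cluster_tuning_overlap <- function(clusters, place_ids, speed_ids) {
  gs <- clusters$clusters
  k <- length(gs)
  if (k == 0L)
    return(list(frac_place = NA_real_, frac_speed = NA_real_,
                frac_both = NA_real_, frac_neither = NA_real_,
                mean_place_per_cluster = NA_real_,
                mean_speed_per_cluster = NA_real_, n_clusters = 0L))
  np <- vapply(gs, function(g) length(intersect(g, place_ids)), integer(1L))
  ns <- vapply(gs, function(g) length(intersect(g, speed_ids)), integer(1L))
  list(frac_place = mean(np > 0), frac_speed = mean(ns > 0),
       frac_both = mean(np > 0 & ns > 0),
       frac_neither = mean(np == 0 & ns == 0),
       mean_place_per_cluster = mean(np), mean_speed_per_cluster = mean(ns),
       n_clusters = k)
}
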