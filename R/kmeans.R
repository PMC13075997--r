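# Seeded, deterministic k-means for gene-body signal matrices: Lloyd's
# algorithm with Euclidean distance and k-means++ initialization. Used to
# split gene-body occupancy heatmap rows into signal classes.

# Squared Euclidean distance of every row of x to each center (k x p).
dist2_to_centers <- function(x, centers) {
  d <- matrix(0, nrow(x), nrow(centers))
  for (j in seq_len(nrow(centers))) {
    d[, j] <- rowSums(sweep(x, 2, centers[j, ], "-")^2)
  }
  d
}

#' Seeded k-means++ clustering (Lloyd's algorithm)
#'
#' Deterministic given `seed`: centers are initialized with the k-means++
#' rule (first center sampled uniformly, subsequent centers with probability
#' proportional to squared distance from the nearest chosen center), then
#' Lloyd iterations run to an assignment fixed point or `max_iter`
#' iterations. The within-cluster sum of squares is non-increasing across
#' iterations. An emptied cluster is re-seeded from the point farthest from
#' its assigned center.
#'
#' @param x Numeric matrix, rows = observations. Missing cells are treated
#'   as 0 for distance purposes.
#' @param k Number of clusters; must not exceed the number of distinct rows.
#' @param seed Integer seed controlling the initialization.
#' @param max_iter Iteration cap (default 300).
#' @param n_start Number of independent k-means++ restarts (all derived
#'   deterministically from `seed`); the run with the smallest
#'   within-cluster sum of squares wins (default 10). Lloyd's algorithm
#'   only reaches a local optimum, so restarts guard against poor
#'   initializations.
#' @return A list: `cluster` (assignments, named by rownames), `centers`,
#'   `totss_within` (within-cluster sum of squares), `iterations`.
#' @export
kmeans_pp <- function(x, k, seed = 1, max_iter = 300, n_start = 10) {
  x <- as.matrix(x)
  x[is.na(x)] <- 0
  if (nrow(unique(x)) < k)
    sc_stop("k = %d exceeds the number of distinct rows (%d)", k, nrow(unique(x)))
  best <- NULL
  for (s in seq_len(n_start)) {
    fit <- kmeans_pp_once(x, k, derive_seed(seed, paste0("start", s)), max_iter)
    if (is.null(best) || fit$totss_within < best$totss_within) best <- fit
  }
  best
}

kmeans_pp_once <- function(x, k, seed, max_iter) {
  n <- nrow(x)
  centers <- with_seed(seed, {
    ctr <- matrix(NA_real_, k, ncol(x))
    ctr[1, ] <- x[sample.int(n, 1), ]
    if (k > 1) for (j in 2:k) {
      d2 <- apply(dist2_to_centers(x, ctr[seq_len(j - 1), , drop = FALSE]), 1, min)
      if (all(d2 == 0)) ctr[j, ] <- x[sample.int(n, 1), ]
      else ctr[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    ctr
  })
  assign <- rep(0L, n)
  it <- 0L
  repeat {
    it <- it + 1L
    d2 <- dist2_to_centers(x, centers)
    new_assign <- max.col(-d2, ties.method = "first")
    # re-seed any emptied cluster from the globally farthest point
    for (j in seq_len(k)) {
      if (!any(new_assign == j)) {
        far <- which.max(d2[cbind(seq_len(n), new_assign)])
        centers[j, ] <- x[far, ]
        new_assign[far] <- j
      }
    }
    if (identical(new_assign, assign) || it >= max_iter) {
      assign <- new_assign
      break
    }
    assign <- new_assign
    for (j in seq_len(k)) centers[j, ] <- colMeans(x[assign == j, , drop = FALSE])
  }
  d2 <- dist2_to_centers(x, centers)
  wss <- sum(d2[cbind(seq_len(n), assign)])
  names(assign) <- rownames(x)
  list(cluster = assign, centers = centers, totss_within = wss, iterations = it)
}

#' Split k-means clusters into high/low signal classes
#'
#' The cluster with the highest mean signal becomes the high class; the
#' remaining clusters are merged into the low class. Ties in cluster means
#' are broken toward the larger cluster (with a message).
#'
#' @param clusters Integer cluster assignments (e.g. from [kmeans_pp()]),
#'   named by gene id.
#' @param x The clustered matrix (rows aligned with `clusters`).
#' @param high_label,low_label Labels to emit.
#' @return Character vector of labels, named like `clusters`.
#' @export
assign_high_low <- function(clusters, x, high_label = "U2AF2_high",
                            low_label = "U2AF2_low") {
  x <- as.matrix(x)
  x[is.na(x)] <- 0
  ks <- sort(unique(clusters))
  mns <- vapply(ks, function(j) mean(x[clusters == j, , drop = FALSE]), numeric(1))
  sizes <- vapply(ks, function(j) sum(clusters == j), numeric(1))
  top <- which(mns == max(mns))
  if (length(top) > 1) {
    message("tie in cluster means; breaking toward the larger cluster")
    top <- top[which.max(sizes[top])]
  }
  out <- ifelse(clusters == ks[top], high_label, low_label)
  names(out) <- names(clusters)
  out
}
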