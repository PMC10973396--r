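#' Lloyd k-means with k-means++ initialization
#'
#' From-scratch k-means minimizing the within-cluster sum of squared
#' distances (WSS). Each of `n_init` restarts draws k-means++ starting
#' centers from a seeded generator, then iterates Lloyd's two steps
#' (assign to nearest center, recompute centroids) until the labels stop
#' changing or `max_iter` is reached; the restart with the lowest WSS is
#' returned. If a cluster empties during iteration its center is re-seeded
#' at the point farthest from its assigned center (deterministic given the
#' state).
#'
#' @param m Numeric matrix or data frame of observations.
#' @param k Number of clusters (<= rows of `m`).
#' @param seed Integer seed controlling initialization.
#' @param n_init Number of random restarts (>= 1).
#' @param max_iter Lloyd iteration cap per restart.
#' @return Object of class `kmeans_fit`: list with `labels`, `centers`,
#'   `wss`, `iterations`, `seed`, `k`.
#' @export
lloyd_kmeans <- function(m, k, seed = 1L, n_init = 10L, max_iter = 300L) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (k < 1 || k > n) abort("`k` must be between 1 and the number of rows.")
  if (n_init < 1) abort("`n_init` must be >= 1.")
  best <- NULL
  withr::with_seed(as.integer(seed), {
    for (run in seq_len(n_init)) {
      centers <- kmeanspp_init(m, k)
      fit <- lloyd_iterate(m, centers, max_iter)
      if (is.null(best) || fit$wss < best$wss) best <- fit
    }
  })
  best$seed <- as.integer(seed)
  best$k <- as.integer(k)
  names(best$labels) <- rownames(m)
  class(best) <- "kmeans_fit"
  best
}

# k-means++: first center uniform, then proportional to squared distance
# to the nearest chosen center
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  centers <- matrix(NA_real_, k, ncol(m))
  centers[1, ] <- m[sample.int(n, 1), ]
  if (k == 1) return(centers)
  d2 <- rowSums(sweep(m, 2, centers[1, ], "-")^2)
  for (j in 2:k) {
    if (all(d2 == 0)) {
      pick <- sample.int(n, 1)
    } else {
      pick <- sample.int(n, 1, prob = d2)
    }
    centers[j, ] <- m[pick, ]
    d2 <- pmin(d2, rowSums(sweep(m, 2, centers[j, ], "-")^2))
  }
  centers
}

assign_nearest <- function(m, centers) {
  cross <- tcrossprod(m, centers)              # n x k
  d2 <- outer(rowSums(m^2), rowSums(centers^2), "+") - 2 * cross
  max.col(-d2, ties.method = "first")
}

lloyd_iterate <- function(m, centers, max_iter) {
  k <- nrow(centers)
  labels <- assign_nearest(m, centers)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    for (j in seq_len(k)) {
      if (any(labels == j)) {
        centers[j, ] <- colMeans(m[labels == j, , drop = FALSE])
      }
    }
    # empty-cluster repair: move center to the globally farthest point
    for (j in seq_len(k)) {
      if (!any(labels == j)) {
        resid <- rowSums((m - centers[labels, , drop = FALSE])^2)
        centers[j, ] <- m[which.max(resid), ]
        labels <- assign_nearest(m, centers)
      }
    }
    new_labels <- assign_nearest(m, centers)
    if (identical(new_labels, labels) || iter >= max_iter) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  for (j in seq_len(k)) {
    if (any(labels == j)) {
      centers[j, ] <- colMeans(m[labels == j, , drop = FALSE])
    }
  }
  wss <- sum((m - centers[labels, , drop = FALSE])^2)
  list(labels = labels, centers = centers, wss = wss, iterations = iter)
}

#' @export
print.kmeans_fit <- function(x, ...) {
  cat("<kmeans_fit> k = ", x$k, ", WSS = ", format(x$wss),
      ", ", x$iterations, " iterations\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.kmeans_fit <- function(x, ...) {
  tb <- as_tibble(as.data.frame(x$centers))
  dplyr::bind_cols(tibble(cluster = seq_len(nrow(tb)),
                          size = tabulate(x$labels, nbins = nrow(tb))), tb)
}

#' @exportS3Method generics::glance
glance.kmeans_fit <- function(x, ...) {
  tibble(k = x$k, wss = x$wss, iterations = x$iterations, seed = x$seed)
}

#' Hybrid hierarchical + k-means clustering (hkmeans)
#'
#' Cuts a Ward.D2 tree of the data at `k`, computes the per-cluster
#' centroids, and runs a single deterministic Lloyd refinement initialized at
#' those centroids. Lloyd never increases the WSS of its initial partition,
#' so the hybrid result is at least as compact as the hierarchical cut.
#'
#' @inheritParams lloyd_kmeans
#' @param max_iter Lloyd iteration cap.
#' @return A `kmeans_fit` with an extra `hierarchical_labels` element holding
#'   the initializing tree-cut partition.
#' @export
hybrid_hkmeans <- function(m, k, max_iter = 300L) {
  m <- as.matrix(m)
  if (k < 1 || k > nrow(m)) abort("`k` must be between 1 and the number of rows.")
  dend <- ward_d2_linkage(pairwise_euclidean(m))
  hlab <- cut_dendrogram(dend, k = k)
  centers <- do.call(rbind, lapply(seq_len(k), function(j) {
    colMeans(m[hlab == j, , drop = FALSE])
  }))
  fit <- lloyd_iterate(m, centers, max_iter)
  fit$seed <- NA_integer_
  fit$k <- as.integer(k)
  fit$hierarchical_labels <- hlab
  names(fit$labels) <- rownames(m)
  class(fit) <- "kmeans_fit"
  fit
}

#' Within-cluster sum of squares of an arbitrary partition
#'
#' @param m Numeric matrix of observations.
#' @param labels Integer cluster labels, one per row.
#' @return Total WSS around the per-cluster centroids.
#' @export
partition_wss <- function(m, labels) {
  m <- as.matrix(m)
  sum(vapply(split(seq_len(nrow(m)), labels), function(ix) {
    sub <- m[ix, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub), "-")^2)
  }, numeric(1)))
}
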