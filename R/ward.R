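#' Pairwise Euclidean distance matrix
#'
#' @param m Numeric matrix or data frame (rows = observations).
#' @return Symmetric n x n matrix of Euclidean distances with zero diagonal
#'   and the row names of `m` as dimnames.
#' @export
pairwise_euclidean <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m) || any(!is.finite(m))) abort("Input must be finite numeric.")
  sq <- rowSums(m^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(m)
  d2[d2 < 0] <- 0  # clip tiny negatives from floating-point cancellation
  d <- sqrt(d2)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Ward.D2 agglomerative clustering
#'
#' From-scratch agglomeration by the Lance-Williams recurrence on *squared*
#' distances (the Ward.D2 variant of Murtagh & Legendre):
#' `D2(i+j, k) = ((n_i + n_k) D2(i,k) + (n_j + n_k) D2(j,k) - n_k D2(i,j)) /
#' (n_i + n_j + n_k)`. At every step the global minimum pair is merged and
#' the recorded height is the square root of its current squared distance,
#' i.e. heights are reported on the distance scale. Ties are broken towards
#' the pair with the smallest (left, right) member indices, so the merge
#' sequence is deterministic.
#'
#' @param d Symmetric distance matrix (e.g. from [pairwise_euclidean()]).
#' @return Object of class `ward_dendrogram`: list with an hclust-style
#'   `merge` matrix (negative entries are leaves), `height` vector of the
#'   n-1 merge heights, `labels`, and `n`.
#' @export
ward_d2_linkage <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 2) abort("Need at least 2 points.")
  if (!isTRUE(all.equal(d, t(d))) || any(d < 0) || any(diag(d) != 0)) {
    abort("`d` must be a symmetric non-negative matrix with zero diagonal.")
  }
  labels <- rownames(d) %||% as.character(seq_len(n))
  d2 <- d^2
  diag(d2) <- Inf
  active <- rep(TRUE, n)
  sizes <- rep(1L, n)
  cluster_id <- -seq_len(n)      # hclust convention: -leaf or +merge index
  first_leaf <- seq_len(n)       # smallest member index, for tie-breaking
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- d2[idx, idx, drop = FALSE]
    best <- which(sub == min(sub), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (left, right) smallest-member pair
    pi <- idx[best[, 1]]; pj <- idx[best[, 2]]
    key_l <- pmin(first_leaf[pi], first_leaf[pj])
    key_r <- pmax(first_leaf[pi], first_leaf[pj])
    pick <- order(key_l, key_r)[1]
    i <- pi[pick]; j <- pj[pick]
    height[step] <- sqrt(d2[i, j])
    left <- cluster_id[i]; right <- cluster_id[j]
    if (first_leaf[j] < first_leaf[i]) { tmp <- left; left <- right; right <- tmp }
    merge[step, ] <- c(left, right)

    # Lance-Williams update into slot i; retire slot j
    others <- setdiff(idx, c(i, j))
    if (length(others) > 0) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[others]
      dij <- d2[i, j]
      upd <- ((ni + nk) * d2[i, others] + (nj + nk) * d2[j, others] -
                nk * dij) / (ni + nj + nk)
      d2[i, others] <- upd
      d2[others, i] <- upd
    }
    sizes[i] <- sizes[i] + sizes[j]
    first_leaf[i] <- min(first_leaf[i], first_leaf[j])
    cluster_id[i] <- step
    active[j] <- FALSE
    d2[j, ] <- Inf
    d2[, j] <- Inf
  }
  structure(list(merge = merge, height = height, labels = labels, n = n,
                 method = "ward.D2"),
            class = "ward_dendrogram")
}

#' @export
print.ward_dendrogram <- function(x, ...) {
  cat("<ward_dendrogram> ", x$n, " leaves, ", length(x$height),
      " merges (Ward.D2)\n", sep = "")
  cat(sprintf("  merge heights: %.4g .. %.4g\n",
              min(x$height), max(x$height)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ward_dendrogram <- function(x, ...) {
  sizes <- merge_sizes(x)
  tibble(step = seq_along(x$height),
         left = x$merge[, 1], right = x$merge[, 2],
         height = x$height, size = sizes)
}

merge_sizes <- function(dend) {
  sz <- integer(length(dend$height))
  for (s in seq_along(sz)) {
    sz[s] <- sum(vapply(dend$merge[s, ], function(id) {
      if (id < 0) 1L else sz[id]
    }, integer(1)))
  }
  sz
}

leaf_order <- function(dend) {
  collect <- function(id) {
    if (id < 0) return(-id)
    c(collect(dend$merge[id, 1]), collect(dend$merge[id, 2]))
  }
  collect(length(dend$height))
}

#' @export
as.hclust.ward_dendrogram <- function(x, ...) {
  structure(list(merge = x$merge, height = x$height, order = leaf_order(x),
                 labels = x$labels, method = "ward.D2",
                 dist.method = "euclidean", call = match.call()),
            class = "hclust")
}

#' Cut a dendrogram into clusters
#'
#' Either into exactly `k` groups (the `k - 1` highest merges are undone) or
#' at a height threshold `h` (merges with height greater than `h` are
#' undone). Cluster labels are numbered by first-leaf order: the cluster
#' containing the first leaf is 1, the next new cluster along the leaves 2,
#' and so on.
#'
#' @param dend A [ward_d2_linkage()] result.
#' @param k Number of clusters (1..n), or `NULL`.
#' @param h Height threshold (>= 0), or `NULL`. Exactly one of `k`/`h` must
#'   be given.
#' @return Integer vector of cluster labels named by leaf label.
#' @export
cut_dendrogram <- function(dend, k = NULL, h = NULL) {
  stopifnot(inherits(dend, "ward_dendrogram"))
  n <- dend$n
  if (is.null(k) == is.null(h)) abort("Give exactly one of `k` or `h`.")
  if (!is.null(k)) {
    if (k < 1 || k > n) abort("`k` must be between 1 and the number of leaves.")
    n_apply <- n - k
  } else {
    if (h < 0) abort("`h` must be non-negative.")
    n_apply <- sum(dend$height <= h)
  }
  member <- seq_len(n)
  if (n_apply > 0) {
    cluster_members <- vector("list", length(dend$height))
    for (s in seq_len(n_apply)) {
      mem <- unlist(lapply(dend$merge[s, ], function(id) {
        if (id < 0) -id else cluster_members[[id]]
      }))
      cluster_members[[s]] <- mem
      member[mem] <- min(member[mem])
    }
  }
  labs <- match(member, unique(member))
  names(labs) <- dend$labels
  labs
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights (each child branch spans the
#' height difference to its parent merge). Requires the \pkg{ape} package.
#'
#' @param dend A [ward_d2_linkage()] result.
#' @param path Optional file to write to.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(dend, path = NULL) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the `ape` package.")
  }
  phy <- ape::as.phylo(as.hclust(dend))
  txt <- ape::write.tree(phy)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
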