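#' Cluster purity against known classes
#'
#' Purity is the fraction of points whose cluster's majority class matches
#' their own class: `(1/n) * sum over clusters of max class count`. Used here
#' to quantify how cleanly a clustering separates line types (CMS/B/R/SFP),
#' i.e. its "resolution power".
#'
#' @param labels Cluster labels.
#' @param classes Known class per point (same length).
#' @return List with `purity` (scalar) and `table`, a tibble of per-cluster
#'   size, majority class and majority fraction.
#' @export
cluster_purity <- function(labels, classes) {
  if (length(labels) == 0) abort("Empty input.")
  if (length(labels) != length(classes)) abort("Lengths differ.")
  ct <- table(labels, classes)
  maj <- apply(ct, 1, which.max)
  tb <- tibble(
    cluster = rownames(ct),
    n = as.integer(rowSums(ct)),
    majority_class = colnames(ct)[maj],
    majority_fraction = apply(ct, 1, max) / rowSums(ct)
  )
  list(purity = sum(apply(ct, 1, max)) / length(labels), table = tb)
}

#' Adjusted Rand index
#'
#' Hubert-Arabie chance-corrected agreement between two partitions, computed
#' from the contingency table. 1 for identical partitions, approximately 0
#' for independent random labelings, and can be negative.
#'
#' @param a,b Two label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) == 0) abort("Empty input.")
  if (length(a) != length(b)) abort("Lengths differ.")
  ct <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(ct, 2))
  sum_a <- sum(choose(rowSums(ct), 2))
  sum_b <- sum(choose(colSums(ct), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
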