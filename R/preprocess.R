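#' Yeo-Johnson power transform
#'
#' Elementwise transform `psi(x, lambda)`: for `x >= 0`,
#' `((x+1)^lambda - 1)/lambda` (`log(x+1)` when `lambda = 0`); for `x < 0`,
#' `-((1-x)^(2-lambda) - 1)/(2-lambda)` (`-log(1-x)` when `lambda = 2`).
#' Unlike Box-Cox it is defined for negative values and is strictly
#' increasing in `x` for every `lambda`.
#'
#' @param x Finite numeric vector.
#' @param lambda Transform exponent.
#' @return Transformed numeric vector.
#' @export
yeo_johnson <- function(x, lambda) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("`x` must be finite numeric.")
  }
  stopifnot(is.numeric(lambda), length(lambda) == 1, is.finite(lambda))
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) < 1e-12) {
    out[pos] <- log1p(x[pos])
  } else {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  }
  if (abs(lambda - 2) < 1e-12) {
    out[!pos] <- -log1p(-x[!pos])
  } else {
    out[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  }
  out
}

yj_profile_loglik <- function(x, lambda) {
  n <- length(x)
  z <- yeo_johnson(x, lambda)
  s2 <- mean((z - mean(z))^2)
  if (s2 <= 0) return(-Inf)
  -n / 2 * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
}

#' Fit the Yeo-Johnson exponent by maximum likelihood
#'
#' Maximizes the Gaussian profile log-likelihood of the transformed data,
#' including the Jacobian term, over `lambda` in `interval`. The search uses
#' a coarse grid to bracket the best region followed by golden-section
#' refinement, so multimodal profiles are handled.
#'
#' @param x Numeric vector, length >= 3, non-constant.
#' @param interval Search interval for `lambda` (default `[-5, 5]`).
#' @return Object of class `yj_fit`: list with `lambda` and `loglik`.
#' @export
fit_yeo_johnson <- function(x, interval = c(-5, 5)) {
  if (!is.numeric(x) || any(!is.finite(x))) abort("`x` must be finite numeric.")
  if (length(x) < 3) abort("Need at least 3 observations to fit lambda.")
  if (var(x) == 0) abort("Cannot fit lambda on a constant vector.")
  grid <- seq(interval[1], interval[2], length.out = 101)
  ll <- vapply(grid, function(l) yj_profile_loglik(x, l), numeric(1))
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(l) yj_profile_loglik(x, l),
                  interval = c(lo, hi), maximum = TRUE, tol = 1e-6)
  structure(list(lambda = opt$maximum, loglik = opt$objective),
            class = "yj_fit")
}

#' @export
print.yj_fit <- function(x, ...) {
  cat(sprintf("<yj_fit> lambda = %.4f (profile log-likelihood %.3f)\n",
              x$lambda, x$loglik))
  invisible(x)
}

#' Min-max scale columns to [0, 1]
#'
#' Each column is mapped by `(x - min) / (max - min)`; the per-column minima
#' and maxima are recorded in attributes `scaled_min` / `scaled_max`.
#' Constant columns are mapped to 0 (with a warning) rather than dropped, so
#' column bookkeeping is preserved. Columns already in `{0,1}` are unchanged.
#'
#' @param x Data frame or matrix of finite numeric columns.
#' @return Tibble of scaled columns with scaling attributes.
#' @export
minmax_scale <- function(x) {
  m <- as.matrix(x)
  if (!is.numeric(m) || any(!is.finite(m))) abort("Input must be finite numeric.")
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    warn(paste0("Constant columns mapped to 0: ",
                toString(colnames(m)[const])))
    rng[const] <- 1
  }
  scaled <- sweep(sweep(m, 2, lo, "-"), 2, rng, "/")
  scaled[, const] <- 0
  out <- as_tibble(as.data.frame(scaled))
  attr(out, "scaled_min") <- lo
  attr(out, "scaled_max") <- hi
  out
}

#' Integrate panel blocks into one [0,1] feature matrix
#'
#' Concatenates column-wise the (optionally Yeo-Johnson transformed, then
#' min-max scaled) continuous traits with the binary SSR and protein blocks.
#' Binary columns already lie in `{0,1}` and are never transformed. All blocks
#' enter with equal weight. Row order equals panel row order.
#'
#' @param panel A [germplasm_panel()].
#' @param yeo_johnson If `TRUE` (default), each trait column passes through a
#'   fitted Yeo-Johnson transform before min-max scaling.
#' @return A numeric matrix of class `feature_matrix` with genotype ids as row
#'   names and attributes `provenance` (per-column tag in
#'   trait/ssr/protein), `lambda` (fitted exponents, when used) and the
#'   recorded trait min/max.
#' @export
integrate_features <- function(panel, yeo_johnson = TRUE) {
  stopifnot(inherits(panel, "germplasm_panel"))
  blocks <- list()
  lambda <- NULL
  prov <- character(0)
  if (ncol(panel$traits) > 0) {
    tr <- panel$traits
    if (yeo_johnson) {
      yj_fn <- get("yeo_johnson", mode = "function")  # arg shadows the function
      fits <- lapply(tr, fit_yeo_johnson)
      lambda <- vapply(fits, `[[`, numeric(1), "lambda")
      tr <- as_tibble(purrr::map2(tr, lambda, yj_fn))
    }
    tr <- minmax_scale(tr)
    blocks$traits <- as.matrix(tr)
    prov <- c(prov, rep("trait", ncol(tr)))
  }
  if (ncol(panel$ssr) > 0) {
    blocks$ssr <- as.matrix(panel$ssr)
    prov <- c(prov, rep("ssr", ncol(panel$ssr)))
  }
  if (ncol(panel$protein) > 0) {
    blocks$protein <- as.matrix(panel$protein)
    prov <- c(prov, rep("protein", ncol(panel$protein)))
  }
  if (length(blocks) == 0) abort("Panel has no feature columns.")
  m <- do.call(cbind, unname(blocks))
  rownames(m) <- panel$info$genotype
  structure(m, class = c("feature_matrix", "matrix", "array"),
            provenance = prov, lambda = lambda)
}

#' @exportS3Method generics::tidy
tidy.feature_matrix <- function(x, ...) {
  dplyr::bind_cols(tibble(genotype = rownames(x)),
                   as_tibble(as.data.frame(unclass(x))))
}
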