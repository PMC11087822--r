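# Drug-drug similarity kernels from binary feature vectors.

#' Gaussian RBF kernel between drug feature vectors
#'
#' Computes `k(x_i, x_j) = exp(-||x_i - x_j||^2 / (2 sigma^2))` for every
#' query/reference drug pair. For `X_query = X_ref` the result is symmetric
#' with unit diagonal and positive semidefinite.
#'
#' @param X_query [feature_table()] of query drugs (rows of the kernel).
#' @param X_ref [feature_table()] of reference drugs (columns); must share
#'   the same feature space (identical `feature_ids` in the same order).
#' @param sigma kernel width, in feature-space distance units; > 0.
#' @return A `kernel_matrix` with entries in (0, 1].
#' @export
rbf_kernel <- function(X_query, X_ref = X_query, sigma) {
  stopifnot(inherits(X_query, "feature_table"), inherits(X_ref, "feature_table"))
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  if (!identical(X_query$feature_ids, X_ref$feature_ids)) {
    stop("query and reference feature spaces do not match", call. = FALSE)
  }
  A <- X_query$values
  B <- X_ref$values
  # ||a - b||^2 = ||a||^2 + ||b||^2 - 2 a.b, clamped at 0 against roundoff
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  K <- exp(-d2 / (2 * sigma^2))
  dimnames(K) <- list(X_query$drug_ids, X_ref$drug_ids)
  structure(list(values = K, sigma = sigma,
                 source_features = X_query$feature_name),
            class = "kernel_matrix")
}

#' Linear combination of kernels for feature integration
#'
#' Entrywise weighted sum of kernels sharing identical drug orderings, with
#' weights normalized to sum to 1 so a unit diagonal is preserved.
#'
#' @param kernels list of `kernel_matrix` objects with identical row and
#'   column drug id orderings.
#' @param weights non-negative weights, one per kernel, sum > 0. Default
#'   equal weights.
#' @return A combined `kernel_matrix`.
#' @export
combine_kernels <- function(kernels, weights = rep(1, length(kernels))) {
  stopifnot(length(kernels) >= 1L, length(weights) == length(kernels))
  if (any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be non-negative with positive sum", call. = FALSE)
  }
  ref <- kernels[[1L]]
  for (k in kernels[-1L]) {
    if (!identical(dimnames(k$values), dimnames(ref$values))) {
      stop("kernels must share identical drug orderings", call. = FALSE)
    }
  }
  w <- weights / sum(weights)
  V <- w[1L] * ref$values
  for (i in seq_along(kernels)[-1L]) V <- V + w[i] * kernels[[i]]$values
  structure(list(values = V,
                 sigma = vapply(kernels, `[[`, numeric(1), "sigma"),
                 source_features = paste(
                   vapply(kernels, function(k) paste(k$source_features,
                                                     collapse = "+"),
                          character(1)), collapse = "+")),
            class = "kernel_matrix")
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("kernel_matrix (%s): %d x %d, sigma = %s\n",
              x$source_features, nrow(x$values), ncol(x$values),
              paste(signif(x$sigma, 4), collapse = ", ")))
  invisible(x)
}
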