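# The four predictors: naive prevalence baseline, kernel ridge regression
# (KR), multiple kernel regression (MKR), and VKR (NMF + KR on the drug
# factor). All produce real-valued score matrices (ADR x new drug); scores
# are ranking scores, never probabilities.

#' Naive prevalence baseline
#'
#' Scores every new drug for ADR i with the prevalence of ADR i among the
#' known drugs: `score(i, j) = mean_k Y[i, k]`, constant across new drugs.
#'
#' @param Y_known [interaction_matrix()] of known drugs.
#' @param new_drug_ids ids of the drugs to score.
#' @return score matrix, ADRs x new drugs.
#' @export
naive_fit_predict <- function(Y_known, new_drug_ids) {
  stopifnot(inherits(Y_known, "interaction_matrix"))
  if (ncol(Y_known$values) == 0L) stop("no known drugs", call. = FALSE)
  prev <- rowMeans(Y_known$values)
  scores <- matrix(prev, nrow = length(prev), ncol = length(new_drug_ids),
                   dimnames = list(Y_known$adr_ids, as.character(new_drug_ids)))
  scores
}

#' Fit kernel ridge regression coefficients
#'
#' Minimizes `||T - K W||^2 + lambda ||W||^2` (Frobenius norms) over W,
#' where T is the target matrix. The unique minimizer for lambda > 0 is
#' `W = (K'K + lambda I)^{-1} K' T`, computed by a stable linear solve.
#' Targets are the transposed label matrix for plain KR and the NMF drug
#' factor V for VKR.
#'
#' `form = "rkhs"` instead solves the classical kernel-ridge system
#' `W = (K + lambda I)^{-1} T`, provided for comparison.
#'
#' @param K `kernel_matrix`, square, training drugs x training drugs.
#' @param targets numeric matrix, rows ordered as K's rows.
#' @param lambda ridge penalty, >= 0 (`lambda = 0` requires invertibility).
#' @param form `"primal"` (the penalized least-squares objective above,
#'   default) or `"rkhs"`.
#' @return A `coefficient_matrix` with fields `W`, `lambda`, `form`.
#' @export
kr_fit <- function(K, targets, lambda, form = c("primal", "rkhs")) {
  form <- match.arg(form)
  stopifnot(inherits(K, "kernel_matrix"))
  Km <- K$values
  targets <- as.matrix(targets)
  if (nrow(Km) != ncol(Km)) stop("K must be square", call. = FALSE)
  if (nrow(targets) != nrow(Km)) {
    stop("target rows must match kernel dimension", call. = FALSE)
  }
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0) {
    stop("lambda must be a non-negative scalar", call. = FALSE)
  }
  N <- nrow(Km)
  W <- tryCatch({
    if (form == "primal") {
      A <- crossprod(Km) + diag(lambda, N)
      solve(A, crossprod(Km, targets))
    } else {
      solve(Km + diag(lambda, N), targets)
    }
  }, error = function(e) {
    stop("kernel system is singular; use lambda > 0 (", conditionMessage(e),
         ")", call. = FALSE)
  })
  rownames(W) <- rownames(Km)
  structure(list(W = W, lambda = lambda, form = form),
            class = "coefficient_matrix")
}

#' Predict with fitted kernel ridge coefficients
#'
#' Returns `K_new %*% W`: one row per new drug, one column per target.
#'
#' @param K_new `kernel_matrix` of new drugs (rows) vs training drugs
#'   (columns, ordered as the rows of `W`).
#' @param W a `coefficient_matrix` from [kr_fit()].
#' @return numeric matrix, new drugs x targets.
#' @export
kr_predict <- function(K_new, W) {
  stopifnot(inherits(K_new, "kernel_matrix"), inherits(W, "coefficient_matrix"))
  if (ncol(K_new$values) != nrow(W$W)) {
    stop("K_new columns must match coefficient rows", call. = FALSE)
  }
  K_new$values %*% W$W
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a non-negative matrix `Y ~ U V'` (U: ADRs x L, V: drugs x L,
#' both non-negative) by minimizing the Frobenius objective
#' `||Y - U V'||^2` with Lee-Seung multiplicative updates, which make the
#' objective non-increasing at every iteration. Factors are initialized
#' uniform-random non-negative, scaled so `mean(U V') = mean(Y)`, from
#' `seed`. A small constant (1e-12) inside update denominators guards
#' against zero-locking on sparse data.
#'
#' @param Y an [interaction_matrix()] or non-negative numeric matrix.
#' @param L number of components, `1 <= L <= min(dim(Y))`.
#' @param seed integer RNG seed for the initialization.
#' @param max_iter maximum update sweeps (default 500).
#' @param tol stop when the relative objective decrease falls below this
#'   (default 1e-6).
#' @return A `factor_pair` with `U`, `V`, `L`, final `objective`, `n_iter`,
#'   `seed`, and the per-iteration `objective_trace`.
#' @export
nmf_factorize <- function(Y, L, seed, max_iter = 500L, tol = 1e-6) {
  Ym <- if (inherits(Y, "interaction_matrix")) Y$values else as.matrix(Y)
  if (any(Ym < 0)) stop("Y must be non-negative", call. = FALSE)
  M <- nrow(Ym); N <- ncol(Ym)
  if (!(L >= 1 && L <= min(M, N))) {
    stop("L must be in 1..min(dim(Y))", call. = FALSE)
  }
  L <- as.integer(L)
  eps <- 1e-12
  mean_y <- mean(Ym)
  if (mean_y == 0) {
    U <- matrix(0, M, L); V <- matrix(0, N, L)
    return(structure(list(U = U, V = V, L = L, objective = 0,
                          n_iter = 0L, seed = as.integer(seed),
                          objective_trace = numeric(0)),
                     class = "factor_pair"))
  }
  init <- with_seed(seed, list(U = matrix(runif(M * L), M, L),
                               V = matrix(runif(N * L), N, L)))
  U <- init$U; V <- init$V
  # scale so the reconstruction matches Y's mean: E[UV'] = L/4 before scaling
  s <- sqrt(mean_y / mean(tcrossprod(U, V)))
  U <- U * s; V <- V * s
  obj <- sum((Ym - tcrossprod(U, V))^2)
  trace <- numeric(max_iter)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    U <- U * (Ym %*% V) / (U %*% crossprod(V) + eps)
    V <- V * (crossprod(Ym, U)) / (V %*% crossprod(U) + eps)
    new_obj <- sum((Ym - tcrossprod(U, V))^2)
    trace[it] <- new_obj
    if (obj > 0 && (obj - new_obj) / obj < tol) {
      obj <- new_obj
      break
    }
    obj <- new_obj
  }
  rownames(U) <- rownames(Ym); rownames(V) <- colnames(Ym)
  structure(list(U = U, V = V, L = L, objective = obj, n_iter = it,
                 seed = as.integer(seed), objective_trace = trace[seq_len(it)]),
            class = "factor_pair")
}

#' Fit the VKR model (NMF then kernel ridge on the drug factor)
#'
#' Step 1 factorizes the known-drug ADR matrix `Y ~ U V'` with
#' [nmf_factorize()]; step 2 regresses the drug factor V on the drug kernel
#' with [kr_fit()]. New-drug profiles are then reconstructed by
#' [vkr_predict()] as `U (K_new W)'`.
#'
#' @param Y_known [interaction_matrix()] of known drugs.
#' @param K training `kernel_matrix` indexed by the known drugs.
#' @param L NMF component count.
#' @param lambda ridge penalty for the KR step.
#' @param seed seed for the NMF initialization.
#' @param ... passed to [nmf_factorize()] (`max_iter`, `tol`) and
#'   [kr_fit()] (`form`).
#' @return list with `factors` (a `factor_pair`) and `coef`
#'   (a `coefficient_matrix`).
#' @export
vkr_fit <- function(Y_known, K, L, lambda, seed, ...) {
  stopifnot(inherits(Y_known, "interaction_matrix"),
            inherits(K, "kernel_matrix"))
  dots <- list(...)
  nmf_args <- dots[names(dots) %in% c("max_iter", "tol")]
  kr_args <- dots[names(dots) %in% "form"]
  fp <- do.call(nmf_factorize,
                c(list(Y = Y_known, L = L, seed = seed), nmf_args))
  cm <- do.call(kr_fit, c(list(K = K, targets = fp$V, lambda = lambda),
                          kr_args))
  list(factors = fp, coef = cm)
}

#' Predict new-drug ADR profiles with a fitted VKR model
#'
#' Computes `scores = U (K_new W)'`, an ADRs x new-drugs matrix: the kernel
#' regression extrapolates the drug factor to the new drugs
#' (`V_new = K_new W`) and the ADR factor U maps it back to ADR space.
#'
#' @param U ADR factor (M x L), e.g. `fit$factors$U`.
#' @param W a `coefficient_matrix` from the KR step (`fit$coef`).
#' @param K_new `kernel_matrix` of new vs training drugs.
#' @return score matrix, ADRs x new drugs.
#' @export
vkr_predict <- function(U, W, K_new) {
  V_new <- kr_predict(K_new, W)          # N' x L
  if (ncol(U) != ncol(V_new)) {
    stop("component counts of U and K_new %*% W do not match", call. = FALSE)
  }
  scores <- U %*% t(V_new)
  dimnames(scores) <- list(rownames(U), rownames(K_new$values))
  scores
}

#' Multiple kernel regression: mix two single-kernel KR score matrices
#'
#' Fits one KR model per kernel and blends the two prediction score
#' matrices: `mix * s1 + (1 - mix) * s2`.
#'
#' @param kernel_pairs list of 2 elements, each `list(train = K, new =
#'   K_new)` with identically ordered drugs.
#' @param targets target matrix (training drugs x T), e.g. `t(Y_known)`.
#' @param lambdas length-2 ridge penalties, one per kernel.
#' @param mix weight of the first kernel's scores, in `[0, 1]`.
#' @param form passed to [kr_fit()].
#' @return numeric matrix, new drugs x T.
#' @export
mkr_fit_predict <- function(kernel_pairs, targets, lambdas, mix = 0.5,
                            form = "primal") {
  stopifnot(length(kernel_pairs) == 2L, length(lambdas) == 2L)
  if (!is.numeric(mix) || length(mix) != 1L || mix < 0 || mix > 1) {
    stop("mix must be in [0, 1]", call. = FALSE)
  }
  preds <- lapply(1:2, function(i) {
    w <- kr_fit(kernel_pairs[[i]]$train, targets, lambdas[[i]], form = form)
    kr_predict(kernel_pairs[[i]]$new, w)
  })
  mix * preds[[1L]] + (1 - mix) * preds[[2L]]
}

#' @export
print.factor_pair <- function(x, ...) {
  cat(sprintf("factor_pair: %d x %d (U), %d x %d (V), L = %d, objective %.6g after %d iterations\n",
              nrow(x$U), ncol(x$U), nrow(x$V), ncol(x$V), x$L, x$objective,
              x$n_iter))
  invisible(x)
}
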