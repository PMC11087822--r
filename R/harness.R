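# Model harness: a uniform fit-on-known-drugs / predict-for-new-drugs
# surface over the four methods, hyperparameter grids, seeded grid-search
# CV, 5x4 nested CV and hold-out evaluation.

#' Hyperparameter grid
#'
#' Defaults follow the study protocol: component counts {5, 10, 15, 20, 25}
#' and log-spaced lambda/sigma grids. The unbounded printed grids
#' `{..., 1e-2, ..., 1e2, ...}` are bounded here to `1e-3 .. 1e3`
#' (7 values). The MKR mix weight defaults to 0.5.
#'
#' @param L_values NMF component counts (VKR only).
#' @param lambda_values ridge penalties, > 0 for tuning.
#' @param sigma_values RBF kernel widths, > 0.
#' @param mix_values MKR mixing weights in `[0, 1]`.
#' @return A `hyper_grid` list.
#' @export
hyper_grid <- function(L_values = c(5, 10, 15, 20, 25),
                       lambda_values = 10^(-3:3),
                       sigma_values = 10^(-3:3),
                       mix_values = 0.5) {
  stopifnot(all(lambda_values > 0), all(sigma_values > 0),
            all(mix_values >= 0 & mix_values <= 1), all(L_values >= 1))
  structure(list(L_values = sort(unique(L_values)),
                 lambda_values = sort(unique(lambda_values)),
                 sigma_values = sort(unique(sigma_values)),
                 mix_values = sort(unique(mix_values))),
            class = "hyper_grid")
}

#' Model specification
#'
#' Names a predictor and its fixed (non-tuned) options. The spec plus a
#' hyperparameter combination fully determines a fit.
#'
#' @param method one of `"naive"`, `"kr"`, `"mkr"`, `"vkr"`.
#' @param kernel_form `"primal"` (the penalized least-squares objective) or
#'   `"rkhs"`; passed to [kr_fit()].
#' @param weights kernel combination weights when several feature tables
#'   are supplied to `"kr"`/`"vkr"` (default equal).
#' @return A `model_spec`.
#' @export
model_spec <- function(method = c("naive", "kr", "mkr", "vkr"),
                       kernel_form = c("primal", "rkhs"),
                       weights = NULL) {
  structure(list(method = match.arg(method),
                 kernel_form = match.arg(kernel_form),
                 weights = weights),
            class = "model_spec")
}

# Expand the tuning grid for one method into a data.frame of combinations.
# Columns are always L, lambda, sigma, mix (NA where not applicable).
expand_method_grid <- function(spec, grid) {
  g <- switch(spec$method,
    naive = data.frame(L = NA_real_, lambda = NA_real_, sigma = NA_real_,
                       mix = NA_real_),
    kr = expand.grid(L = NA_real_, lambda = grid$lambda_values,
                     sigma = grid$sigma_values, mix = NA_real_),
    vkr = expand.grid(L = grid$L_values, lambda = grid$lambda_values,
                      sigma = grid$sigma_values, mix = NA_real_),
    mkr = expand.grid(L = NA_real_, lambda = grid$lambda_values,
                      sigma = grid$sigma_values, mix = grid$mix_values)
  )
  unique(g)
}

# Build the training and query kernels for one sigma: one RBF kernel per
# feature table, combined with the spec's weights (default equal).
build_kernels <- function(spec, features, train_ids, query_ids, sigma) {
  ks <- lapply(features, function(ft) {
    Xt <- subset_drugs(ft, train_ids)
    list(train = rbf_kernel(Xt, Xt, sigma),
         new = rbf_kernel(subset_drugs(ft, query_ids), Xt, sigma))
  })
  if (length(ks) == 1L) return(ks[[1L]])
  w <- if (is.null(spec$weights)) rep(1, length(ks)) else spec$weights
  list(train = combine_kernels(lapply(ks, `[[`, "train"), w),
       new = combine_kernels(lapply(ks, `[[`, "new"), w))
}

#' Fit a model on known drugs and score new drugs
#'
#' The single entry point used by every evaluation harness: trains the
#' method named in `spec` on `Y_known` (never seeing any new-drug label)
#' and returns ranking scores for the new drugs.
#'
#' @param spec a [model_spec()].
#' @param Y_known [interaction_matrix()] of the known (training) drugs.
#' @param features named list of [feature_table()] covering training and
#'   new drugs (ignored by `"naive"`; `"mkr"` needs exactly 2).
#' @param new_drug_ids drugs to score.
#' @param hyper list/row with `L`, `lambda`, `sigma`, `mix` as the method
#'   requires.
#' @param seed seed for stochastic components (NMF initialization).
#' @return score matrix, ADRs x new drugs.
#' @export
fit_predict <- function(spec, Y_known, features, new_drug_ids, hyper,
                        seed = 1L) {
  stopifnot(inherits(spec, "model_spec"), inherits(Y_known, "interaction_matrix"))
  new_drug_ids <- as.character(new_drug_ids)
  if (spec$method == "naive") {
    return(naive_fit_predict(Y_known, new_drug_ids))
  }
  if (inherits(features, "feature_table")) features <- list(features)
  train_ids <- Y_known$drug_ids
  if (spec$method == "mkr") {
    if (length(features) != 2L) {
      stop("mkr requires exactly 2 feature tables", call. = FALSE)
    }
    pairs <- lapply(features, function(ft) {
      Xt <- subset_drugs(ft, train_ids)
      list(train = rbf_kernel(Xt, Xt, hyper$sigma),
           new = rbf_kernel(subset_drugs(ft, new_drug_ids), Xt, hyper$sigma))
    })
    lam <- if (length(hyper$lambda) == 2L) hyper$lambda else
      rep(hyper$lambda, 2L)
    pred <- mkr_fit_predict(unname(pairs), t(Y_known$values), lam,
                            mix = hyper$mix, form = spec$kernel_form)
    scores <- t(pred)
    dimnames(scores) <- list(Y_known$adr_ids, new_drug_ids)
    return(scores)
  }
  kp <- build_kernels(spec, features, train_ids, new_drug_ids, hyper$sigma)
  if (spec$method == "kr") {
    w <- kr_fit(kp$train, t(Y_known$values), hyper$lambda,
                form = spec$kernel_form)
    scores <- t(kr_predict(kp$new, w))
    dimnames(scores) <- list(Y_known$adr_ids, new_drug_ids)
    return(scores)
  }
  # vkr
  fit <- vkr_fit(Y_known, kp$train, L = hyper$L, lambda = hyper$lambda,
                 seed = seed, form = spec$kernel_form)
  vkr_predict(fit$factors$U, fit$coef, kp$new)
}

# Deterministic tie-break among equal-criterion combinations: stronger
# regularization first (larger lambda), then smaller L, then smaller sigma,
# then smaller mix.
order_combos <- function(g) {
  order(-replace(g$lambda, is.na(g$lambda), Inf),
        replace(g$L, is.na(g$L), -Inf),
        replace(g$sigma, is.na(g$sigma), -Inf),
        replace(g$mix, is.na(g$mix), -Inf))
}

#' Grid-search cross-validation on known drugs
#'
#' For every hyperparameter combination, fits on each training split and
#' scores micro-pooled metrics on the validation split (masked as new
#' drugs); returns the combination maximizing the mean criterion (AUPR).
#' Folds whose pooled truth is single-class are skipped with a warning.
#'
#' @param spec a [model_spec()].
#' @param Y [interaction_matrix()] of the drugs available for tuning.
#' @param features named list of [feature_table()].
#' @param grid a [hyper_grid()].
#' @param n_folds folds for the tuning CV (default 5).
#' @param seed seed for the fold plan and model fits.
#' @param criterion optimized metric; `"aupr"` only.
#' @return list with `best` (named hyperparameter list) and `table`
#'   (per-combination mean metrics).
#' @export
grid_search_cv <- function(spec, Y, features, grid, n_folds = 5L, seed,
                           criterion = "aupr") {
  criterion <- match.arg(criterion, "aupr")
  combos <- expand_method_grid(spec, grid)
  fp <- make_folds(Y$drug_ids, n_folds, seed)
  fold_sets <- split(names(fp$assignments), fp$assignments)
  sums_aupr <- numeric(nrow(combos))
  sums_auroc <- numeric(nrow(combos))
  n_scored <- integer(nrow(combos))
  for (f in seq_along(fold_sets)) {
    val_ids <- fold_sets[[f]]
    masked <- mask_new_drugs(Y, val_ids)
    lab <- as.vector(masked$Y_truth_new$values)
    if (all(lab == 0) || all(lab == 1)) {
      warning(sprintf("fold %d skipped: pooled validation truth is single-class",
                      f - 1L))
      next
    }
    for (ci in seq_len(nrow(combos))) {
      sc <- fit_predict(spec, masked$Y_known, features, val_ids,
                        as.list(combos[ci, ]), seed = seed)
      m <- pool_and_score(masked$Y_truth_new, sc)
      sums_aupr[ci] <- sums_aupr[ci] + m[["aupr"]]
      sums_auroc[ci] <- sums_auroc[ci] + m[["auroc"]]
      n_scored[ci] <- n_scored[ci] + 1L
    }
  }
  if (all(n_scored == 0L)) {
    stop("all folds were single-class; cannot tune", call. = FALSE)
  }
  tab <- combos
  tab$mean_aupr <- sums_aupr / n_scored
  tab$mean_auroc <- sums_auroc / n_scored
  tab$n_folds_scored <- n_scored
  pref <- order_combos(combos)
  best_idx <- pref[which.max(tab$mean_aupr[pref])]
  list(best = as.list(combos[best_idx, ]), table = tab)
}

#' Nested cross-validation (outer evaluation, inner tuning)
#'
#' The default 5x4 protocol: drugs are split into `outer` folds; in each
#' outer fold an inner `inner`-fold grid-search CV on the outer-training
#' drugs selects the hyperparameters, the model is refit on the full
#' outer-training set, and the outer-validation drugs are scored as masked
#' new drugs. Hyperparameters never see the data they are evaluated on.
#' The fold plan depends only on `seed` and the drug ids, so different
#' methods run under the same seed share folds exactly — the precondition
#' for paired t-tests across methods.
#'
#' @inheritParams grid_search_cv
#' @param outer number of outer folds (default 5).
#' @param inner number of inner tuning folds (default 4).
#' @return An `eval_report` with per-fold metrics and chosen
#'   hyperparameters, means and standard deviations.
#' @export
nested_cv <- function(spec, Y, features, grid, outer = 5L, inner = 4L, seed) {
  fp <- make_folds(Y$drug_ids, outer, seed)
  fold_sets <- split(names(fp$assignments), fp$assignments)
  rows <- vector("list", length(fold_sets))
  for (f in seq_along(fold_sets)) {
    val_ids <- fold_sets[[f]]
    masked <- mask_new_drugs(Y, val_ids)
    inner_seed <- (as.integer(seed) + 7919L * f) %% 2147483647L
    gs <- grid_search_cv(spec, masked$Y_known, features, grid,
                         n_folds = inner, seed = inner_seed)
    sc <- fit_predict(spec, masked$Y_known, features, val_ids, gs$best,
                      seed = seed)
    m <- pool_and_score(masked$Y_truth_new, sc)
    rows[[f]] <- data.frame(fold = f - 1L, n_val = length(val_ids),
                            aupr = m[["aupr"]], auroc = m[["auroc"]],
                            L = gs$best$L, lambda = gs$best$lambda,
                            sigma = gs$best$sigma, mix = gs$best$mix)
  }
  per_fold <- do.call(rbind, rows)
  structure(list(method = spec$method, per_fold = per_fold,
                 mean_aupr = mean(per_fold$aupr),
                 sd_aupr = stats::sd(per_fold$aupr),
                 mean_auroc = mean(per_fold$auroc),
                 sd_auroc = stats::sd(per_fold$auroc),
                 seed = as.integer(seed), fold_plan = fp),
            class = "eval_report")
}

#' Tune on known drugs, then score the hold-out set once
#'
#' Runs a `n_folds`-fold grid-search CV on the known drugs, refits the
#' model with the selected hyperparameters on all known drugs, and scores
#' the hold-out drugs (features only; their labels are used solely for
#' scoring).
#'
#' @inheritParams grid_search_cv
#' @param Y0 the full [interaction_matrix()] (known + hold-out drugs).
#' @param split a `split_plan` from [split_holdout()].
#' @return list with `aupr`, `auroc`, `chosen` hyperparameters, `n_known`,
#'   `n_new`, `seed`.
#' @export
holdout_evaluate <- function(spec, Y0, features, split, grid, n_folds = 5L,
                             seed) {
  stopifnot(inherits(split, "split_plan"))
  masked <- mask_new_drugs(Y0, split$new_drug_ids)
  chosen <- if (spec$method == "naive") {
    list(L = NA_real_, lambda = NA_real_, sigma = NA_real_, mix = NA_real_)
  } else {
    grid_search_cv(spec, masked$Y_known, features, grid,
                   n_folds = n_folds, seed = seed)$best
  }
  sc <- fit_predict(spec, masked$Y_known, features, split$new_drug_ids,
                    chosen, seed = seed)
  m <- pool_and_score(masked$Y_truth_new, sc)
  list(aupr = m[["aupr"]], auroc = m[["auroc"]], chosen = chosen,
       n_known = length(split$known_drug_ids),
       n_new = length(split$new_drug_ids), seed = as.integer(seed))
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report [%s], seed %d: AUPR %.4f +/- %.4f, AUROC %.4f +/- %.4f over %d folds\n",
              x$method, x$seed, x$mean_aupr, x$sd_aupr, x$mean_auroc,
              x$sd_auroc, nrow(x$per_fold)))
  invisible(x)
}
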