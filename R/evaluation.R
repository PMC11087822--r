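# Ranking metrics (micro-pooled AUPR / AUROC), fold plans, and paired
# t-tests. Cross-validation harnesses live in harness.R.

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: positives are visited in score-descending
#' order and each contributes the precision at its rank, weighted by its
#' recall increment (1 / number of positives). Tied scores are handled as a
#' block: every positive in a tied block receives the precision computed at
#' the end of the block, so constant scores yield the prevalence.
#'
#' @param labels binary 0/1 vector with at least one positive.
#' @param scores real score vector of the same length.
#' @return average precision in `[0, 1]`.
#' @export
aupr <- function(labels, scores) {
  check_metric_input(labels, scores)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  n_pos <- sum(lab)
  # block boundaries: last index of each run of tied scores
  ends <- c(which(diff(sc) != 0), length(sc))
  cum_tp <- cumsum(lab)[ends]
  cum_n <- ends
  tp_in_block <- diff(c(0, cum_tp))
  sum(tp_in_block / n_pos * (cum_tp / cum_n))
}

#' Area under the ROC curve (tie-corrected rank statistic)
#'
#' Equals the Mann-Whitney statistic
#' `P(score+ > score-) + 0.5 P(score+ = score-)` over all positive-negative
#' pairs, computed from midranks.
#'
#' @inheritParams aupr
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  check_metric_input(labels, scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)                     # midranks handle ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

check_metric_input <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have the same length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L) {
    stop("need at least one positive and one negative label", call. = FALSE)
  }
  invisible(TRUE)
}

#' Micro-pooled AUPR and AUROC over all (ADR, new drug) entries
#'
#' Flattens the truth and score matrices over every (ADR, drug) cell into a
#' single label/score vector and applies [aupr()] and [auroc()]. One value
#' per fold, not a per-ADR macro average.
#'
#' @param Y_truth [interaction_matrix()] of withheld true labels.
#' @param scores score matrix with identical ADR/drug ordering.
#' @return named vector `c(aupr = ..., auroc = ...)`.
#' @export
pool_and_score <- function(Y_truth, scores) {
  stopifnot(inherits(Y_truth, "interaction_matrix"))
  sm <- if (is.list(scores) && !is.null(scores$scores)) scores$scores else scores
  if (!all(dim(Y_truth$values) == dim(sm))) {
    stop("truth and score dimensions do not match", call. = FALSE)
  }
  if (!is.null(dimnames(sm)) &&
      (!identical(rownames(sm), Y_truth$adr_ids) ||
       !identical(colnames(sm), Y_truth$drug_ids))) {
    stop("truth and score id orderings do not match", call. = FALSE)
  }
  lab <- as.vector(Y_truth$values)
  sc <- as.vector(sm)
  c(aupr = aupr(lab, sc), auroc = auroc(lab, sc))
}

#' Random balanced fold assignment
#'
#' Uniform random partition of the drugs into `n_folds` folds whose sizes
#' differ by at most one, reproducible from `seed`.
#'
#' @param drug_ids drugs to partition.
#' @param n_folds number of folds, `2 <= n_folds <= length(drug_ids)`.
#' @param seed integer RNG seed.
#' @return A `fold_plan`: `assignments` (named integer vector, drug id to
#'   fold index in `0..n_folds-1`), `n_folds`, `seed`.
#' @export
make_folds <- function(drug_ids, n_folds, seed) {
  drug_ids <- as.character(drug_ids)
  if (n_folds < 2L) stop("need at least 2 folds", call. = FALSE)
  if (n_folds > length(drug_ids)) {
    stop("more folds than drugs", call. = FALSE)
  }
  shuffled <- with_seed(seed, sample(drug_ids))
  assignments <- (seq_along(shuffled) - 1L) %% as.integer(n_folds)
  names(assignments) <- shuffled
  assignments <- assignments[drug_ids]  # back to input order
  structure(list(assignments = assignments, n_folds = as.integer(n_folds),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

#' Paired t-test over cross-validation folds
#'
#' Classical paired t statistic on the fold-wise differences, two-sided
#' p-value from Student's t with n-1 degrees of freedom. If every
#' difference is exactly zero the methods are indistinguishable and p = 1
#' is returned; zero-variance nonzero differences give p = 0.
#'
#' @param metric_a,metric_b per-fold metric vectors (same folds, same
#'   order, length >= 2).
#' @return two-sided p-value.
#' @export
paired_t_test <- function(metric_a, metric_b) {
  if (length(metric_a) != length(metric_b) || length(metric_a) < 2L) {
    stop("need paired vectors of equal length >= 2", call. = FALSE)
  }
  d <- metric_a - metric_b
  if (all(d == 0)) return(1.0)
  s <- stats::sd(d)
  if (s == 0) return(0.0)
  n <- length(d)
  t_stat <- mean(d) / (s / sqrt(n))
  2 * stats::pt(-abs(t_stat), df = n - 1)
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %d drugs in %d folds (seed %d), sizes %s\n",
              length(x$assignments), x$n_folds, x$seed,
              paste(tabulate(x$assignments + 1L, x$n_folds), collapse = "/")))
  invisible(x)
}
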