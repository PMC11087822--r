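# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (enumeration / brute force / generic
# optimizers) and share no code with the implementation paths they check.

# exhaustive positive-negative pair counting (O(n^2)) for AUROC
pairwise_auroc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# explicit PR step-curve construction for AUPR (distinct scores assumed)
pr_curve_aupr_oracle <- function(labels, scores) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tp <- cumsum(lab)
  precision <- tp / seq_along(lab)
  recall <- tp / sum(lab)
  sum(diff(c(0, recall)) * precision)
}

# generic-optimizer minimizer of ||T - K W||^2 + lambda ||W||^2
kr_optim_oracle <- function(K, targets, lambda, maxit = 2000) {
  n <- nrow(K); t_ <- ncol(targets)
  objf <- function(w) {
    W <- matrix(w, n, t_)
    sum((targets - K %*% W)^2) + lambda * sum(W^2)
  }
  grf <- function(w) {
    W <- matrix(w, n, t_)
    as.vector(-2 * crossprod(K, targets - K %*% W) + 2 * lambda * W)
  }
  stats::optim(rep(0, n * t_), objf, grf, method = "L-BFGS-B",
               control = list(maxit = maxit, factr = 1e3))
}

# random binary feature table with unique drug ids
random_feature_table <- function(n, p, density = 0.4, seed = 1,
                                 name = "rand") {
  set.seed(seed)
  feature_table(matrix(rbinom(n * p, 1, density), n, p,
                       dimnames = list(sprintf("d%03d", seq_len(n)),
                                       sprintf("f%03d", seq_len(p)))),
                feature_name = name)
}

# random binary interaction matrix guaranteed to have both classes
random_interaction_matrix <- function(m, n, density = 0.2, seed = 1) {
  set.seed(seed)
  vals <- matrix(rbinom(m * n, 1, density), m, n)
  if (sum(vals) == 0) vals[1, 1] <- 1
  if (sum(vals) == m * n) vals[1, 1] <- 0
  interaction_matrix(vals, sprintf("a%03d", seq_len(m)),
                     sprintf("d%03d", seq_len(n)))
}

# deterministic tiny pair-list file
write_pair_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
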