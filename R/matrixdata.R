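# Containers and plumbing for the drug-ADR label matrix and binary drug
# feature tables. Orientation is fixed throughout the package:
#   Y (interaction_matrix): ADR rows x drug columns
#   X (feature_table):      drug rows x feature columns

#' Binary ADR-by-drug interaction matrix
#'
#' Constructs the label container `Y`: a binary matrix with one row per ADR
#' and one column per drug. Entry (i, j) is 1 iff drug j is known to cause
#' ADR i.
#'
#' @param values binary matrix, ADRs x drugs.
#' @param adr_ids character vector of row identifiers (no duplicates).
#' @param drug_ids character vector of column identifiers (no duplicates).
#' @return An `interaction_matrix` object.
#' @export
interaction_matrix <- function(values, adr_ids = rownames(values),
                               drug_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stop_if_not_binary(values, "interaction matrix")
  adr_ids <- as.character(adr_ids)
  drug_ids <- as.character(drug_ids)
  if (length(adr_ids) != nrow(values) || length(drug_ids) != ncol(values)) {
    stop("id lengths must match matrix dimensions", call. = FALSE)
  }
  stop_if_duplicated(adr_ids, "ADR ids")
  stop_if_duplicated(drug_ids, "drug ids")
  dimnames(values) <- list(adr_ids, drug_ids)
  structure(list(values = values, adr_ids = adr_ids, drug_ids = drug_ids),
            class = "interaction_matrix")
}

#' Binary drug feature table
#'
#' One row per drug, one column per binary feature (e.g. interacting genes
#' for DGI features, fingerprint bits for chemical-structure features).
#'
#' @param values binary matrix, drugs x features.
#' @param drug_ids character row identifiers (no duplicates).
#' @param feature_ids character column identifiers.
#' @param feature_name label for the feature source ("DGI", "Chem", ...).
#' @return A `feature_table` object.
#' @export
feature_table <- function(values, drug_ids = rownames(values),
                          feature_ids = colnames(values),
                          feature_name = "features") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  stop_if_not_binary(values, "feature table")
  drug_ids <- as.character(drug_ids)
  feature_ids <- as.character(feature_ids)
  if (length(drug_ids) != nrow(values) || length(feature_ids) != ncol(values)) {
    stop("id lengths must match matrix dimensions", call. = FALSE)
  }
  stop_if_duplicated(drug_ids, "drug ids")
  dimnames(values) <- list(drug_ids, feature_ids)
  structure(list(values = values, drug_ids = drug_ids,
                 feature_ids = feature_ids, feature_name = feature_name),
            class = "feature_table")
}

#' Subset a feature table to a set of drugs, in the given order
#'
#' @param x a `feature_table`.
#' @param drug_ids drugs to keep; must all be present.
#' @return A `feature_table` restricted to `drug_ids`.
#' @export
subset_drugs <- function(x, drug_ids) {
  stopifnot(inherits(x, "feature_table"))
  drug_ids <- as.character(drug_ids)
  missing <- setdiff(drug_ids, x$drug_ids)
  if (length(missing)) {
    stop("unknown drug ids: ", paste(utils::head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  feature_table(x$values[drug_ids, , drop = FALSE], drug_ids,
                x$feature_ids, x$feature_name)
}

#' Read a tab-separated pair list
#'
#' Reads SIDER/DGIdb-style flat files: one `(drug, item)` pair per line,
#' tab-separated, `#`-prefixed comment lines ignored, UTF-8. Only the first
#' two columns are used. Pairs are deduplicated keeping first-occurrence
#' order.
#'
#' @param path file path.
#' @param role `"adr"` for drug-ADR pairs or `"feature"` for drug-feature
#'   pairs; recorded, not interpreted.
#' @return A data.frame with columns `drug_id`, `item_id` and attribute
#'   `role`; zero rows for an empty file.
#' @export
read_pair_list <- function(path, role = c("adr", "feature")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    out <- data.frame(drug_id = character(), item_id = character(),
                      stringsAsFactors = FALSE)
    attr(out, "role") <- role
    return(out)
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad)) {
    stop(sprintf("malformed line %d in %s: expected >= 2 tab-separated fields",
                 idx[bad[1L]], path), call. = FALSE)
  }
  drug <- vapply(parts, `[[`, "", 1L)
  item <- vapply(parts, `[[`, "", 2L)
  dup <- duplicated(paste(drug, item, sep = "\r"))
  out <- data.frame(drug_id = drug[!dup], item_id = item[!dup],
                    stringsAsFactors = FALSE)
  attr(out, "role") <- role
  out
}

#' Assemble a binary matrix from a pair list
#'
#' Entry is 1 iff the `(drug, item)` pair is present. For `role = "adr"` the
#' result is an [interaction_matrix()] (items = ADRs as rows, drugs as
#' columns); for `role = "feature"` a [feature_table()] (drugs as rows,
#' items = features as columns).
#'
#' @param pairs data.frame with columns `drug_id`, `item_id` (as returned by
#'   [read_pair_list()]).
#' @param drug_order full ordered drug id vector.
#' @param item_order full ordered item id vector.
#' @param role `"adr"` or `"feature"`.
#' @param feature_name label used when `role = "feature"`.
#' @return An `interaction_matrix` or `feature_table`.
#' @export
build_matrix <- function(pairs, drug_order, item_order,
                         role = c("adr", "feature"),
                         feature_name = "features") {
  role <- match.arg(role)
  drug_order <- as.character(drug_order)
  item_order <- as.character(item_order)
  unknown_d <- setdiff(pairs$drug_id, drug_order)
  unknown_i <- setdiff(pairs$item_id, item_order)
  if (length(unknown_d) || length(unknown_i)) {
    stop("pairs reference unknown ids: ",
         paste(utils::head(c(unknown_d, unknown_i), 5L), collapse = ", "),
         call. = FALSE)
  }
  m <- matrix(0, length(item_order), length(drug_order),
              dimnames = list(item_order, drug_order))
  if (nrow(pairs)) {
    m[cbind(match(pairs$item_id, item_order),
            match(pairs$drug_id, drug_order))] <- 1
  }
  if (role == "adr") {
    interaction_matrix(m, item_order, drug_order)
  } else {
    feature_table(t(m), drug_order, item_order, feature_name)
  }
}

#' Drop drugs that carry no features
#'
#' A drug is kept iff it appears in at least one feature table with at least
#' one nonzero feature bit; an all-zero feature row counts as featureless
#' (it carries no similarity information under an RBF kernel). Column order
#' of `Y` is preserved.
#'
#' @param Y an [interaction_matrix()].
#' @param features list of [feature_table()] objects.
#' @return The filtered `interaction_matrix`.
#' @export
filter_featureless_drugs <- function(Y, features) {
  stopifnot(inherits(Y, "interaction_matrix"))
  if (inherits(features, "feature_table")) features <- list(features)
  has_feat <- rep(FALSE, length(Y$drug_ids))
  names(has_feat) <- Y$drug_ids
  for (ft in features) {
    stopifnot(inherits(ft, "feature_table"))
    nz <- ft$drug_ids[rowSums(ft$values) > 0]
    has_feat[names(has_feat) %in% nz] <- TRUE
  }
  keep <- Y$drug_ids[has_feat]
  if (!length(keep)) stop("no drugs with features remain", call. = FALSE)
  interaction_matrix(Y$values[, keep, drop = FALSE], Y$adr_ids, keep)
}

#' Reserve a random hold-out set of drugs
#'
#' Samples `round(fraction * N)` drugs (round half up) uniformly at random,
#' reproducibly from `seed`, as the hold-out ("new") set; the rest are the
#' known drugs.
#'
#' @param drug_ids full drug id vector.
#' @param fraction hold-out proportion in (0, 1); default 0.25.
#' @param seed integer RNG seed.
#' @return A `split_plan` with `known_drug_ids`, `new_drug_ids`, `seed`.
#' @export
split_holdout <- function(drug_ids, fraction = 0.25, seed) {
  drug_ids <- as.character(drug_ids)
  if (length(drug_ids) < 2L) stop("need at least 2 drugs", call. = FALSE)
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  n_new <- round_half_up(fraction * length(drug_ids))
  n_new <- max(1L, min(length(drug_ids) - 1L, as.integer(n_new)))
  new_ids <- with_seed(seed, sort(sample(drug_ids, n_new)))
  structure(list(known_drug_ids = setdiff(drug_ids, new_ids),
                 new_drug_ids = new_ids, seed = as.integer(seed)),
            class = "split_plan")
}

#' Mask drugs as new: withhold their columns from training
#'
#' Splits `Y0` into the known-drug training matrix and the withheld truth
#' matrix for the masked ("new") drugs. No new-drug label reaches any
#' training path: `Y_known` simply does not contain those columns.
#'
#' @param Y0 the full [interaction_matrix()] (known + new drugs).
#' @param new_drug_ids drugs to mask; must be a proper subset of
#'   `Y0$drug_ids`.
#' @return list with `Y_known` and `Y_truth_new`, both `interaction_matrix`.
#' @export
mask_new_drugs <- function(Y0, new_drug_ids) {
  stopifnot(inherits(Y0, "interaction_matrix"))
  new_drug_ids <- as.character(new_drug_ids)
  unknown <- setdiff(new_drug_ids, Y0$drug_ids)
  if (length(unknown)) {
    stop("unknown drug ids: ", paste(utils::head(unknown, 5L), collapse = ", "),
         call. = FALSE)
  }
  known <- setdiff(Y0$drug_ids, new_drug_ids)
  if (!length(known)) stop("cannot mask all drugs: no training data",
                           call. = FALSE)
  list(
    Y_known = interaction_matrix(Y0$values[, known, drop = FALSE],
                                 Y0$adr_ids, known),
    Y_truth_new = if (length(new_drug_ids)) {
      interaction_matrix(Y0$values[, new_drug_ids, drop = FALSE],
                         Y0$adr_ids, new_drug_ids)
    } else {
      interaction_matrix(Y0$values[, character(0), drop = FALSE],
                         Y0$adr_ids, character(0))
    }
  )
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction_matrix: %d ADRs x %d drugs, density %.4f\n",
              nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table '%s': %d drugs x %d features, density %.4f\n",
              x$feature_name, nrow(x$values), ncol(x$values), mean(x$values)))
  invisible(x)
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split_plan: %d known drugs, %d hold-out drugs (seed %d)\n",
              length(x$known_drug_ids), length(x$new_drug_ids), x$seed))
  invisible(x)
}
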