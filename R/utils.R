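#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All seeded operations in the package funnel through this helper so that a
# seed given to one function never perturbs randomness elsewhere.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Round half away from zero (base round() is round-half-even).
round_half_up <- function(x) floor(x + 0.5)

stop_if_not_binary <- function(m, what) {
  if (!all(m %in% c(0, 1))) {
    stop(sprintf("%s must contain only 0/1 entries", what), call. = FALSE)
  }
}

stop_if_duplicated <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicate %s: %s", what,
                 paste(utils::head(dup, 5L), collapse = ", ")), call. = FALSE)
  }
}

#' Write a matrix as TSV with row and column headers
#'
#' @param m numeric matrix with dimnames.
#' @param path output file path.
#' @export
write_matrix_tsv <- function(m, path) {
  stopifnot(is.matrix(m))
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path TSV file with an `id` column holding row names.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}
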