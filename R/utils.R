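#' @keywords internal
"_PACKAGE"

## Shared internal helpers.

#' Run code under a temporary RNG state
#'
#' Evaluates `expr` with the RNG seeded at `seed`, then restores the caller's
#' RNG state, so that simulation helpers do not perturb user scripts.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples.
#' Thin wrapper around [mclust::adjustedRandIndex()] that drops pairs where
#' either label is `NA` (e.g. unassigned samples).
#'
#' @param a,b label vectors of equal length; `NA` entries are dropped pairwise.
#' @return a single number in \[-1, 1\]; 1 means identical partitions,
#'   0 is the chance level. Returns `NA` if fewer than 2 complete pairs remain.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  keep <- !is.na(a) & !is.na(b)
  if (sum(keep) < 2) return(NA_real_)
  mclust::adjustedRandIndex(a[keep], b[keep])
}

#' Read and write tab-delimited numeric matrices
#'
#' Matrices are stored with row features (genes, epitopes, arms) and one
#' header line of sample identifiers; tab-delimited, UTF-8, '.' decimal.
#'
#' @param path file path.
#' @return `read_matrix_tsv`: a numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  as.matrix(df)
}

#' @rdname read_matrix_tsv
#' @param x numeric matrix with row and column names.
#' @param feature_col name used for the leading feature-identifier column.
#' @export
write_matrix_tsv <- function(x, path, feature_col = "feature") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- feature_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
write_df_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @noRd
stopifnot_prob <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("%s must lie in [0, 1]", what), call. = FALSE)
  }
  invisible(x)
}
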