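## Expression preprocessing: background/log transform, quantile
## normalization, probe-to-gene summarization, batch adjustment, MAD feature
## selection.

#' Background-subtract and log2-transform probe intensities
#'
#' Subtracts a fixed background offset from raw fluorescence intensities,
#' sets post-subtraction values below 1 to missing, and returns log2
#' intensities.
#'
#' @param intensities probe x sample matrix of raw intensities.
#' @param offset background offset to subtract (default 10).
#' @return matrix of log2 intensities with `NA` where the corrected
#'   intensity fell below 1.
#' @export
background_log <- function(intensities, offset = 10) {
  if (!is.numeric(offset) || length(offset) != 1 || offset <= 0) {
    stop("offset must be a positive number", call. = FALSE)
  }
  corrected <- intensities - offset
  corrected[corrected < 1] <- NA
  log2(corrected)
}

#' Quantile normalization
#'
#' Forces every sample (column) onto the same distribution: the across-sample
#' mean of order statistics. Missing values stay missing and are excluded
#' from the reference distribution. Delegates to
#' [limma::normalizeQuantiles()].
#'
#' @param x numeric matrix, features x samples, at least two columns.
#' @return matrix of the same shape with identical column distributions.
#' @export
quantile_normalize <- function(x) {
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples",
                        call. = FALSE)
  all_na <- colSums(!is.na(x)) == 0
  if (any(all_na)) {
    stop("column(s) entirely missing: ",
         paste(colnames(x)[all_na], collapse = ", "), call. = FALSE)
  }
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

## PC1 summary of a probe block (probes x samples), sign-fixed to correlate
## positively with the probe mean and rescaled to the mean probe variance.
probe_pc1 <- function(block) {
  imputed <- t(apply(block, 1, function(v) {
    v[is.na(v)] <- mean(v, na.rm = TRUE)
    v
  }))
  centred <- imputed - rowMeans(imputed)
  sv <- svd(centred, nu = 0, nv = 1)
  scores <- sv$v[, 1] * sv$d[1]
  probe_mean <- colMeans(imputed)
  if (stats::cor(scores, probe_mean) < 0) scores <- -scores
  target_sd <- sqrt(mean(apply(imputed, 1, stats::var)))
  if (stats::sd(scores) > 0) {
    scores <- scores / stats::sd(scores) * target_sd
  }
  mean(probe_mean) + scores - mean(scores)
}

## Largest subset of probes whose mean pairwise Pearson correlation reaches
## `min_cor`; enumerated exactly for small blocks, greedy otherwise; falls
## back to all probes when nothing qualifies.
correlating_subset <- function(block, min_cor = 0.3) {
  p <- nrow(block)
  if (p <= 2) return(seq_len(p))
  cm <- suppressWarnings(stats::cor(t(block), use = "pairwise.complete.obs"))
  cm[is.na(cm)] <- 0
  mean_pair <- function(idx) {
    sub <- cm[idx, idx]
    mean(sub[upper.tri(sub)])
  }
  if (p <= 12) {
    best <- NULL
    best_score <- -Inf
    for (size in p:2) {
      combs <- utils::combn(p, size)
      for (j in seq_len(ncol(combs))) {
        sc <- mean_pair(combs[, j])
        if (sc >= min_cor && sc > best_score) {
          best <- combs[, j]
          best_score <- sc
        }
      }
      if (!is.null(best)) break  # largest qualifying size found
    }
    if (!is.null(best)) return(best)
    return(seq_len(p))
  }
  ## Greedy: drop the probe with the lowest mean correlation to the rest.
  idx <- seq_len(p)
  while (length(idx) > 2 && mean_pair(idx) < min_cor) {
    contrib <- vapply(idx, function(i) {
      mean(cm[i, setdiff(idx, i)])
    }, numeric(1))
    idx <- idx[-which.min(contrib)]
  }
  if (mean_pair(idx) >= min_cor) idx else seq_len(p)
}

#' Summarize probe-level intensities to gene level
#'
#' Genes measured by a single probe pass through unchanged. Genes with
#' multiple probes are summarized by the first principal component of a
#' correlating probe subset (mean pairwise Pearson r >= `min_cor`; the
#' largest qualifying subset is kept, with fallback to all probes). The
#' component is sign-fixed to correlate positively with the mean of the
#' selected probes and rescaled to their mean variance.
#'
#' @param intensities probe x sample matrix.
#' @param probe_to_gene named character vector mapping probe id to gene
#'   symbol; must cover every probe row.
#' @param min_cor correlation threshold defining the probe subset.
#' @return gene x sample matrix with one row per mapped gene.
#' @export
summarize_probes <- function(intensities, probe_to_gene, min_cor = 0.3) {
  probes <- rownames(intensities)
  if (is.null(probes)) stop("intensities must have probe rownames")
  missing_map <- setdiff(probes, names(probe_to_gene))
  if (length(missing_map)) {
    stop("probes without gene mapping: ",
         paste(utils::head(missing_map, 5), collapse = ", "), call. = FALSE)
  }
  genes <- unique(unname(probe_to_gene[probes]))
  out <- matrix(NA_real_, length(genes), ncol(intensities),
                dimnames = list(genes, colnames(intensities)))
  for (g in genes) {
    rows <- probes[probe_to_gene[probes] == g]
    if (length(rows) == 0) stop("gene with zero probes: ", g)
    if (length(rows) == 1) {
      out[g, ] <- intensities[rows, ]
    } else {
      block <- intensities[rows, , drop = FALSE]
      keep <- correlating_subset(block, min_cor)
      out[g, ] <- probe_pc1(block[keep, , drop = FALSE])
    }
  }
  out
}

#' Location/scale batch adjustment
#'
#' Per gene, equalizes batch means to the overall gene mean and rescales each
#' batch to the pooled within-batch variance. This is the non-shrunk
#' location/scale limit of empirical-Bayes batch correction; with a single
#' batch the matrix is returned unchanged.
#'
#' @param x gene x sample matrix.
#' @param batch_labels per-sample batch identifiers.
#' @return adjusted matrix of the same shape.
#' @export
adjust_batch <- function(x, batch_labels) {
  batch <- as.character(rep_len(batch_labels, ncol(x)))
  tab <- table(batch)
  if (length(tab) < 2) return(x)
  if (any(tab < 2)) {
    stop("each batch needs >= 2 samples; singleton batch: ",
         paste(names(tab)[tab < 2], collapse = ", "), call. = FALSE)
  }
  out <- x
  grand_mean <- rowMeans(x)
  batch_idx <- split(seq_len(ncol(x)), batch)
  ## pooled within-batch variance per gene (weights n_b - 1)
  ss <- 0
  for (idx in batch_idx) {
    m <- rowMeans(x[, idx, drop = FALSE])
    ss <- ss + rowSums((x[, idx, drop = FALSE] - m)^2)
  }
  pooled_sd <- sqrt(ss / (ncol(x) - length(batch_idx)))
  for (idx in batch_idx) {
    m <- rowMeans(x[, idx, drop = FALSE])
    s <- apply(x[, idx, drop = FALSE], 1, stats::sd)
    s[s == 0] <- 1
    out[, idx] <- (x[, idx, drop = FALSE] - m) / s * pooled_sd + grand_mean
  }
  out
}

#' Select the most variable genes by median absolute deviation
#'
#' Ranks genes by the raw median absolute deviation from the gene median
#' (no consistency factor) and keeps the top `n`. Ties are broken
#' lexicographically by gene name.
#'
#' @param x gene x sample matrix.
#' @param n number of genes to keep (default 1000).
#' @return data frame of class `feature_selection` with columns `gene` and
#'   `mad`, ordered by decreasing MAD.
#' @export
select_top_mad <- function(x, n = 1000) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  mads <- apply(x, 1, function(v) stats::median(abs(v - stats::median(v,
                na.rm = TRUE)), na.rm = TRUE))
  if (n > length(mads)) {
    warning("requested ", n, " genes but only ", length(mads),
            " available; returning all")
    n <- length(mads)
  }
  ord <- order(-mads, rownames(x))
  sel <- data.frame(gene = rownames(x)[ord][seq_len(n)],
                    mad = unname(mads[ord][seq_len(n)]),
                    stringsAsFactors = FALSE)
  class(sel) <- c("feature_selection", class(sel))
  sel
}
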