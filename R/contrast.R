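## Subtype characterization: signal-to-noise differential expression
## ranking, gene set enrichment (weighted running-sum), marker association
## tests, signature-overlap test, EMT scoring, RPPA-correlated gene
## selection, and a block-scaled SVD joint factorization.

#' Signal-to-noise differential expression ranking
#'
#' Scores each gene as `(mean1 - mean2) / (sd1 + sd2)` between the two
#' classes, with each class standard deviation floored at 0.2 times the
#' absolute class mean (and at 0.2 when the mean is zero) to avoid division
#' blow-up on near-constant genes. Genes are returned in descending score
#' order.
#'
#' @param x gene x sample matrix.
#' @param labels per-sample class labels with exactly two levels; samples
#'   with `NA` labels are dropped.
#' @return data frame of class `ranked_list` with columns `gene` and
#'   `score`, ordered by decreasing score. The level treated as class 1 is
#'   stored in attribute `classes`.
#' @export
signal_to_noise <- function(x, labels) {
  labels <- as.character(labels)
  keep <- !is.na(labels)
  x <- x[, keep, drop = FALSE]
  labels <- labels[keep]
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must have exactly two classes",
                             call. = FALSE)
  if (any(table(labels) < 2)) {
    stop("both classes need >= 2 samples", call. = FALSE)
  }
  i1 <- labels == lev[1]
  m1 <- rowMeans(x[, i1, drop = FALSE])
  m2 <- rowMeans(x[, !i1, drop = FALSE])
  s1 <- apply(x[, i1, drop = FALSE], 1, stats::sd)
  s2 <- apply(x[, !i1, drop = FALSE], 1, stats::sd)
  floor_sd <- function(s, m) pmax(s, pmax(0.2 * abs(m), 0.2 * (m == 0)))
  score <- (m1 - m2) / (floor_sd(s1, m1) + floor_sd(s2, m2))
  ord <- order(-score)
  out <- data.frame(gene = rownames(x)[ord], score = unname(score[ord]),
                    stringsAsFactors = FALSE)
  attr(out, "classes") <- lev
  class(out) <- c("ranked_list", class(out))
  out
}

## Weighted Kolmogorov-Smirnov running-sum enrichment score.  Hit steps are
## proportional to |score|^p (normalized), miss steps are 1/(N - Nh); the ES
## is the running-sum value of largest magnitude.
running_sum_es <- function(scores, is_hit, p = 1) {
  n <- length(scores)
  nh <- sum(is_hit)
  w <- abs(scores)^p
  denom <- sum(w[is_hit])
  step <- ifelse(is_hit,
                 if (denom > 0) w / denom else 1 / nh,
                 -1 / (n - nh))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Gene set enrichment analysis on a ranked list
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment as in standard GSEA:
#' hit increments proportional to `|score|^p`, miss decrements `1/(N - Nh)`.
#' Significance is assessed by gene-set permutation: for each set, random
#' sets of equal size are drawn from the ranked universe. NES is the ES
#' divided by the mean magnitude of same-sign null scores; FDR is
#' Benjamini-Hochberg across sets.
#'
#' @param ranked a [signal_to_noise()] result (or data frame with `gene`
#'   and `score`).
#' @param gene_sets named list of gene identifier vectors (e.g. from
#'   [read_gmt()]).
#' @param n_perm number of gene-set permutations.
#' @param p weight exponent on the ranking scores (default 1).
#' @param seed integer seed for the permutations.
#' @return data frame of class `enrichment_result` with one row per gene
#'   set: `set`, `size`, `es`, `nes`, `p_value`, `fdr` and
#'   `leading_edge` (comma-separated genes up to the running-sum extremum).
#'   Sets with no gene in the ranked list are skipped with a warning.
#' @export
gsea <- function(ranked, gene_sets, n_perm = 1000, p = 1, seed = 1L) {
  genes <- ranked$gene
  scores <- ranked$score
  n <- length(genes)
  sizes <- vapply(gene_sets, function(gs) sum(genes %in% gs), integer(1))
  empty <- sizes == 0
  if (any(empty)) {
    warning("skipping gene set(s) with no gene in the ranked list: ",
            paste(names(gene_sets)[empty], collapse = ", "))
    gene_sets <- gene_sets[!empty]
    sizes <- sizes[!empty]
  }
  if (length(gene_sets) == 0) stop("no gene set overlaps the ranked list",
                                   call. = FALSE)
  es <- numeric(length(gene_sets))
  leading <- character(length(gene_sets))
  for (i in seq_along(gene_sets)) {
    is_hit <- genes %in% gene_sets[[i]]
    es[i] <- es_i <- running_sum_es(scores, is_hit, p)
    ## leading edge: hits at or before (after, for negative ES) the extremum
    w <- abs(scores)^p
    denom <- sum(w[is_hit])
    step <- ifelse(is_hit, if (denom > 0) w / denom else 1 / sum(is_hit),
                   -1 / (n - sum(is_hit)))
    run <- cumsum(step)
    pos <- which.max(abs(run))
    le <- if (es_i >= 0) genes[seq_len(pos)][is_hit[seq_len(pos)]]
          else genes[pos:n][is_hit[pos:n]]
    leading[i] <- paste(le, collapse = ",")
  }
  ## Null ES per distinct set size, by random gene sets.
  null_by_size <- list()
  with_seed(seed, {
    for (sz in unique(sizes)) {
      nulls <- vapply(seq_len(n_perm), function(b) {
        hit <- logical(n)
        hit[sample.int(n, sz)] <- TRUE
        running_sum_es(scores, hit, p)
      }, numeric(1))
      null_by_size[[as.character(sz)]] <- nulls
    }
  })
  pval <- numeric(length(es))
  nes <- numeric(length(es))
  for (i in seq_along(es)) {
    nulls <- null_by_size[[as.character(sizes[i])]]
    same <- nulls[sign(nulls) == sign(es[i]) | es[i] == 0]
    if (length(same) == 0) same <- abs(nulls)
    pval[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
    nes[i] <- es[i] / mean(abs(same))
  }
  out <- data.frame(set = names(gene_sets), size = as.integer(sizes),
                    es = es, nes = nes, p_value = pval,
                    fdr = stats::p.adjust(pval, "BH"),
                    leading_edge = leading,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Wilcoxon rank-sum marker test
#'
#' Two-sided rank-sum test of a continuous marker between two groups: exact
#' enumeration for small untied samples (total n <= 20), normal
#' approximation with tie correction otherwise. With all values tied the
#' p-value is 1.
#'
#' @param values numeric vector.
#' @param labels two-level grouping; `NA` labels dropped.
#' @return list with `statistic` (Mann-Whitney U for the first level) and
#'   `p_value`.
#' @export
wilcoxon_marker <- function(values, labels) {
  labels <- as.character(labels)
  keep <- !is.na(labels) & !is.na(values)
  values <- values[keep]
  labels <- labels[keep]
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("labels must have exactly two classes",
                             call. = FALSE)
  a <- values[labels == lev[1]]
  b <- values[labels == lev[2]]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  if (length(unique(values)) == 1) {
    return(list(statistic = length(a) * length(b) / 2, p_value = 1))
  }
  ties <- any(duplicated(values))
  exact <- (length(values) <= 20) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Fisher's exact enrichment test on a binary feature
#'
#' Conditional hypergeometric two-sided test (tables with probability at
#' most that of the observed table) on the 2x2 cross-tabulation of a binary
#' feature against two groups. The reported odds ratio is the sample odds
#' ratio, with a 0.5 continuity correction applied when any cell is zero.
#'
#' @param binary_feature logical/0-1 vector, or a pre-formed 2x2 table via
#'   `table2x2`.
#' @param labels two-level grouping aligned with `binary_feature`.
#' @param table2x2 optional 2x2 contingency matrix, overriding the vectors.
#' @return list with `odds_ratio`, `p_value`, `table` and `degenerate`
#'   (`TRUE` when a margin is empty, in which case `p_value = 1` and the
#'   odds ratio is `NA`).
#' @export
fisher_enrichment <- function(binary_feature = NULL, labels = NULL,
                              table2x2 = NULL) {
  tab <- if (!is.null(table2x2)) {
    as.matrix(table2x2)
  } else {
    keep <- !is.na(binary_feature) & !is.na(labels)
    t(table(factor(as.integer(binary_feature[keep]), levels = c(1, 0)),
            as.character(labels[keep])))
  }
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(odds_ratio = NA_real_, p_value = 1, table = tab,
                degenerate = TRUE))
  }
  p <- stats::fisher.test(tab)$p.value
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  if (any(tab == 0)) {
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  list(odds_ratio = (a * d) / (b * c), p_value = p, table = tab,
       degenerate = FALSE)
}

#' One-sided binomial test for signature overlap
#'
#' Probability of observing at least `n_de_in_sig` differentially expressed
#' genes among `sig_size` signature genes when each is differentially
#' expressed independently with probability `background_rate` (the
#' genome-wide differential expression fraction, supplied by the caller).
#'
#' @param n_de_in_sig observed differentially expressed signature genes.
#' @param sig_size signature size.
#' @param background_rate background probability in (0, 1).
#' @return one-sided p-value `P(X >= n_de_in_sig)`.
#' @export
signature_overlap_binomial <- function(n_de_in_sig, sig_size,
                                       background_rate) {
  if (n_de_in_sig < 0 || sig_size < 1 || n_de_in_sig > sig_size) {
    stop("need 0 <= n_de_in_sig <= sig_size", call. = FALSE)
  }
  if (background_rate <= 0 || background_rate >= 1) {
    stop("background_rate must be in (0, 1)", call. = FALSE)
  }
  stats::pbinom(n_de_in_sig - 1, sig_size, background_rate,
                lower.tail = FALSE)
}

#' Per-sample signature score (mean z-score)
#'
#' Scores each sample as the mean of gene-wise z-scored expression over the
#' signature genes present in the matrix; used for epithelial-mesenchymal
#' transition (EMT) scoring.
#'
#' @param x gene x sample matrix.
#' @param signature_genes character vector of gene identifiers.
#' @return named numeric vector of per-sample scores.
#' @export
emt_score <- function(x, signature_genes) {
  present <- intersect(signature_genes, rownames(x))
  if (length(present) == 0) stop("no signature gene present in the matrix",
                                 call. = FALSE)
  if (length(present) < length(signature_genes)) {
    warning(length(signature_genes) - length(present),
            " signature gene(s) absent from the matrix")
  }
  z <- t(scale(t(x[present, , drop = FALSE])))
  colMeans(z)
}

#' Select genes most correlated with protein epitopes
#'
#' For each RPPA epitope, ranks genes by absolute Pearson correlation with
#' the epitope over shared samples and keeps the top `top_n`; the union over
#' epitopes is returned. Constant epitopes are skipped with a warning.
#'
#' @param expr gene x sample matrix.
#' @param rppa epitope x sample matrix.
#' @param top_n genes kept per epitope (default 10).
#' @return character vector of selected genes (union, in first-seen order).
#' @export
select_rppa_correlated_genes <- function(expr, rppa, top_n = 10) {
  shared <- intersect(colnames(expr), colnames(rppa))
  if (length(shared) < 3) stop("need >= 3 shared samples", call. = FALSE)
  e <- expr[, shared, drop = FALSE]
  r <- rppa[, shared, drop = FALSE]
  selected <- character(0)
  for (i in seq_len(nrow(r))) {
    if (stats::sd(r[i, ], na.rm = TRUE) == 0 || all(is.na(r[i, ]))) {
      warning("skipping constant epitope: ", rownames(r)[i])
      next
    }
    cc <- suppressWarnings(
      stats::cor(t(e), r[i, ], use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    top <- rownames(e)[order(-abs(cc))][seq_len(min(top_n, nrow(e)))]
    selected <- union(selected, top)
  }
  if (length(selected) == 0) stop("all epitopes constant", call. = FALSE)
  selected
}

#' Joint factorization of expression and protein blocks
#'
#' Block-scaled singular value decomposition over two data blocks sharing
#' samples: features are z-scored within each block, blocks are weighted to
#' equal total variance, stacked, and decomposed. The top `k` factors are
#' returned, ordered by singular value, each sign-fixed to correlate
#' positively with its largest-weight feature. This is a light-weight
#' factorization used to recover latent sample axes (e.g. an EMT axis)
#' shared by transcripts and proteins.
#'
#' @param expr_subset gene x sample matrix (typically the RPPA-correlated
#'   gene subset).
#' @param rppa epitope x sample matrix.
#' @param k number of factors (default 5); must be below the number of
#'   shared samples.
#' @return list with `scores` (sample x k), `weights` (feature x k, rows
#'   named `expr:` / `rppa:`), `d` (singular values) and `block` (feature
#'   block membership).
#' @export
joint_factorization <- function(expr_subset, rppa, k = 5) {
  shared <- intersect(colnames(expr_subset), colnames(rppa))
  if (length(shared) < 3) stop("need >= 3 shared samples", call. = FALSE)
  if (k >= length(shared)) stop("k must be below the sample count",
                                call. = FALSE)
  zblock <- function(m, tag) {
    z <- t(scale(t(m[, shared, drop = FALSE])))
    z[is.na(z)] <- 0
    keep <- apply(z, 1, function(v) any(v != 0))
    z <- z[keep, , drop = FALSE]
    z <- z / sqrt(nrow(z))  # equal total variance per block
    rownames(z) <- paste0(tag, ":", rownames(z))
    z
  }
  stacked <- rbind(zblock(expr_subset, "expr"), zblock(rppa, "rppa"))
  sv <- svd(stacked, nu = k, nv = k)
  scores <- sv$v %*% diag(sv$d[seq_len(k)], k)
  weights <- sv$u
  for (j in seq_len(k)) {
    imax <- which.max(abs(weights[, j]))
    if (stats::cor(scores[, j], stacked[imax, ]) < 0) {
      scores[, j] <- -scores[, j]
      weights[, j] <- -weights[, j]
    }
  }
  dimnames(scores) <- list(shared, paste0("factor", seq_len(k)))
  dimnames(weights) <- list(rownames(stacked), paste0("factor", seq_len(k)))
  list(scores = scores, weights = weights, d = sv$d[seq_len(k)],
       block = sub(":.*", "", rownames(stacked)))
}
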