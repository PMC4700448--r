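## Subtype discovery: hierarchical base clustering, feature-resampled
## consensus matrix, consensus-matrix reclustering, and stability-based
## assignment with an explicit unassigned class.

#' Pearson distance between samples
#'
#' `1 - Pearson correlation` between sample columns. Errors on constant
#' sample vectors, for which the correlation is undefined.
#' @param x feature x sample matrix.
#' @return `dist` object over samples.
#' @export
pearson_dist <- function(x) {
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant sample vector(s) under Pearson distance: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  stats::as.dist(1 - stats::cor(x))
}

#' Hierarchical base clustering of samples
#'
#' Agglomerative clustering of sample columns with the requested linkage and
#' distance, cut at `k` clusters. `linkage = "ward"` is Ward's D1 criterion
#' (`hclust` method `"ward.D"`). Deterministic given the input column order.
#'
#' @param x feature x sample matrix.
#' @param k number of clusters (>= 2).
#' @param linkage one of `"average"`, `"ward"`, `"complete"`, `"single"`.
#' @param distance `"pearson"` (1 - correlation) or `"euclidean"`.
#' @return integer cluster labels named by sample.
#' @export
base_cluster <- function(x, k = 2,
                         linkage = c("average", "ward", "complete", "single"),
                         distance = c("pearson", "euclidean")) {
  linkage <- match.arg(linkage)
  distance <- match.arg(distance)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (ncol(x) < k) stop("need at least k samples", call. = FALSE)
  d <- switch(distance,
              pearson = pearson_dist(x),
              euclidean = stats::dist(t(x)))
  method <- switch(linkage, ward = "ward.D", linkage)
  stats::cutree(stats::hclust(d, method = method), k = k)
}

#' Consensus matrix from feature-resampled clustering
#'
#' Repeatedly subsamples a fraction of the features without replacement,
#' reclusters the samples, and records how often each sample pair lands in
#' the same cluster. Entry (i, j) is the co-clustering frequency over all
#' iterations (the pairwise concordance).
#'
#' @inheritParams base_cluster
#' @param n_iterations number of resampling iterations (>= 2 unless
#'   `feature_fraction = 1`).
#' @param feature_fraction fraction of features drawn per iteration, in
#'   (0, 1].
#' @param seed integer seed making the resampling reproducible.
#' @return object of class `consensus_matrix`: list with the sample x sample
#'   `matrix` plus the run descriptors.
#' @export
consensus_matrix <- function(x, k = 2, n_iterations = 1000,
                             feature_fraction = 0.9,
                             linkage = "average", distance = "pearson",
                             seed = 1L) {
  if (feature_fraction <= 0 || feature_fraction > 1) {
    stop("feature_fraction must be in (0, 1]", call. = FALSE)
  }
  if (n_iterations < 2 && feature_fraction < 1) {
    stop("n_iterations must be >= 2", call. = FALSE)
  }
  n <- ncol(x)
  g <- nrow(x)
  n_feat <- max(2L, floor(feature_fraction * g))
  co <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  with_seed(seed, {
    for (it in seq_len(n_iterations)) {
      idx <- if (n_feat < g) sample.int(g, n_feat) else seq_len(g)
      labels <- base_cluster(x[idx, , drop = FALSE], k = k,
                             linkage = linkage, distance = distance)
      co <- co + outer(labels, labels, "==")
    }
  })
  cm <- co / n_iterations
  diag(cm) <- 1
  structure(list(matrix = cm, n_iterations = n_iterations,
                 feature_fraction = feature_fraction,
                 k = k, linkage = linkage, distance = distance),
            class = "consensus_matrix")
}

#' Stability-based subtype assignment from a consensus matrix
#'
#' Reclusters the consensus matrix (complete linkage, Euclidean distance)
#' into two clusters, then greedily removes the sample with the lowest mean
#' within-cluster concordance from any cluster in which some pair falls
#' below the concordance threshold, until all within-cluster pairs reach the
#' threshold. Removed samples are labelled `"unassigned"`.
#'
#' @param cm a [consensus_matrix()] object (or a plain symmetric matrix).
#' @param threshold minimum pairwise within-cluster concordance (default
#'   0.8).
#' @return object of class `subtype_assignment`: data frame with columns
#'   `sample`, `label` (`"1"`, `"2"`, `"unassigned"`) and `min_concordance`
#'   (minimum concordance with the assigned cluster's members), with the
#'   cluster sizes as attribute `sizes`.
#' @export
assign_stable <- function(cm, threshold = 0.8) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  m <- if (inherits(cm, "consensus_matrix")) cm$matrix else cm
  n <- nrow(m)
  samples <- rownames(m)
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  hc <- stats::hclust(stats::dist(m), method = "complete")
  cl <- stats::cutree(hc, k = min(2, n))
  ## Larger cluster first so label "1" is the bigger subtype.
  sizes <- table(cl)
  relabel <- order(-sizes)
  cl <- match(cl, relabel)

  members <- list(which(cl == 1), which(cl == 2))
  unassigned <- integer(0)
  repeat {
    viol <- vapply(members, function(idx) {
      if (length(idx) < 2) return(FALSE)
      sub <- m[idx, idx]
      min(sub[upper.tri(sub)]) < threshold
    }, logical(1))
    if (!any(viol)) break
    ## candidate removals: samples in violating clusters, ranked by mean
    ## within-cluster concordance
    worst <- NULL
    worst_val <- Inf
    for (ci in which(viol)) {
      idx <- members[[ci]]
      mean_conc <- vapply(idx, function(i) {
        mean(m[i, setdiff(idx, i)])
      }, numeric(1))
      j <- which.min(mean_conc)
      if (mean_conc[j] < worst_val) {
        worst_val <- mean_conc[j]
        worst <- c(ci, idx[j])
      }
    }
    members[[worst[1]]] <- setdiff(members[[worst[1]]], worst[2])
    unassigned <- c(unassigned, worst[2])
  }

  label <- rep("unassigned", n)
  label[members[[1]]] <- "1"
  label[members[[2]]] <- "2"
  min_conc <- rep(NA_real_, n)
  for (ci in 1:2) {
    idx <- members[[ci]]
    for (i in idx) {
      others <- setdiff(idx, i)
      min_conc[i] <- if (length(others)) min(m[i, others]) else 1
    }
  }
  out <- data.frame(sample = samples, label = label,
                    min_concordance = min_conc, stringsAsFactors = FALSE)
  attr(out, "sizes") <- c(`1` = length(members[[1]]),
                          `2` = length(members[[2]]),
                          unassigned = length(unassigned))
  class(out) <- c("subtype_assignment", class(out))
  out
}

#' Consensus subtype discovery from an expression matrix
#'
#' The full discovery pipeline: select the `n_features` genes with highest
#' median absolute deviation, median-centre each gene (standard practice
#' before correlation-based clustering), build the feature-resampled
#' consensus matrix, and derive stable subtype assignments.
#'
#' @inheritParams consensus_matrix
#' @param expr gene x sample expression matrix (normalized log scale).
#' @param n_features number of top-MAD genes to cluster on.
#' @param concordance minimum pairwise within-cluster concordance for
#'   assignment.
#' @return list with elements `assignment` ([assign_stable()] output),
#'   `consensus` ([consensus_matrix()] output) and `features` (the selected
#'   gene list).
#' @export
discover_subtypes <- function(expr, n_features = 1000, k = 2,
                              n_iterations = 1000, feature_fraction = 0.9,
                              linkage = "average", distance = "pearson",
                              concordance = 0.8, seed = 1L) {
  sel <- select_top_mad(expr, n_features)
  x <- expr[sel$gene, , drop = FALSE]
  x <- x - apply(x, 1, stats::median)
  cm <- consensus_matrix(x, k = k, n_iterations = n_iterations,
                         feature_fraction = feature_fraction,
                         linkage = linkage, distance = distance, seed = seed)
  list(assignment = assign_stable(cm, threshold = concordance),
       consensus = cm, features = sel)
}

#' Cross-method clustering stability report
#'
#' Runs the consensus pipeline under several base clustering methods and
#' reports the pairwise adjusted Rand index between the resulting
#' assignments (computed over samples assigned by both methods).
#'
#' @param x feature x sample matrix (already feature-selected and centred).
#' @param methods list of method descriptors, each a list with elements
#'   `linkage` and `distance` (e.g. `list(linkage = "ward",
#'   distance = "pearson")`).
#' @param agreement_threshold pairwise ARI below which the report flags
#'   instability.
#' @inheritParams consensus_matrix
#' @param concordance assignment concordance threshold.
#' @return list with `assignments` (one [assign_stable()] result per
#'   method), `ari` (method x method matrix) and `stable` (logical; `FALSE`
#'   when any pairwise ARI falls below `agreement_threshold`).
#' @export
stability_report <- function(x, methods, k = 2, n_iterations = 250,
                             feature_fraction = 0.9, concordance = 0.8,
                             agreement_threshold = 0.8, seed = 1L) {
  if (length(methods) < 2) stop("need >= 2 methods", call. = FALSE)
  names(methods) <- vapply(methods, function(m) {
    paste(m$linkage, m$distance, sep = "/")
  }, character(1))
  assignments <- lapply(methods, function(m) {
    cm <- consensus_matrix(x, k = k, n_iterations = n_iterations,
                           feature_fraction = feature_fraction,
                           linkage = m$linkage, distance = m$distance,
                           seed = seed)
    assign_stable(cm, threshold = concordance)
  })
  nm <- length(methods)
  ari <- matrix(NA_real_, nm, nm,
                dimnames = list(names(methods), names(methods)))
  for (i in seq_len(nm)) {
    for (j in seq_len(nm)) {
      la <- assignments[[i]]$label
      lb <- assignments[[j]]$label
      la[la == "unassigned"] <- NA
      lb[lb == "unassigned"] <- NA
      ari[i, j] <- adjusted_rand(la, lb)
    }
  }
  off <- ari[upper.tri(ari)]
  list(assignments = assignments, ari = ari,
       stable = all(!is.na(off)) && all(off >= agreement_threshold))
}
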