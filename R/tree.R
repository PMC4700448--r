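## Conditional-inference survival tree: per-node association tests of
## features against log-rank scores with Bonferroni stopping, log-rank
## maximizing split points, and minsplit/minbucket constraints.

#' Survival tree parameters
#'
#' @param alpha threshold on the Bonferroni-corrected per-node p-value
#'   (default 0.25).
#' @param minsplit minimum node size to attempt a split (default 20).
#' @param minbucket minimum leaf size (default 10).
#' @param correction multiplicity correction across features per node; only
#'   `"bonferroni"` is implemented.
#' @return list of class `tree_params`.
#' @export
tree_params <- function(alpha = 0.25, minsplit = 20, minbucket = 10,
                        correction = "bonferroni") {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]", call. = FALSE)
  correction <- match.arg(correction, "bonferroni")
  if (minbucket > minsplit / 2) {
    warning("minbucket > minsplit/2: some nodes above minsplit cannot split")
  }
  structure(list(alpha = alpha, minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket), correction = correction),
            class = "tree_params")
}

#' Log-rank scores for censored survival responses
#'
#' The censored-response transformation used by conditional-inference
#' survival trees: `score_i = event_i - H(t_i)` where `H` is the
#' Nelson-Aalen cumulative hazard estimate. Scores sum to zero.
#'
#' @param time,event survival outcome.
#' @return numeric score vector; if there are no events the scores are all
#'   zero and carry attribute `no_events = TRUE`.
#' @export
logrank_scores <- function(time, event) {
  n <- length(time)
  if (sum(event) == 0) {
    return(structure(rep(0, n), no_events = TRUE))
  }
  ut <- sort(unique(time[event == 1]))
  d <- vapply(ut, function(u) sum(time == u & event == 1), numeric(1))
  at_risk <- vapply(ut, function(u) sum(time >= u), numeric(1))
  cumhaz_step <- cumsum(d / at_risk)
  ## H(t_i): cumulative hazard at each subject's own time
  idx <- findInterval(time, ut)
  H <- ifelse(idx == 0, 0, cumhaz_step[pmax(idx, 1)])
  event - H
}

#' Per-node association test between a feature and log-rank scores
#'
#' Linear statistic `T = sum(feature * score)` standardized by its exact
#' permutation mean and variance (closed form), with a two-sided normal
#' approximation for the p-value. A constant feature carries no information
#' and returns p = 1.
#'
#' @param feature numeric feature values.
#' @param scores log-rank scores from [logrank_scores()].
#' @return list with `statistic` (standardized, signed) and `p_value`.
#' @export
node_test <- function(feature, scores) {
  n <- length(feature)
  if (n != length(scores)) stop("lengths differ", call. = FALSE)
  if (stats::sd(feature) == 0 || stats::sd(scores) == 0) {
    return(list(statistic = 0, p_value = 1))
  }
  tstat <- sum(feature * scores)
  mu <- sum(feature) * sum(scores) / n
  vr <- sum((feature - mean(feature))^2) *
    sum((scores - mean(scores))^2) / (n - 1)
  z <- (tstat - mu) / sqrt(vr)
  list(statistic = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Best binary split of a feature by the log-rank criterion
#'
#' Scans all thresholds at midpoints between consecutive distinct observed
#' feature values with both sides at least `minbucket` samples, and returns
#' the threshold maximizing the two-sample log-rank statistic (computed as
#' the standardized sum of log-rank scores on the left side; ties go to the
#' lower threshold). Samples equal to the threshold go left.
#'
#' @param feature numeric feature.
#' @param time,event survival outcome.
#' @param minbucket minimum group size on each side.
#' @return list with `threshold`, `statistic` (chi-square form, the squared
#'   standardized statistic) and `feasible`; `feasible = FALSE` when no
#'   threshold satisfies the size constraint.
#' @export
find_split <- function(feature, time, event, minbucket = 10) {
  n <- length(feature)
  scores <- logrank_scores(time, event)
  ord <- order(feature)
  f_sorted <- feature[ord]
  s_sorted <- scores[ord]
  cum <- cumsum(s_sorted)
  tot <- sum(scores)
  ssq <- sum((scores - mean(scores))^2)
  cuts <- which(diff(f_sorted) > 0)  # split after position c
  cuts <- cuts[cuts >= minbucket & (n - cuts) >= minbucket]
  if (length(cuts) == 0 || ssq == 0) {
    return(list(threshold = NA_real_, statistic = NA_real_,
                feasible = FALSE))
  }
  mu <- cuts * tot / n
  vr <- ssq * cuts * (n - cuts) / (n * (n - 1))
  stat <- (cum[cuts] - mu)^2 / vr
  best <- cuts[which.max(stat)]  # which.max takes the first = lower threshold
  list(threshold = (f_sorted[best] + f_sorted[best + 1]) / 2,
       statistic = max(stat), feasible = TRUE)
}

#' Fit a conditional-inference survival tree
#'
#' Recursive partitioning of censored survival data: at each node every
#' feature is tested against the node's log-rank scores ([node_test()]),
#' p-values are Bonferroni-corrected across features, and the node becomes a
#' leaf when the smallest corrected p-value exceeds `alpha` or the node is
#' smaller than `minsplit`. Otherwise the winning feature is split at the
#' log-rank-maximizing threshold ([find_split()]) and the children are
#' fitted recursively. Leaves are numbered in depth-first order (left
#' first).
#'
#' @param features data frame or matrix of candidate features
#'   (samples x features).
#' @param time,event survival outcome.
#' @param params a [tree_params()] object.
#' @return object of class `survival_tree`: list with `root` (nested node
#'   list), `groups` (per-sample leaf id), `features_used`, `n_leaves` and
#'   `params`. Internal nodes carry `feature`, `threshold` and `p_adj`.
#' @export
fit_tree <- function(features, time, event, params = tree_params()) {
  features <- as.data.frame(features)
  n <- nrow(features)
  if (n != length(time)) stop("features and outcome differ in length")
  if (n < params$minsplit) {
    warning("fewer samples than minsplit: returning a root-only tree")
  }
  m <- ncol(features)

  build <- function(idx) {
    node <- list(n = length(idx), samples = idx)
    if (length(idx) < params$minsplit) {
      node$type <- "leaf"
      return(node)
    }
    sc <- logrank_scores(time[idx], event[idx])
    tests <- lapply(features, function(f) node_test(f[idx], sc))
    praw <- vapply(tests, `[[`, numeric(1), "p_value")
    padj <- pmin(1, praw * m)
    if (min(padj) > params$alpha) {
      node$type <- "leaf"
      return(node)
    }
    winner <- names(features)[which.min(praw)]
    sp <- find_split(features[[winner]][idx], time[idx], event[idx],
                     params$minbucket)
    if (!sp$feasible) {
      node$type <- "leaf"
      node$no_feasible_split <- TRUE
      return(node)
    }
    left <- idx[features[[winner]][idx] <= sp$threshold]
    right <- setdiff(idx, left)
    node$type <- "internal"
    node$feature <- winner
    node$threshold <- sp$threshold
    node$p_adj <- min(padj)
    node$left <- build(left)
    node$right <- build(right)
    node
  }

  root <- build(seq_len(n))
  ## depth-first leaf numbering
  leaf_counter <- 0L
  number <- function(node) {
    if (node$type == "leaf") {
      leaf_counter <<- leaf_counter + 1L
      node$leaf_id <- leaf_counter
    } else {
      node$left <- number(node$left)
      node$right <- number(node$right)
    }
    node
  }
  root <- number(root)
  groups <- integer(n)
  assign_groups <- function(node) {
    if (node$type == "leaf") {
      groups[node$samples] <<- node$leaf_id
    } else {
      assign_groups(node$left)
      assign_groups(node$right)
    }
  }
  assign_groups(root)
  used <- character(0)
  collect <- function(node) {
    if (node$type == "internal") {
      used <<- union(used, node$feature)
      collect(node$left)
      collect(node$right)
    }
  }
  collect(root)
  structure(list(root = root, groups = groups, features_used = used,
                 n_leaves = leaf_counter, params = params),
            class = "survival_tree")
}

#' Route samples through a fitted survival tree
#'
#' Samples at or below a node's threshold go left (the same convention used
#' at fit time).
#'
#' @param tree a [fit_tree()] result.
#' @param features data frame containing every feature named in the tree's
#'   internal nodes.
#' @return integer leaf group id per sample.
#' @export
predict_groups <- function(tree, features) {
  features <- as.data.frame(features)
  missing <- setdiff(tree$features_used, colnames(features))
  if (length(missing)) {
    stop("missing node feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  route <- function(node, i) {
    if (node$type == "leaf") return(node$leaf_id)
    if (features[[node$feature]][i] <= node$threshold) {
      route(node$left, i)
    } else {
      route(node$right, i)
    }
  }
  vapply(seq_len(nrow(features)), function(i) route(tree$root, i),
         integer(1))
}

#' @export
print.survival_tree <- function(x, ...) {
  cat("survival_tree:", x$n_leaves, "leaves")
  if (length(x$features_used)) {
    cat("; splits on", paste(x$features_used, collapse = ", "))
  }
  cat("\n")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf("%s[leaf %d] n=%d\n", pad, node$leaf_id, node$n))
    } else {
      cat(sprintf("%s%s <= %.4g (adj p=%.3g, n=%d)\n", pad, node$feature,
                  node$threshold, node$p_adj, node$n))
      show(node$left, indent + 1)
      show(node$right, indent + 1)
    }
  }
  show(x$root, 1)
  invisible(x)
}

#' Serialize a survival tree to JSON
#'
#' @param tree a [fit_tree()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  strip <- function(node) {
    if (node$type == "leaf") {
      list(type = "leaf", leaf_id = node$leaf_id, n = node$n)
    } else {
      list(type = "internal", feature = node$feature,
           threshold = node$threshold, adj_p = node$p_adj, n = node$n,
           left = strip(node$left), right = strip(node$right))
    }
  }
  jsonlite::write_json(strip(tree$root), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Leave-one-out partial likelihood deviance of tree groups
#'
#' Reporting utility: refits the tree without each sample, routes the held
#' out sample to a leaf, and evaluates the Cox partial likelihood deviance
#' of the resulting group factor. Intended for model reporting, not for
#' model selection.
#'
#' @inheritParams fit_tree
#' @param max_n cap on the number of leave-one-out refits (first `max_n`
#'   samples), keeping the utility affordable on large cohorts.
#' @return mean per-sample contribution to minus twice the partial
#'   log-likelihood of the held-out groupings.
#' @export
loo_tree_deviance <- function(features, time, event, params = tree_params(),
                              max_n = 50) {
  features <- as.data.frame(features)
  n <- nrow(features)
  take <- seq_len(min(n, max_n))
  dev <- vapply(take, function(i) {
    fit <- fit_tree(features[-i, , drop = FALSE], time[-i], event[-i],
                    params)
    grp <- predict_groups(fit, features)
    if (length(unique(grp)) < 2) return(0)
    cf <- survival::coxph(survival::Surv(time, event) ~ factor(grp),
                          ties = "breslow")
    -2 * cf$loglik[2] / n
  }, numeric(1))
  mean(dev)
}
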