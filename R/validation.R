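## Cross-cohort subtype validation: de novo reclustering of the validation
## cohort, correlation of differential-expression vectors, and
## label-association testing.

#' Validate expression subtypes in an independent cohort
#'
#' Runs the full consensus discovery pipeline de novo on the validation
#' expression matrix, computes signal-to-noise differential-expression
#' vectors between the two subtypes in each cohort over the shared genes,
#' orients the validation labels so the correlation is positive, and
#' reports Pearson and Spearman correlations.
#'
#' @param discovery_expr gene x sample matrix of the discovery cohort.
#' @param discovery_assignment a [assign_stable()] result for the discovery
#'   samples.
#' @param validation_expr gene x sample matrix of the validation cohort.
#' @param ... passed to [discover_subtypes()] for the validation cohort
#'   (e.g. `n_features`, `n_iterations`, `seed`).
#' @return object of class `validation_report`: list with
#'   `pearson`, `spearman` (SNR-vector correlations), `snr_discovery`,
#'   `snr_validation` (named vectors on shared genes),
#'   `validation_assignment`, `oriented` (whether validation labels were
#'   flipped) and `unstable` (`TRUE` when the validation clustering did not
#'   yield two stable clusters).
#' @export
validate_subtypes <- function(discovery_expr, discovery_assignment,
                              validation_expr, ...) {
  shared <- intersect(rownames(discovery_expr), rownames(validation_expr))
  if (length(shared) < 50) stop("need >= 50 shared genes", call. = FALSE)
  val <- discover_subtypes(validation_expr, ...)
  va <- val$assignment
  sizes <- attr(va, "sizes")
  unstable <- any(sizes[c("1", "2")] < 2)
  lab_d <- discovery_assignment$label
  lab_d[lab_d == "unassigned"] <- NA
  lab_v <- va$label
  lab_v[lab_v == "unassigned"] <- NA
  if (unstable) {
    return(structure(list(pearson = NA_real_, spearman = NA_real_,
                          snr_discovery = NULL, snr_validation = NULL,
                          validation_assignment = va, oriented = FALSE,
                          unstable = TRUE),
                     class = "validation_report"))
  }
  snr_d <- signal_to_noise(discovery_expr[shared, , drop = FALSE], lab_d)
  snr_v <- signal_to_noise(validation_expr[shared, , drop = FALSE], lab_v)
  vd <- stats::setNames(snr_d$score, snr_d$gene)[shared]
  vv <- stats::setNames(snr_v$score, snr_v$gene)[shared]
  pe <- stats::cor(vd, vv)
  oriented <- FALSE
  if (!is.na(pe) && pe < 0) {
    ## flip validation labels so subtype 1 matches across cohorts
    va$label <- c(`1` = "2", `2` = "1",
                  unassigned = "unassigned")[va$label]
    vv <- -vv
    pe <- -pe
    oriented <- TRUE
  }
  structure(list(pearson = pe,
                 spearman = stats::cor(vd, vv, method = "spearman"),
                 snr_discovery = vd, snr_validation = vv,
                 validation_assignment = va, oriented = oriented,
                 unstable = FALSE),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$unstable) {
    cat("validation_report: validation clustering unstable (<2 clusters)\n")
  } else {
    cat(sprintf(
      "validation_report: SNR-vector correlation r=%.3f (Pearson), %.3f (Spearman) over %d shared genes\n",
      x$pearson, x$spearman, length(x$snr_discovery)))
  }
  invisible(x)
}

#' Association between two sample labelings
#'
#' Cross-tabulates two labelings of the same samples (unassigned/`NA`
#' entries excluded) and tests association: Fisher's exact test for 2x2
#' tables, otherwise a chi-square test with a seeded Monte-Carlo p-value.
#'
#' @param labels_a,labels_b label vectors of equal length; `"unassigned"`
#'   and `NA` entries are dropped.
#' @param n_mc Monte-Carlo replicates for tables larger than 2x2.
#' @param seed integer seed for the Monte-Carlo p-value.
#' @return list with `table`, `statistic`, `p_value` and `method`.
#' @export
label_association <- function(labels_a, labels_b, n_mc = 10000, seed = 1L) {
  if (length(labels_a) != length(labels_b)) {
    stop("labelings must cover the same samples", call. = FALSE)
  }
  a <- as.character(labels_a)
  b <- as.character(labels_b)
  keep <- !is.na(a) & !is.na(b) & a != "unassigned" & b != "unassigned"
  a <- a[keep]
  b <- b[keep]
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stop("need >= 2 categories on each side after exclusions", call. = FALSE)
  }
  tab <- table(a, b)
  if (all(dim(tab) == c(2, 2))) {
    ft <- stats::fisher.test(tab)
    return(list(table = tab, statistic = unname(ft$estimate),
                p_value = ft$p.value, method = "fisher"))
  }
  ct <- with_seed(seed,
    suppressWarnings(stats::chisq.test(tab, simulate.p.value = TRUE,
                                       B = n_mc)))
  list(table = tab, statistic = unname(ct$statistic), p_value = ct$p.value,
       method = "chisq_mc")
}
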