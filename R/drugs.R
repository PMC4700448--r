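## Differential drug-sensitivity testing between subtype-mapped cell lines.

#' Differential drug response between subtypes
#'
#' For each drug with at least `min_per_group` measured cell lines in both
#' subtypes, performs a two-sided Welch t-test on the dose-response AUC
#' between the two subtype groups and controls the FDR across retained
#' drugs by Benjamini-Hochberg. Lower AUC means more sensitive, so the
#' reported sensitive subtype is the group with the lower mean AUC.
#'
#' @param auc drug x cell-line AUC matrix (values in \[0, 1\]; `NA` for
#'   unmeasured pairs).
#' @param subtype_map named vector mapping cell-line id to subtype label
#'   (two levels).
#' @param min_per_group minimum measured lines per subtype for a drug to be
#'   tested (default 3).
#' @param fdr FDR threshold used for the `significant` flag (default 0.25).
#' @return data frame with one row per retained drug: `drug`, `n1`, `n2`,
#'   `mean1`, `mean2`, `t`, `p_value`, `q_value`, `sensitive_subtype`,
#'   `significant`, ordered by p-value. Attribute `n_tested` records the BH
#'   denominator.
#' @export
differential_drugs <- function(auc, subtype_map, min_per_group = 3,
                               fdr = 0.25) {
  lines <- intersect(colnames(auc), names(subtype_map))
  map <- subtype_map[lines]
  lev <- sort(unique(as.character(map)))
  if (length(lev) != 2) stop("subtype_map must have exactly two levels",
                             call. = FALSE)
  auc <- auc[, lines, drop = FALSE]
  rows <- lapply(rownames(auc), function(drug) {
    v <- auc[drug, ]
    a <- v[map == lev[1] & !is.na(v)]
    b <- v[map == lev[2] & !is.na(v)]
    if (length(a) < min_per_group || length(b) < min_per_group) return(NULL)
    tt <- stats::t.test(a, b)  # Welch
    data.frame(drug = drug, n1 = length(a), n2 = length(b),
               mean1 = mean(a), mean2 = mean(b),
               t = unname(tt$statistic), p_value = tt$p.value,
               sensitive_subtype = if (mean(a) <= mean(b)) lev[1] else lev[2],
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    stop("no drug has >= ", min_per_group, " measured lines per subtype",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out$significant <- out$q_value < fdr
  out <- out[order(out$p_value),
             c("drug", "n1", "n2", "mean1", "mean2", "t", "p_value",
               "q_value", "sensitive_subtype", "significant")]
  rownames(out) <- NULL
  attr(out, "n_tested") <- nrow(out)
  out
}
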