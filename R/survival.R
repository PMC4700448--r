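## Survival analysis: Kaplan-Meier estimation, log-rank testing, and a
## stratified Cox likelihood-ratio screen of molecular features with FDR
## control.

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates via [survival::survfit()].
#'
#' @param time positive follow-up times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param groups optional grouping; a single curve when omitted.
#' @return a `survfit` object.
#' @export
kaplan_meier <- function(time, event, groups = NULL) {
  if (any(time <= 0)) stop("times must be strictly positive", call. = FALSE)
  if (is.null(groups)) groups <- rep(1L, length(time))
  if (any(table(groups) < 1)) stop("empty group", call. = FALSE)
  df <- data.frame(time = time, event = event, g = factor(groups))
  survival::survfit(survival::Surv(time, event) ~ g, data = df)
}

#' Log-rank test between survival groups
#'
#' Observed-versus-expected statistic over the pooled event times via
#' [survival::survdiff()]; ties are handled by the simultaneous risk-set
#' convention. With no events the statistic is 0 and p = 1.
#'
#' @inheritParams kaplan_meier
#' @param groups group labels (>= 2 groups).
#' @return list with `statistic` (chi-square), `df` and `p_value`.
#' @export
logrank <- function(time, event, groups) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (sum(event) == 0) {
    return(list(statistic = 0, df = nlevels(g) - 1L, p_value = 1))
  }
  df <- data.frame(time = time, event = event, g = g)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = df)
  dfree <- length(sd_$n) - 1L
  list(statistic = unname(sd_$chisq), df = dfree,
       p_value = stats::pchisq(sd_$chisq, dfree, lower.tail = FALSE))
}

#' Stratified Cox likelihood-ratio test for one feature
#'
#' Fits a stratified Cox proportional hazards model (Breslow ties) with the
#' base clinical covariates, and again with the tested feature added; the
#' likelihood-ratio test on one degree of freedom compares the two. The
#' hazard ratio is per unit of the feature, with a Wald 95% confidence
#' interval.
#'
#' @param time,event survival outcome.
#' @param feature numeric feature tested for association with survival.
#' @param base_covariates optional data frame of clinical covariates
#'   included in both models.
#' @param strata optional stratum ids (e.g. biobank) for the baseline
#'   hazard.
#' @return list with `hr`, `ci_low`, `ci_high`, `p_value` (LRT), `coef` and
#'   `flag` (`"ok"`, `"nonconvergence"` or `"separation"`).
#' @export
cox_lrt <- function(time, event, feature, base_covariates = NULL,
                    strata = NULL) {
  df <- data.frame(.time = time, .event = event, .feature = feature)
  rhs0 <- "1"
  if (!is.null(base_covariates)) {
    base_covariates <- as.data.frame(base_covariates)
    df <- cbind(df, base_covariates)
    rhs0 <- paste(colnames(base_covariates), collapse = " + ")
  }
  if (!is.null(strata)) {
    df$.stratum <- strata
    rhs0 <- paste(rhs0, "+ strata(.stratum)")
  }
  n_cov <- if (is.null(base_covariates)) 0 else ncol(base_covariates)
  if (sum(event) < n_cov + 2) {
    stop("too few events for the model size", call. = FALSE)
  }
  f0 <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs0))
  f1 <- stats::as.formula(paste("survival::Surv(.time, .event) ~", rhs0,
                                "+ .feature"))
  flag <- "ok"
  fit1 <- withCallingHandlers(
    survival::coxph(f1, data = df, ties = "breslow"),
    warning = function(w) {
      flag <<- if (grepl("infinite|converge", conditionMessage(w)))
        "separation" else "nonconvergence"
      invokeRestart("muffleWarning")
    })
  fit0 <- suppressWarnings(survival::coxph(f0, data = df, ties = "breslow"))
  ll0 <- if (length(fit0$loglik) == 2) fit0$loglik[2] else fit0$loglik[1]
  ll1 <- fit1$loglik[2]
  lrt <- max(0, 2 * (ll1 - ll0))
  co <- fit1$coefficients[".feature"]
  se <- sqrt(diag(fit1$var))[length(fit1$coefficients)]
  list(hr = exp(unname(co)),
       ci_low = exp(unname(co) - 1.96 * se),
       ci_high = exp(unname(co) + 1.96 * se),
       p_value = stats::pchisq(lrt, 1, lower.tail = FALSE),
       coef = unname(co), flag = flag)
}

#' Likelihood-ratio survival screen over molecular features
#'
#' Applies [cox_lrt()] to every row of a feature matrix (e.g. RPPA
#' epitopes) against survival, adjusting for base clinical covariates and
#' strata, and controls the false discovery rate across features by
#' Benjamini-Hochberg. Per-feature failures are flagged, not fatal.
#'
#' @param features feature x sample numeric matrix.
#' @inheritParams cox_lrt
#' @return data frame of class `screen_result` with columns `feature`,
#'   `hr`, `ci_low`, `ci_high`, `p_value`, `q_value`, `flag`, ordered by
#'   p-value.
#' @export
survival_screen <- function(features, time, event, base_covariates = NULL,
                            strata = NULL) {
  if (nrow(features) < 1) stop("need >= 1 feature", call. = FALSE)
  rows <- lapply(rownames(features), function(f) {
    res <- tryCatch(
      cox_lrt(time, event, features[f, ], base_covariates, strata),
      error = function(e) list(hr = NA_real_, ci_low = NA_real_,
                               ci_high = NA_real_, p_value = NA_real_,
                               coef = NA_real_, flag = "error"))
    data.frame(feature = f, hr = res$hr, ci_low = res$ci_low,
               ci_high = res$ci_high, p_value = res$p_value,
               flag = res$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value),
             c("feature", "hr", "ci_low", "ci_high", "p_value", "q_value",
               "flag")]
  rownames(out) <- NULL
  class(out) <- c("screen_result", class(out))
  out
}
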