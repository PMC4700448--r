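## Synthetic multi-omic cohort generator.
##
## Emulates the statistical structure the downstream analysis assumes: two
## latent expression subtypes plus a set of unassignable ("mixed") samples,
## gene-level mutation probabilities, subtype-skewed arm-level copy number,
## protein epitopes correlated with their cognate transcripts, and survival
## driven by hypermutation status and one prognostic epitope.

#' Configuration for the synthetic cohort generator
#'
#' Collects every generative parameter with defaults matching a lobular
#' breast cancer cohort: 144 samples, two expression subtypes plus ~29%
#' unassignable samples, the published gene-level mutation frequencies
#' (CDH1 42.8%, PIK3CA 34.8%, ...), arm-level gains of 1q and 8q and loss of
#' 11q skewed towards the hormone-related subtype, a 3.2 Mb sequencing
#' capture, and survival driven by hypermutation and the eIF4B epitope.
#'
#' @param n_samples number of samples.
#' @param n_genes number of genes in the expression matrix.
#' @param n_signature_genes number of genes separating the two subtypes.
#' @param effect_size standardized between-subtype mean shift per signature
#'   gene (units of the residual SD); half the signature genes are up in each
#'   subtype.
#' @param frac_subtype1 proportion of samples in subtype 1 (immune-related).
#' @param frac_mixed proportion of unassignable samples carrying no subtype
#'   signal; subtype 2 receives the remainder.
#' @param mutation_freqs named vector of per-gene mutation probabilities.
#' @param capture_mb sequenced target size in megabases.
#' @param high_rate_frac proportion of hypermutated samples (forced to at
#'   least `rate_threshold` non-silent variants).
#' @param rate_threshold variant count at or above which a sample counts as
#'   hypermutated.
#' @param bg_mu,bg_size negative binomial mean and dispersion of the
#'   background (non-listed-gene) non-silent variant count; defaults
#'   calibrated so the median non-silent total is ~6 per sample.
#' @param cna_arm_probs data frame with columns `arm`, `direction` (+1 gain,
#'   -1 loss), `prob_subtype1`, `prob_subtype2`.
#' @param n_epitopes number of protein epitopes correlated with cognate
#'   transcripts (an independent eIF4B epitope is always appended).
#' @param epitope_gene_corr target Pearson correlation between an epitope and
#'   its cognate transcript.
#' @param beta_mutrate log-hazard coefficient of the hypermutation indicator.
#' @param beta_eif4b log-hazard coefficient per unit of the eIF4B epitope.
#' @param baseline_hazard baseline event rate (events per year).
#' @param censor_frac target proportion of administratively censored samples.
#' @param batch_labels optional per-sample batch identifiers (recycled to
#'   `n_samples`); when given, per-batch gene-wise offsets are added.
#' @param seed integer seed; identical seed and configuration reproduce the
#'   cohort exactly.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 144,
                       n_genes = 2000,
                       n_signature_genes = 200,
                       effect_size = 1.0,
                       frac_subtype1 = 0.44,
                       frac_mixed = 0.29,
                       mutation_freqs = default_mutation_freqs(),
                       capture_mb = 3.2,
                       high_rate_frac = 0.06,
                       rate_threshold = 10,
                       bg_mu = 4.8,
                       bg_size = 6,
                       cna_arm_probs = default_cna_arm_probs(),
                       n_epitopes = 20,
                       epitope_gene_corr = 0.7,
                       beta_mutrate = 1.3,
                       beta_eif4b = 0.7,
                       baseline_hazard = 0.04,
                       censor_frac = 0.35,
                       batch_labels = NULL,
                       seed = 1L) {
  stopifnot_prob(c(frac_subtype1, frac_mixed, high_rate_frac, censor_frac),
                 "proportions")
  stopifnot_prob(epitope_gene_corr, "epitope_gene_corr")
  if (frac_subtype1 + frac_mixed > 1) {
    stop("frac_subtype1 + frac_mixed must not exceed 1", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (n_signature_genes > n_genes) {
    stop("n_signature_genes must not exceed n_genes", call. = FALSE)
  }
  if (length(mutation_freqs) == 0) {
    stop("mutation_freqs must list at least one gene", call. = FALSE)
  }
  if (is.null(names(mutation_freqs)) || any(!nzchar(names(mutation_freqs)))) {
    stop("mutation_freqs must be a named vector", call. = FALSE)
  }
  stopifnot_prob(mutation_freqs, "mutation_freqs")
  if (capture_mb <= 0) stop("capture_mb must be positive", call. = FALSE)
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    effect_size = effect_size, frac_subtype1 = frac_subtype1,
    frac_mixed = frac_mixed, mutation_freqs = mutation_freqs,
    capture_mb = capture_mb, high_rate_frac = high_rate_frac,
    rate_threshold = as.integer(rate_threshold),
    bg_mu = bg_mu, bg_size = bg_size,
    cna_arm_probs = cna_arm_probs, n_epitopes = as.integer(n_epitopes),
    epitope_gene_corr = epitope_gene_corr,
    beta_mutrate = beta_mutrate, beta_eif4b = beta_eif4b,
    baseline_hazard = baseline_hazard, censor_frac = censor_frac,
    batch_labels = batch_labels, seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Published gene-level mutation frequencies used as generator defaults
#'
#' Frequently mutated genes in invasive lobular carcinoma with their reported
#' frequencies: CDH1 (42.8%), PIK3CA (34.8%), GATA3/MAP3K1/AKT1 (5.1% each),
#' MAP2K4/NF1/ERBB2 (4.3%), TP53 (3.6%), plus the remaining PI3K pathway
#' members PIK3R3 (2.9%) and PTEN/PIK3CB/PIK3CG/PIK3CD (1.4%).
#' @return named numeric vector of per-gene mutation probabilities.
#' @export
default_mutation_freqs <- function() {
  c(CDH1 = 0.428, PIK3CA = 0.348, GATA3 = 0.051, MAP3K1 = 0.051,
    AKT1 = 0.051, MAP2K4 = 0.043, NF1 = 0.043, ERBB2 = 0.043, TP53 = 0.036,
    PIK3R3 = 0.029, PTEN = 0.014, PIK3CB = 0.014, PIK3CG = 0.014,
    PIK3CD = 0.014)
}

#' Default arm-level copy-number alteration probabilities
#'
#' Gain of 1q and 8q and loss of 11q are more frequent in subtype 2 (the
#' hormone-related subtype); 16q loss is frequent in both subtypes, as is
#' typical for lobular/luminal tumours; remaining arms carry low background
#' alteration rates.
#' @return data frame with columns `arm`, `direction`, `prob_subtype1`,
#'   `prob_subtype2`.
#' @export
default_cna_arm_probs <- function() {
  data.frame(
    arm = c("1q", "8q", "11q", "16q", "16p", "1p", "8p", "11p", "6q", "17q"),
    direction = c(1, 1, -1, -1, 1, -1, -1, -1, -1, 1),
    prob_subtype1 = c(0.25, 0.20, 0.25, 0.60, 0.20, 0.10, 0.15, 0.10, 0.15, 0.10),
    prob_subtype2 = c(0.60, 0.50, 0.65, 0.60, 0.20, 0.10, 0.15, 0.10, 0.15, 0.10),
    stringsAsFactors = FALSE
  )
}

## Gene-level parameters shared by paired cohorts: baseline means, signature
## gene identities and effect directions, epitope cognates.
gene_params <- function(config, gene_seed) {
  with_seed(gene_seed, {
    ng <- config$n_genes
    genes <- sprintf("G%04d", seq_len(ng))
    sig_idx <- sort(sample.int(ng, config$n_signature_genes))
    ## Named marker genes carried by the signature for realism: immune
    ## markers up in subtype 1, hormone/EMT markers up in subtype 2.
    s1_markers <- c("CD4", "CD8A", "PDCD1", "CD274", "CTLA4", "CCL5",
                    "CXCL9", "IL7R")
    s2_markers <- c("ESR1", "PGR", "GATA3", "FN1", "COL11A1", "THBS2",
                    "COL1A1", "COL5A2")
    markers <- c(s1_markers, s2_markers)
    n_named <- min(length(markers), length(sig_idx))
    genes[sig_idx[seq_len(n_named)]] <- markers[seq_len(n_named)]
    ## Half of the signature up in each subtype; named markers keep their
    ## biological direction.
    dir <- rep_len(c(1, -1), length(sig_idx))
    dir[seq_len(n_named)] <- ifelse(markers[seq_len(n_named)] %in% s1_markers,
                                    1, -1)
    delta <- numeric(ng)
    delta[sig_idx] <- dir * config$effect_size
    mu <- stats::rnorm(ng, mean = 7, sd = 1.5)
    ## Epitope cognates: half signature genes, half background genes.
    n_ep <- config$n_epitopes
    from_sig <- sig_idx[seq_len(min(ceiling(n_ep / 2), length(sig_idx)))]
    pool <- setdiff(seq_len(ng), sig_idx)
    from_bg <- sample(pool, n_ep - length(from_sig))
    cognates <- c(from_sig, from_bg)[seq_len(n_ep)]
    list(genes = genes, sig_idx = sig_idx, delta = delta, mu = mu,
         cognates = cognates,
         emt_genes = intersect(genes, c("FN1", "COL11A1", "THBS2", "COL1A1",
                                        "COL5A2")),
         s1_markers = intersect(genes, s1_markers),
         s2_markers = intersect(genes, s2_markers))
  })
}

draw_cohort <- function(config, gp, seed, sample_prefix = "S",
                        cohort_shift = FALSE) {
  with_seed(seed, {
    n <- config$n_samples
    samples <- sprintf("%s%03d", sample_prefix, seq_len(n))

    ## --- latent subtypes (deterministic sizes, random placement) ---
    n1 <- round(n * config$frac_subtype1)
    nmix <- round(n * config$frac_mixed)
    n2 <- n - n1 - nmix
    if (n2 < 0) stop("frac_subtype1 + frac_mixed too large for n_samples")
    subtype <- sample(c(rep("1", n1), rep("2", n2), rep("mixed", nmix)))
    s <- ifelse(subtype == "1", 0.5, ifelse(subtype == "2", -0.5, 0))

    ## --- expression ---
    expr <- matrix(stats::rnorm(config$n_genes * n), config$n_genes, n,
                   dimnames = list(gp$genes, samples))
    expr <- expr + gp$mu + outer(gp$delta, s)
    if (cohort_shift) {
      expr <- expr + stats::rnorm(config$n_genes, sd = 0.3)
    }
    batch <- config$batch_labels
    if (!is.null(batch)) {
      batch <- rep_len(as.character(batch), n)
      for (b in unique(batch)) {
        expr[, batch == b] <- expr[, batch == b] +
          stats::rnorm(config$n_genes, sd = 0.5)
      }
    }

    ## --- mutations ---
    thr <- config$rate_threshold
    n_high <- round(n * config$high_rate_frac)
    high_rate <- seq_len(n) %in% sample.int(n, n_high)
    freqs <- config$mutation_freqs
    listed_hit <- matrix(stats::rbinom(length(freqs) * n, 1, rep(freqs, n)),
                         nrow = length(freqs),
                         dimnames = list(names(freqs), samples))
    listed_count <- colSums(listed_hit)
    bg_count <- stats::rnbinom(n, size = config$bg_size, mu = config$bg_mu)
    ## Non-hypermutated samples stay strictly below the rate threshold so the
    ## latent flag and the count criterion coincide; hypermutated samples are
    ## pushed to the threshold and beyond.
    total_lo <- pmin(listed_count + bg_count, thr - 1L)
    bg_lo <- total_lo - pmin(listed_count, thr - 1L)
    extra_hi <- thr + stats::rnbinom(n, size = 2, mu = 4) - listed_count
    bg_count <- ifelse(high_rate, pmax(extra_hi, 0), pmax(bg_lo, 0))
    rows <- list()
    for (j in seq_len(n)) {
      g_listed <- rownames(listed_hit)[listed_hit[, j] == 1]
      g_bg <- if (bg_count[j] > 0) {
        sprintf("BG%03d", sample.int(400, bg_count[j], replace = FALSE))
      } else character(0)
      g_all <- c(g_listed, g_bg)
      if (length(g_all)) {
        cls <- sample(c("missense", "truncating"), length(g_all),
                      replace = TRUE, prob = c(0.7, 0.3))
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[j], gene = g_all, class = cls,
          stringsAsFactors = FALSE)
      }
      n_sil <- stats::rpois(1, 0.8)
      if (n_sil > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[j],
          gene = sprintf("BG%03d", sample.int(400, n_sil, replace = FALSE)),
          class = "silent", stringsAsFactors = FALSE)
      }
    }
    mutations <- do.call(rbind, rows)
    rownames(mutations) <- NULL

    ## --- arm-level copy number ---
    ap <- config$cna_arm_probs
    cna <- matrix(0L, nrow(ap), n, dimnames = list(ap$arm, samples))
    for (i in seq_len(nrow(ap))) {
      p <- ifelse(subtype == "1", ap$prob_subtype1[i],
                  ifelse(subtype == "2", ap$prob_subtype2[i],
                         (ap$prob_subtype1[i] + ap$prob_subtype2[i]) / 2))
      hit <- stats::rbinom(n, 1, p)
      cna[i, ] <- as.integer(hit * ap$direction[i])
    }

    ## --- RPPA: epitopes tracking cognate transcripts, plus eIF4B ---
    r <- config$epitope_gene_corr
    ep_names <- paste0("ep.", gp$genes[gp$cognates])
    rppa <- matrix(NA_real_, length(gp$cognates) + 1L, n,
                   dimnames = list(c(ep_names, "eIF4B"), samples))
    for (i in seq_along(gp$cognates)) {
      z <- as.numeric(scale(expr[gp$cognates[i], ]))
      rppa[i, ] <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    }
    ## eIF4B: bimodal protein abundance (a low- and a high-expressing class),
    ## independent of the expression subtypes.
    lo <- stats::runif(n) < 0.45
    rppa["eIF4B", ] <- stats::rnorm(n, mean = ifelse(lo, -1, 0.8), sd = 0.35)

    ## --- survival and clinical covariates ---
    lp <- config$beta_mutrate * high_rate +
      config$beta_eif4b * rppa["eIF4B", ]
    tte <- stats::rexp(n, rate = config$baseline_hazard * exp(lp))
    if (config$censor_frac > 0) {
      cmax <- tryCatch(
        stats::uniroot(function(m) mean(pmin(tte / m, 1)) - config$censor_frac,
                       interval = c(1e-6, max(tte) * 100))$root,
        error = function(e) max(tte))
      ctime <- stats::runif(n, 0, cmax)
    } else {
      ctime <- rep(Inf, n)
    }
    time <- pmin(tte, ctime)
    event <- as.integer(tte <= ctime)
    time <- pmax(time, 1e-4)
    er <- rep("pos", n)
    er[sample.int(n, 1)] <- "neg"  # a single hormone-receptor-negative sample
    clinical <- data.frame(
      sample = samples,
      time = round(time, 4),
      event = event,
      size_mm = round(exp(stats::rnorm(n, log(20), 0.4)), 1),
      grade = sample(1:3, n, replace = TRUE, prob = c(0.2, 0.6, 0.2)),
      positive_nodes = stats::rnbinom(n, size = 1, mu = 1.5),
      hormonal_therapy = stats::rbinom(n, 1, 0.6),
      chemo = stats::rbinom(n, 1, 0.3),
      age = round(stats::rnorm(n, 60, 10), 1),
      biobank = sample(paste0("BB", 1:4), n, replace = TRUE),
      er = er,
      pr = ifelse(er == "neg", "neg", "pos"),
      her2 = sample(c("neg", "pos"), n, replace = TRUE, prob = c(0.95, 0.05)),
      stringsAsFactors = FALSE
    )

    truth <- data.frame(sample = samples, subtype = subtype,
                        high_rate = high_rate, stringsAsFactors = FALSE)

    cohort <- list(expression = expr, mutations = mutations, cna = cna,
                   rppa = rppa, clinical = clinical, truth = truth,
                   markers = list(subtype1_up = gp$s1_markers,
                                  subtype2_up = gp$s2_markers,
                                  emt = gp$emt_genes),
                   config = config)
    class(cohort) <- "omic_cohort"
    cohort
  })
}

#' Simulate a multi-omic cohort
#'
#' Draws a cohort with two latent expression subtypes plus unassignable
#' samples, per-gene mutations, subtype-skewed arm-level copy number,
#' transcript-correlated protein epitopes, and exponential survival whose
#' log hazard is `beta_mutrate * 1[hypermutated] + beta_eif4b * eIF4B`.
#' The same configuration and seed always reproduce the identical cohort.
#'
#' @param config a [sim_config()] object.
#' @return an `omic_cohort`: a list with elements `expression`
#'   (gene x sample), `mutations` (long table: sample, gene, class),
#'   `cna` (arm x sample in -1/0/+1), `rppa` (epitope x sample), `clinical`
#'   (per-sample data frame), `truth` (latent subtype and hypermutation
#'   flag) and `markers` (named marker gene lists).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gp <- gene_params(config, config$seed)
  draw_cohort(config, gp, seed = config$seed + 1L)
}

#' Simulate a discovery/validation cohort pair
#'
#' Two independent cohorts drawn from the same latent subtype model: gene
#' baselines, signature gene identities and effect directions are shared,
#' while samples, noise and a per-cohort global expression offset differ.
#'
#' @inheritParams simulate_cohort
#' @return list with elements `discovery` and `validation`, both
#'   `omic_cohort` objects.
#' @export
simulate_validation_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gp <- gene_params(config, config$seed)
  list(
    discovery = draw_cohort(config, gp, seed = config$seed + 1L,
                            sample_prefix = "D"),
    validation = draw_cohort(config, gp, seed = config$seed + 2L,
                             sample_prefix = "V", cohort_shift = TRUE)
  )
}

#' @export
print.omic_cohort <- function(x, ...) {
  cat("omic_cohort:", ncol(x$expression), "samples\n")
  cat("  expression:", nrow(x$expression), "genes\n")
  cat("  mutations :", nrow(x$mutations), "variants\n")
  cat("  cna       :", nrow(x$cna), "arms\n")
  cat("  rppa      :", nrow(x$rppa), "epitopes\n")
  cat("  subtypes  :", paste(sprintf("%s=%d", names(table(x$truth$subtype)),
                                     table(x$truth$subtype)), collapse = " "),
      "\n")
  invisible(x)
}

#' Write a cohort to tab-delimited files
#'
#' Writes `expression.tsv`, `rppa.tsv` and `cna_arms.tsv` (features as rows,
#' header of sample ids), `mutations.tsv` (MAF-like columns
#' `Tumor_Sample_Barcode`, `Hugo_Symbol`, `Variant_Classification`),
#' `clinical.tsv`, `truth.tsv`, and the configuration as `config.yaml`.
#'
#' @param cohort an `omic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "omic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"), "gene")
  write_matrix_tsv(cohort$rppa, file.path(dir, "rppa.tsv"), "epitope")
  write_matrix_tsv(cohort$cna, file.path(dir, "cna_arms.tsv"), "arm")
  maf_class <- c(missense = "Missense_Mutation",
                 truncating = "Nonsense_Mutation", silent = "Silent")
  maf <- data.frame(Tumor_Sample_Barcode = cohort$mutations$sample,
                    Hugo_Symbol = cohort$mutations$gene,
                    Variant_Classification =
                      unname(maf_class[cohort$mutations$class]),
                    stringsAsFactors = FALSE)
  write_df_tsv(maf, file.path(dir, "mutations.tsv"))
  write_df_tsv(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_df_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  cfg <- cohort$config
  cfg$cna_arm_probs <- as.list(cfg$cna_arm_probs)
  cfg$mutation_freqs <- as.list(cfg$mutation_freqs)
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}
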