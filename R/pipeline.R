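## End-to-end orchestration: simulate (optional) -> cluster -> characterize
## -> validate (optional) -> survival screen -> survival tree -> drug screen
## (optional), with a manifest recording every parameter and seed actually
## used.

PI3K_GENES <- c("PIK3CA", "PIK3R3", "PTEN", "PIK3CB", "PIK3CG", "PIK3CD",
                "AKT1")

## Per-stage seed fan-out: stage_seed = global seed + fixed stage offset, so
## toggling stages never changes the seeds of the stages that run.
STAGE_SEED_OFFSET <- c(simulate = 1L, cluster = 2L, characterize = 3L,
                       validate = 4L, survival = 5L, tree = 6L, drugs = 7L)

#' Pipeline configuration
#'
#' Assembles all stage parameters with their standard defaults (top-1000
#' MAD genes, k = 2, 90% feature resampling, 0.8 concordance, 3.2 Mb
#' capture, hypermutation at 10 variants, tree alpha 0.25 with minsplit 20
#' and minbucket 10, drug filter of 3 lines per group at FDR 0.25).
#'
#' @param out_dir output directory for all stage results.
#' @param seed global integer seed; per-stage seeds are derived by adding a
#'   fixed per-stage offset.
#' @param simulate if `TRUE` (default) a synthetic cohort is generated;
#'   otherwise `input_dir` must point to cohort TSV files as written by
#'   [write_cohort()].
#' @param sim list of [sim_config()] overrides for the simulated cohort.
#' @param input_dir directory with cohort files when `simulate = FALSE`.
#' @param validate run the cross-cohort validation stage (simulated pair).
#' @param drugs optional list with `auc` (path to drug x line TSV) and
#'   `subtype_map` (path to two-column TSV: line, subtype); `NULL` skips
#'   the stage.
#' @param gmt optional GMT file path for the enrichment stage.
#' @param n_features,k,feature_fraction,n_iterations,concordance consensus
#'   clustering parameters (see [discover_subtypes()]).
#' @param capture_mb,rate_threshold mutation burden parameters.
#' @param alpha,minsplit,minbucket survival tree parameters.
#' @param drug_min_per_group,drug_fdr drug screen parameters.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            sim = list(), input_dir = NULL,
                            validate = FALSE, drugs = NULL, gmt = NULL,
                            n_features = 1000, k = 2,
                            feature_fraction = 0.9, n_iterations = 1000,
                            concordance = 0.8, capture_mb = 3.2,
                            rate_threshold = 10, alpha = 0.25,
                            minsplit = 20, minbucket = 10,
                            drug_min_per_group = 3, drug_fdr = 0.25) {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed),
              simulate = isTRUE(simulate), sim = sim,
              input_dir = input_dir, validate = isTRUE(validate),
              drugs = drugs, gmt = gmt, n_features = n_features, k = k,
              feature_fraction = feature_fraction,
              n_iterations = n_iterations, concordance = concordance,
              capture_mb = capture_mb, rate_threshold = rate_threshold,
              alpha = alpha, minsplit = minsplit, minbucket = minbucket,
              drug_min_per_group = drug_min_per_group, drug_fdr = drug_fdr)
  if (!cfg$simulate) {
    if (is.null(cfg$input_dir)) {
      stop("input_dir is required when simulate = FALSE", call. = FALSE)
    }
    expr_path <- file.path(cfg$input_dir, "expression.tsv")
    if (!file.exists(expr_path)) {
      stop("expression matrix not found: ", expr_path, call. = FALSE)
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with [pipeline_config()] fields.
#' @return a `run_config` object.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

read_cohort_dir <- function(dir) {
  cohort <- list(
    expression = read_matrix_tsv(file.path(dir, "expression.tsv")),
    mutations = read_mutations(file.path(dir, "mutations.tsv")),
    cna = read_matrix_tsv(file.path(dir, "cna_arms.tsv")),
    rppa = read_matrix_tsv(file.path(dir, "rppa.tsv")),
    clinical = utils::read.delim(file.path(dir, "clinical.tsv"),
                                 stringsAsFactors = FALSE),
    truth = NULL, markers = NULL, config = NULL
  )
  truth_path <- file.path(dir, "truth.tsv")
  if (file.exists(truth_path)) {
    cohort$truth <- utils::read.delim(truth_path, stringsAsFactors = FALSE)
  }
  class(cohort) <- "omic_cohort"
  cohort
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order, writing one TSV/JSON file per
#' result plus `manifest.json` (all parameters, seeds and output file
#' checksums) and a plain-text `run.log`. A failing stage halts the run
#' with the stage name; outputs of completed stages are retained. Reruns
#' with the same configuration and seed are byte-identical.
#'
#' @param config a [pipeline_config()] object (or a YAML path).
#' @return the output directory, invisibly; the manifest is also returned
#'   as attribute `manifest`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  stage_seed <- function(stage) config$seed + STAGE_SEED_OFFSET[[stage]]
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(log_lines, paste0("FAILED at stage ", stage, ": ",
                                     conditionMessage(e))),
                 file.path(out, "run.log"))
      stop("stage ", stage, " failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  ## --- cohort ---
  validation_cohort <- NULL
  cohort <- run_stage("simulate", {
    if (config$simulate) {
      sim_args <- config$sim
      sim_args$seed <- stage_seed("simulate")
      sc <- do.call(sim_config, sim_args)
      if (config$validate) {
        pair <- simulate_validation_pair(sc)
        validation_cohort <- pair$validation
        ch <- pair$discovery
      } else {
        ch <- simulate_cohort(sc)
      }
      write_cohort(ch, file.path(out, "cohort"))
      note("simulate: n=", ncol(ch$expression), " genes=",
           nrow(ch$expression))
      ch
    } else {
      note("load: ", config$input_dir)
      read_cohort_dir(config$input_dir)
    }
  })
  if (config$validate && config$simulate) {
    ## re-create the pair deterministically (closure above cannot assign)
    sim_args <- config$sim
    sim_args$seed <- stage_seed("simulate")
    validation_cohort <- simulate_validation_pair(
      do.call(sim_config, sim_args))$validation
  }

  ## --- consensus subtype discovery ---
  disc <- run_stage("cluster", {
    d <- discover_subtypes(cohort$expression,
                           n_features = config$n_features, k = config$k,
                           n_iterations = config$n_iterations,
                           feature_fraction = config$feature_fraction,
                           concordance = config$concordance,
                           seed = stage_seed("cluster"))
    write_df_tsv(as.data.frame(d$assignment),
                 file.path(out, "assignment.tsv"))
    write_matrix_tsv(d$consensus$matrix, file.path(out, "consensus.tsv"),
                     "sample")
    sizes <- attr(d$assignment, "sizes")
    note("cluster: sizes ", paste(names(sizes), sizes, sep = "=",
                                  collapse = " "))
    d
  })
  labels <- disc$assignment$label
  labels[labels == "unassigned"] <- NA
  names(labels) <- disc$assignment$sample

  ## --- characterization ---
  chr <- run_stage("characterize", {
    res <- list()
    res$snr <- signal_to_noise(cohort$expression, labels)
    write_df_tsv(as.data.frame(res$snr), file.path(out, "snr.tsv"))
    if (!is.null(config$gmt)) {
      sets <- read_gmt(config$gmt)
      res$enrichment <- gsea(res$snr, sets,
                             seed = stage_seed("characterize"))
      write_df_tsv(as.data.frame(res$enrichment),
                   file.path(out, "enrichment.tsv"))
    }
    res$mutprof <- mutation_profile(cohort$mutations,
                                    samples = colnames(cohort$expression),
                                    capture_mb = config$capture_mb,
                                    rate_threshold = config$rate_threshold)
    write_df_tsv(data.frame(sample = names(res$mutprof$counts),
                            nonsilent = unname(res$mutprof$counts),
                            rate_per_mb = unname(res$mutprof$rate_per_mb),
                            high_rate = unname(res$mutprof$high_rate)),
                 file.path(out, "mutation_profile.tsv"))
    res$pi3k <- pathway_collapse(res$mutprof$gene_matrix, PI3K_GENES)
    ## per-arm CNA enrichment between subtypes
    cna_rows <- lapply(rownames(cohort$cna), function(arm) {
      fe <- fisher_enrichment(cohort$cna[arm, names(labels)] != 0, labels)
      data.frame(arm = arm, odds_ratio = fe$odds_ratio,
                 p_value = fe$p_value, stringsAsFactors = FALSE)
    })
    res$cna_enrichment <- do.call(rbind, cna_rows)
    write_df_tsv(res$cna_enrichment, file.path(out, "cna_enrichment.tsv"))
    ## factorization of RPPA-correlated genes + RPPA
    sel_genes <- select_rppa_correlated_genes(cohort$expression,
                                              cohort$rppa)
    res$factors <- joint_factorization(
      cohort$expression[sel_genes, , drop = FALSE], cohort$rppa,
      k = min(5, ncol(cohort$expression) - 1))
    write_matrix_tsv(t(res$factors$scores), file.path(out, "factors.tsv"),
                     "factor")
    ## EMT score from bundled marker genes when available
    if (!is.null(cohort$markers) && length(cohort$markers$emt)) {
      res$emt <- emt_score(cohort$expression, cohort$markers$emt)
    }
    note("characterize: ", nrow(res$snr), " genes ranked; PI3K frequency ",
         sprintf("%.3f", res$pi3k$frequency))
    res
  })

  ## --- cross-cohort validation ---
  if (config$validate && !is.null(validation_cohort)) {
    run_stage("validate", {
      rep_ <- validate_subtypes(cohort$expression, disc$assignment,
                                validation_cohort$expression,
                                n_features = config$n_features,
                                k = config$k,
                                n_iterations = config$n_iterations,
                                feature_fraction = config$feature_fraction,
                                concordance = config$concordance,
                                seed = stage_seed("validate"))
      write_df_tsv(data.frame(metric = c("pearson", "spearman"),
                              value = c(rep_$pearson, rep_$spearman)),
                   file.path(out, "validation.tsv"))
      note("validate: pearson=", sprintf("%.3f", rep_$pearson))
      rep_
    })
  }

  ## --- survival screen on RPPA epitopes ---
  clin <- cohort$clinical
  screen <- run_stage("survival", {
    base_cov <- clin[, intersect(c("size_mm", "grade", "positive_nodes",
                                   "hormonal_therapy", "chemo", "age"),
                                 colnames(clin)), drop = FALSE]
    s <- survival_screen(cohort$rppa[, clin$sample, drop = FALSE],
                         time = clin$time, event = clin$event,
                         base_covariates = base_cov,
                         strata = clin$biobank)
    write_df_tsv(as.data.frame(s), file.path(out, "screen.tsv"))
    note("survival: ", sum(s$q_value < 0.01, na.rm = TRUE),
         " epitope(s) at FDR<1%")
    s
  })

  ## --- survival tree ---
  run_stage("tree", {
    mp <- chr$mutprof
    feats <- data.frame(
      mutation_rate = unname(mp$rate_per_mb[clin$sample]),
      cna_burden = colMeans(cohort$cna[, clin$sample, drop = FALSE] != 0)
    )
    if (!is.null(chr$emt)) feats$emt <- unname(chr$emt[clin$sample])
    ## epitopes associated with survival enter as candidate features
    sig_ep <- screen$feature[!is.na(screen$q_value) & screen$q_value < 0.05]
    for (ep in sig_ep) {
      feats[[ep]] <- unname(cohort$rppa[ep, clin$sample])
    }
    tr <- fit_tree(feats, clin$time, clin$event,
                   tree_params(alpha = config$alpha,
                               minsplit = config$minsplit,
                               minbucket = config$minbucket))
    write_tree_json(tr, file.path(out, "tree.json"))
    write_df_tsv(data.frame(sample = clin$sample, group = tr$groups),
                 file.path(out, "groups.tsv"))
    km <- kaplan_meier(clin$time, clin$event, tr$groups)
    sm <- summary(km)
    grp <- if (is.null(sm$strata)) rep("all", length(sm$time))
           else as.character(sm$strata)
    km_df <- data.frame(group = grp, time = sm$time, surv = sm$surv)
    write_df_tsv(km_df, file.path(out, "km.tsv"))
    note("tree: ", tr$n_leaves, " leaves; features ",
         paste(tr$features_used, collapse = ","))
    tr
  })

  ## --- drug screen ---
  if (!is.null(config$drugs)) {
    run_stage("drugs", {
      auc <- read_matrix_tsv(config$drugs$auc)
      map_df <- utils::read.delim(config$drugs$subtype_map,
                                  stringsAsFactors = FALSE)
      map <- stats::setNames(as.character(map_df[[2]]), map_df[[1]])
      dr <- differential_drugs(auc, map,
                               min_per_group = config$drug_min_per_group,
                               fdr = config$drug_fdr)
      write_df_tsv(dr, file.path(out, "drugs.tsv"))
      note("drugs: ", sum(dr$significant), " differential at FDR<",
           config$drug_fdr)
      dr
    })
  }

  ## --- manifest and log ---
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        c("manifest.json", "run.log")))
  md5 <- tools::md5sum(file.path(out, files))
  manifest <- list(
    package = "lobsuite",
    parameters = config[setdiff(names(config), c("out_dir"))],
    stage_seeds = as.list(config$seed + STAGE_SEED_OFFSET),
    files = as.list(stats::setNames(unname(md5), files))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(structure(out, manifest = manifest))
}
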