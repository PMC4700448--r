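test_that("identical seed and config reproduce the cohort exactly", {
  cfg <- sim_config(n_samples = 40, n_genes = 100, n_signature_genes = 20,
                    n_epitopes = 4, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression, b$expression)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$cna, b$cna)
  expect_identical(a$rppa, b$rppa)
  c2 <- simulate_cohort(sim_config(n_samples = 40, n_genes = 100,
                                   n_signature_genes = 20, n_epitopes = 4,
                                   seed = 8))
  expect_false(identical(a$expression, c2$expression))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(frac_subtype1 = 0.8, frac_mixed = 0.3),
               "exceed 1")
  expect_error(sim_config(mutation_freqs = numeric(0)), "at least one")
  expect_error(sim_config(mutation_freqs = c(0.4, 0.2)), "named")
  expect_error(sim_config(mutation_freqs = c(CDH1 = 1.2)), "\\[0, 1\\]")
  expect_error(sim_config(effect_size = -1), "effect_size")
  expect_error(sim_config(n_genes = 10, n_signature_genes = 20),
               "n_signature_genes")
})

test_that("cohort tables share one sample index and times are positive", {
  ch <- small_cohort(seed = 3)
  ids <- colnames(ch$expression)
  expect_identical(colnames(ch$rppa), ids)
  expect_identical(colnames(ch$cna), ids)
  expect_identical(ch$clinical$sample, ids)
  expect_identical(ch$truth$sample, ids)
  expect_true(all(ch$mutations$sample %in% ids))
  expect_true(all(ch$clinical$time > 0))
  expect_true(all(ch$clinical$event %in% 0:1))
  expect_true(all(ch$cna %in% c(-1L, 0L, 1L)))
  ## a single hormone-receptor-negative sample
  expect_identical(sum(ch$clinical$er == "neg"), 1L)
})

test_that("empirical mutation frequencies match the configured rates", {
  ## CDH1 at its published 42.8% frequency; binomial tolerance at n = 10000
  cfg <- sim_config(n_samples = 10000, n_genes = 20, n_signature_genes = 4,
                    n_epitopes = 2,
                    mutation_freqs = c(CDH1 = 0.428, PIK3CA = 0.348),
                    seed = 42)
  ch <- simulate_cohort(cfg)
  cdh1 <- sum(ch$mutations$gene == "CDH1" & ch$mutations$class != "silent")
  expect_lt(abs(cdh1 / 10000 - 0.428), 0.01)
  pik <- sum(ch$mutations$gene == "PIK3CA" & ch$mutations$class != "silent")
  expect_lt(abs(pik / 10000 - 0.348), 0.01)
})

test_that("non-silent burden has median ~6 and the hypermutated class is exact", {
  ch <- simulate_cohort(sim_config(n_samples = 1000, n_genes = 50,
                                   n_signature_genes = 10, n_epitopes = 2,
                                   seed = 9))
  mp <- mutation_profile(ch$mutations, ch$truth$sample)
  expect_lte(abs(median(mp$counts) - 6), 1)
  ## latent flag coincides with the count criterion
  expect_identical(unname(mp$high_rate), ch$truth$high_rate)
  expect_identical(sum(ch$truth$high_rate), 60L)
  expect_true(all(mp$counts[ch$truth$high_rate] >= 10))
  expect_true(all(mp$counts[!ch$truth$high_rate] < 10))
})

test_that("hypermutation hazard coefficient is recovered by a Cox fit", {
  ## beta_mutrate = 1 and no epitope effect: group hazard ratio -> e
  cfg <- sim_config(n_samples = 2000, n_genes = 30, n_signature_genes = 6,
                    n_epitopes = 2, beta_mutrate = 1, beta_eif4b = 0,
                    censor_frac = 0.2, seed = 17)
  ch <- simulate_cohort(cfg)
  fit <- cox_lrt(ch$clinical$time, ch$clinical$event,
                 as.numeric(ch$truth$high_rate))
  expect_gt(fit$hr, 2.3)
  expect_lt(fit$hr, 3.3)
})

test_that("epitopes track cognate transcripts at the target correlation", {
  ch <- simulate_cohort(sim_config(n_samples = 500, n_genes = 100,
                                   n_signature_genes = 20, n_epitopes = 8,
                                   epitope_gene_corr = 0.7, seed = 5))
  eps <- setdiff(rownames(ch$rppa), "eIF4B")
  cors <- vapply(eps, function(e) {
    gene <- sub("^ep\\.", "", e)
    cor(ch$rppa[e, ], ch$expression[gene, ])
  }, numeric(1))
  expect_lt(abs(mean(cors) - 0.7), 0.08)
  expect_true("eIF4B" %in% rownames(ch$rppa))
  ## eIF4B independent of subtype
  p <- wilcoxon_marker(ch$rppa["eIF4B", ch$truth$subtype != "mixed"],
                       ch$truth$subtype[ch$truth$subtype != "mixed"])$p_value
  expect_gt(p, 0.001)
})

test_that("zero effect size carries no subtype signal", {
  ch <- small_cohort(seed = 11, effect_size = 0)
  lab <- ch$truth$subtype
  keep <- lab != "mixed"
  snr <- signal_to_noise(ch$expression[, keep], lab[keep])
  expect_lt(max(abs(snr$score)), 1)   # no gene separates the groups strongly
  expect_lt(abs(mean(snr$score)), 0.05)
})

test_that("validation pairs share gene identities but not samples", {
  cfg <- sim_config(n_samples = 50, n_genes = 200, n_signature_genes = 40,
                    n_epitopes = 4, seed = 2)
  pair <- simulate_validation_pair(cfg)
  expect_identical(rownames(pair$discovery$expression),
                   rownames(pair$validation$expression))
  expect_identical(pair$discovery$markers, pair$validation$markers)
  expect_false(any(colnames(pair$discovery$expression) %in%
                     colnames(pair$validation$expression)))
  expect_false(identical(pair$discovery$truth$subtype,
                         pair$validation$truth$subtype))
})

test_that("cohorts round-trip through the TSV writer", {
  ch <- small_cohort(seed = 19, n = 25)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expr <- read_matrix_tsv(file.path(dir, "expression.tsv"))
  expect_equal(expr, ch$expression, tolerance = 1e-12)
  muts <- read_mutations(file.path(dir, "mutations.tsv"))
  expect_identical(nrow(muts), nrow(ch$mutations))
  expect_true(all(muts$class %in% c("Missense_Mutation",
                                    "Nonsense_Mutation", "Silent")))
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  expect_identical(cfg$n_samples, 25L)
})
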