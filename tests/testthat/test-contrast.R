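test_that("signal-to-noise scores match the closed form and its symmetries", {
  x <- rbind(g1 = c(1, 3, 0, 2))
  colnames(x) <- paste0("s", 1:4)
  lab <- c("a", "a", "b", "b")
  expect_equal(signal_to_noise(x, lab)$score, 1 / (2 * sqrt(2)),
               tolerance = 1e-6)
  ## identical groups score zero
  x2 <- rbind(g1 = c(1, 2, 1, 2))
  colnames(x2) <- colnames(x)
  expect_equal(signal_to_noise(x2, lab)$score, 0)
  ## swapping labels negates every score
  set.seed(3)
  m <- matrix(rnorm(80), 8, 10,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  labs <- rep(c("a", "b"), 5)
  fwd <- signal_to_noise(m, labs)
  rev_ <- signal_to_noise(m, chartr("ab", "ba", labs))
  expect_equal(setNames(fwd$score, fwd$gene)[rev_$gene], -rev_$score,
               ignore_attr = TRUE)
  expect_error(signal_to_noise(m, c("a", rep("b", 9))), ">= 2 samples")
})

test_that("enrichment scores match a brute-force running sum exactly", {
  set.seed(7)
  scores <- sort(rnorm(10), decreasing = TRUE)
  rk <- data.frame(gene = paste0("g", 1:10), score = scores)
  hits <- c(1, 4, 9)
  res <- gsea(rk, list(s = paste0("g", hits)), n_perm = 200, seed = 1)
  expect_equal(res$es, es_oracle(scores, seq_len(10) %in% hits),
               tolerance = 1e-12)
  ## single top-ranked gene at weight 0 maximizes the running sum
  res1 <- gsea(rk, list(top = "g1"), n_perm = 50, p = 0, seed = 1)
  expect_equal(res1$es, 1)
  ## uniformly interleaved set: small |ES|, large p
  rk2 <- data.frame(gene = paste0("g", 1:20), score = seq(2, -2,
                                                          length.out = 20))
  even <- paste0("g", seq(2, 20, 2))
  res2 <- gsea(rk2, list(even = even), n_perm = 500, seed = 5)
  expect_gt(res2$p_value, 0.5)
  expect_warning(gsea(rk, list(s = "g1", none = "absent"), n_perm = 20,
                      seed = 1),
                 "no gene in the ranked list")
})

test_that("enrichment scores agree with an independent implementation", {
  set.seed(21)
  genes <- paste0("g", 1:200)
  scores <- sort(rnorm(200, sd = 2), decreasing = TRUE)
  rk <- data.frame(gene = genes, score = scores)
  sets <- list(a = sample(genes, 15), b = sample(genes, 40),
               c = genes[1:10])
  res <- gsea(rk, sets, n_perm = 100, seed = 2)
  for (nm in names(sets)) {
    ref <- fgsea::calcGseaStat(setNames(scores, genes),
                               which(genes %in% sets[[nm]]),
                               gseaParam = 1)
    expect_equal(res$es[res$set == nm], ref, tolerance = 1e-8)
  }
})

test_that("weight-zero enrichment is invariant to monotone score changes", {
  genes <- paste0("g", 1:30)
  rk1 <- data.frame(gene = genes, score = seq(3, -3, length.out = 30))
  rk2 <- data.frame(gene = genes,
                    score = exp(seq(3, -3, length.out = 30)))
  set_ <- list(s = genes[c(2, 5, 11, 25)])
  e1 <- gsea(rk1, set_, n_perm = 10, p = 0, seed = 1)$es
  e2 <- gsea(rk2, set_, n_perm = 10, p = 0, seed = 1)$es
  expect_equal(e1, e2, tolerance = 1e-12)
})

test_that("rank-sum marker test is exact for small samples", {
  res <- wilcoxon_marker(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$p_value, 1 / 3, tolerance = 1e-12)
  ## identical groups and fully tied values
  expect_equal(wilcoxon_marker(rep(2, 8), rep(c("a", "b"), 4))$p_value, 1)
  expect_equal(wilcoxon_marker(c(1, 2, 3, 1, 2, 3),
                               rep(c("a", "b"), each = 3))$p_value, 1)
  ## exact p matches full enumeration for random untied data
  set.seed(5)
  for (r in 1:5) {
    v <- sample(1000, 8)
    a <- v[1:4]
    b <- v[5:8]
    p_pkg <- wilcoxon_marker(c(a, b), rep(c("a", "b"), each = 4))$p_value
    expect_equal(p_pkg, wilcox_oracle(a, b), tolerance = 1e-12)
  }
  expect_error(wilcoxon_marker(1:4, rep("a", 4)), "two classes")
})

test_that("Fisher enrichment reproduces hypergeometric enumeration", {
  f <- fisher_enrichment(table2x2 = matrix(c(3, 1, 1, 3), 2))
  expect_equal(f$p_value, 0.4857143, tolerance = 1e-6)
  f2 <- fisher_enrichment(table2x2 = matrix(c(5, 0, 0, 5), 2))
  expect_equal(f2$p_value, 2 / 252, tolerance = 1e-9)
  ## independence: odds ratio 1
  f3 <- fisher_enrichment(table2x2 = matrix(c(6, 3, 4, 2), 2))
  expect_equal(f3$odds_ratio, 1)
  ## empty margin flagged with p = 1
  f4 <- fisher_enrichment(table2x2 = matrix(c(0, 0, 4, 2), 2))
  expect_true(f4$degenerate)
  expect_equal(f4$p_value, 1)
  ## vector interface builds the table over complete pairs
  feat <- c(1, 1, 1, 0, 0, 0, NA)
  lab <- c("x", "x", "y", "y", "y", "x", "x")
  f5 <- fisher_enrichment(feat, lab)
  expect_identical(sum(f5$table), 6L)
})

test_that("signature overlap binomial tail behaves as the closed form", {
  expect_equal(signature_overlap_binomial(10, 10, 0.5), 0.5^10)
  expect_equal(signature_overlap_binomial(0, 25, 0.3), 1)
  ## at any plausible background rate the reported overlap is extreme
  expect_lt(signature_overlap_binomial(685, 1902, 0.25), 1e-6)
  expect_error(signature_overlap_binomial(11, 10, 0.5), "sig_size")
  expect_error(signature_overlap_binomial(5, 10, 0), "background_rate")
})

test_that("signature scoring averages z-scores and separates planted subtypes", {
  set.seed(9)
  x <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  sc <- emt_score(x, "g2")
  expect_equal(unname(sc), unname(scale(x["g2", ])[, 1]))
  ## a sample sitting at the cohort mean on every signature gene scores 0
  y <- rbind(a = c(1, 3, 2), b = c(5, 1, 3))
  colnames(y) <- paste0("s", 1:3)  # s3 is at the mean of both genes
  expect_equal(unname(emt_score(y, c("a", "b"))["s3"]), 0)
  expect_error(emt_score(x, "missing_gene"), "no signature gene")
  expect_warning(emt_score(x, c("g1", "nope")), "absent")
  ## planted subtype-2 EMT signal is detected at n = 100
  ch <- simulate_cohort(sim_config(n_samples = 100, n_genes = 300,
                                   n_signature_genes = 60, effect_size = 1,
                                   n_epitopes = 2, seed = 33))
  keep <- ch$truth$subtype != "mixed"
  sc2 <- emt_score(ch$expression[, keep], ch$markers$emt)
  expect_lt(wilcoxon_marker(sc2, ch$truth$subtype[keep])$p_value, 0.01)
})

test_that("RPPA-correlated gene selection follows the absolute-correlation order", {
  set.seed(12)
  n <- 30
  e1 <- rnorm(n)
  genes <- rbind(gA = e1 * 2 + rnorm(n, sd = 0.1),     # strong +
                 gB = -e1 * 2 + rnorm(n, sd = 0.15),   # strong -
                 gC = rnorm(n), gD = rnorm(n), gE = rnorm(n))
  colnames(genes) <- paste0("s", 1:n)
  rppa <- rbind(ep1 = e1)
  colnames(rppa) <- colnames(genes)
  sel <- select_rppa_correlated_genes(genes, rppa, top_n = 2)
  expect_setequal(sel, c("gA", "gB"))
  ## duplicated epitope leaves the union unchanged
  rppa2 <- rbind(ep1 = e1, ep2 = e1)
  colnames(rppa2) <- colnames(genes)
  expect_setequal(select_rppa_correlated_genes(genes, rppa2, top_n = 2),
                  sel)
  ## exhaustive check against the full correlation table on 2 epitopes
  rppa3 <- rbind(ep1 = e1, ep2 = rnorm(n))
  colnames(rppa3) <- colnames(genes)
  sel3 <- select_rppa_correlated_genes(genes, rppa3, top_n = 1)
  best2 <- rownames(genes)[which.max(abs(cor(t(genes), rppa3["ep2", ])))]
  expect_setequal(sel3, unique(c("gA", best2)))
  flat_rppa <- rbind(flat = rep(1, n), ep1 = e1)
  colnames(flat_rppa) <- colnames(genes)
  expect_warning(select_rppa_correlated_genes(genes, flat_rppa),
                 "constant epitope")
})

test_that("joint factorization recovers planted shared factors", {
  set.seed(4)
  n <- 40
  v <- rnorm(n)
  expr <- outer(rnorm(6), v) + matrix(rnorm(6 * n, sd = 1e-3), 6, n)
  rppa <- outer(rnorm(3), v) + matrix(rnorm(3 * n, sd = 1e-3), 3, n)
  dimnames(expr) <- list(paste0("g", 1:6), paste0("s", 1:n))
  dimnames(rppa) <- list(paste0("e", 1:3), paste0("s", 1:n))
  jf <- joint_factorization(expr, rppa, k = 1)
  expect_gt(abs(cor(jf$scores[, 1], v)), 0.999)
  ## sign convention: positive correlation with the largest-weight feature
  imax <- which.max(abs(jf$weights[, 1]))
  expect_gt(cor(jf$scores[, 1],
                rbind(expr / sqrt(6), rppa / sqrt(3))[imax, ]), 0)
  expect_error(joint_factorization(expr, rppa, k = n), "below the sample")
  ## two orthogonal planted factors at n = 200
  set.seed(14)
  n2 <- 200
  f1 <- rnorm(n2); f2 <- rnorm(n2)
  E <- outer(rnorm(40), f1) + outer(rnorm(40, sd = 0.5), f2) +
    matrix(rnorm(40 * n2, sd = 0.3), 40, n2)
  P <- outer(rnorm(10), f1) + outer(rnorm(10, sd = 0.5), f2) +
    matrix(rnorm(10 * n2, sd = 0.3), 10, n2)
  dimnames(E) <- list(paste0("g", 1:40), paste0("s", 1:n2))
  dimnames(P) <- list(paste0("e", 1:10), paste0("s", 1:n2))
  jf2 <- joint_factorization(E, P, k = 2)
  cors <- abs(cor(jf2$scores, cbind(f1, f2)))
  expect_gt(max(cors[, 1]), 0.95)
  expect_gt(max(cors[, 2]), 0.95)
})
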