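test_that("hierarchical base clustering separates blobs and handles edge cases", {
  x <- make_blobs(n1 = 8, n2 = 8, sep = 5, seed = 3)
  lab <- base_cluster(x, k = 2)
  expect_equal(adjusted_rand(lab, attr(x, "truth")), 1)
  ## k = n: every sample its own cluster
  lab_n <- base_cluster(x, k = ncol(x))
  expect_identical(length(unique(lab_n)), ncol(x))
  ## constant sample errors under Pearson distance, naming the sample
  bad <- x
  bad[, 3] <- 1
  expect_error(base_cluster(bad, 2), "s3")
  expect_error(base_cluster(x, k = 1), "k must be")
})

test_that("average linkage merges a hand-computed toy in the derived order", {
  ## 1-D points 0, 1, 3.5, 10 (euclidean): merge {0,1} (d=1), then
  ## {0,1}+{3.5} (avg d = (3.5+2.5)/2 = 3), then all.
  x <- rbind(f = c(0, 1, 3.5, 10))
  colnames(x) <- paste0("s", 1:4)
  expect_identical(unname(base_cluster(x, k = 2, distance = "euclidean")),
                   c(1L, 1L, 1L, 2L))
  expect_identical(unname(base_cluster(x, k = 3, distance = "euclidean")),
                   c(1L, 1L, 2L, 3L))
})

test_that("consensus matrices satisfy their invariants", {
  x <- make_blobs(n1 = 6, n2 = 6, sep = 4, seed = 5)
  cm <- consensus_matrix(x, n_iterations = 50, seed = 2)
  m <- cm$matrix
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))
  ## perfectly separated data: entries are all 0 or 1, matching the truth
  expect_true(all(m %in% c(0, 1)))
  truth <- attr(x, "truth")
  expect_true(all(m[truth == 1, truth == 1] == 1))
  expect_true(all(m[truth == 1, truth == 2] == 0))
  ## seed reproducibility
  expect_identical(consensus_matrix(x, n_iterations = 25, seed = 9)$matrix,
                   consensus_matrix(x, n_iterations = 25, seed = 9)$matrix)
  expect_error(consensus_matrix(x, feature_fraction = 0), "feature_fraction")
  expect_error(consensus_matrix(x, feature_fraction = 1.2),
               "feature_fraction")
})

test_that("full feature fraction removes resampling randomness", {
  x <- make_blobs(n1 = 5, n2 = 5, sep = 3, seed = 7)
  one <- consensus_matrix(x, n_iterations = 2, feature_fraction = 1,
                          seed = 1)
  many <- consensus_matrix(x, n_iterations = 40, feature_fraction = 1,
                           seed = 99)
  expect_identical(one$matrix, many$matrix)
  expect_true(all(one$matrix %in% c(0, 1)))
})

test_that("weak-signal consensus entries concentrate away from 0/1", {
  frac_mid <- function(effect, seed) {
    ch <- simulate_cohort(sim_config(n_samples = 60, n_genes = 300,
                                     n_signature_genes = 60,
                                     effect_size = effect, n_epitopes = 2,
                                     seed = seed))
    d <- discover_subtypes(ch$expression, n_features = 200,
                           n_iterations = 100, seed = seed + 1)
    m <- d$consensus$matrix
    off <- m[upper.tri(m)]
    mean(off > 0.2 & off < 0.8)
  }
  expect_gt(frac_mid(0, 21), frac_mid(2.5, 21))
})

test_that("stability-based assignment respects the concordance threshold", {
  ## clean block-diagonal consensus: everyone assigned
  m <- matrix(0, 10, 10, dimnames = list(paste0("s", 1:10),
                                         paste0("s", 1:10)))
  m[1:6, 1:6] <- 1
  m[7:10, 7:10] <- 1
  a <- assign_stable(m)
  expect_identical(sum(a$label == "unassigned"), 0L)
  expect_identical(unname(attr(a, "sizes")[c("1", "2")]), c(6L, 4L))
  expect_true(all(a$min_concordance[a$label != "unassigned"] >= 0.8))
  ## a sample with concordance 0.5 to every other cannot be assigned
  m2 <- m
  m2[5, ] <- 0.5
  m2[, 5] <- 0.5
  diag(m2) <- 1
  a2 <- assign_stable(m2)
  expect_identical(a2$label[5], "unassigned")
  expect_identical(sum(a2$label == "unassigned"), 1L)
  expect_error(assign_stable(m, threshold = 0), "threshold")
})

test_that("assignment is idempotent on the induced stable sub-matrix", {
  set.seed(13)
  ## blocky consensus with noise and some ambiguous samples
  n <- 20
  truth <- rep(1:2, each = 10)
  m <- outer(truth, truth, "==") * 0.6 + 0.2
  m <- m + matrix(runif(n * n, 0, 0.25), n, n)
  m <- (m + t(m)) / 2
  m[m > 1] <- 1
  diag(m) <- 1
  dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
  a <- assign_stable(m, threshold = 0.8)
  keep <- a$label != "unassigned"
  a2 <- assign_stable(m[keep, keep], threshold = 0.8)
  expect_true(all(a2$label != "unassigned"))
  expect_equal(adjusted_rand(a$label[keep], a2$label), 1)
})

test_that("greedy removal attains the minimal removal count on small matrices", {
  ## oracle: over all removal subsets (smallest first), does some subset of
  ## that size make both initial clusters satisfy the all-pairs rule?
  min_removals <- function(m, cl, threshold) {
    n <- nrow(m)
    ok <- function(keep) {
      for (g in unique(cl)) {
        idx <- intersect(which(cl == g), keep)
        if (length(idx) >= 2) {
          sub <- m[idx, idx]
          if (min(sub[upper.tri(sub)]) < threshold) return(FALSE)
        }
      }
      TRUE
    }
    for (r in 0:n) {
      for (drop in if (r == 0) list(integer(0)) else
             asplit(combn(n, r), 2)) {
        if (ok(setdiff(seq_len(n), drop))) return(r)
      }
    }
    n
  }
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    truth <- sample(1:2, n, replace = TRUE)
    if (length(unique(truth)) < 2) truth[1] <- 3 - truth[1]
    m <- outer(truth, truth, "==") * 0.7 + 0.15 +
      matrix(runif(n * n, 0, 0.2), n, n)
    m <- pmin((m + t(m)) / 2, 1)
    diag(m) <- 1
    dimnames(m) <- list(paste0("s", 1:n), paste0("s", 1:n))
    a <- assign_stable(m, threshold = 0.8)
    ## constraint satisfied by construction of the algorithm
    for (g in c("1", "2")) {
      idx <- which(a$label == g)
      if (length(idx) >= 2) {
        sub <- m[idx, idx]
        expect_gte(min(sub[upper.tri(sub)]), 0.8)
      }
    }
    ## removal count is minimal for the same initial partition
    hc <- hclust(dist(m), method = "complete")
    cl <- cutree(hc, k = 2)
    expect_identical(sum(a$label == "unassigned"),
                     min_removals(m, cl, 0.8))
  }
})

test_that("cross-method stability report agrees on strong signal", {
  x <- make_blobs(n1 = 15, n2 = 15, g = 120, sep = 2, seed = 9)
  x <- x - apply(x, 1, median)
  rep_ <- stability_report(x, methods = list(
    list(linkage = "average", distance = "pearson"),
    list(linkage = "average", distance = "pearson"),
    list(linkage = "ward", distance = "pearson")
  ), n_iterations = 80, seed = 3)
  expect_equal(rep_$ari[1, 2], 1)       # identical method twice
  expect_gte(rep_$ari[1, 3], 0.8)       # ward vs average
  expect_true(rep_$stable)
  expect_error(stability_report(x, methods = list(list(linkage = "ward",
                                                       distance = "pearson"))),
               ">= 2 methods")
})

test_that("label recovery improves with effect size over a fixed seed grid", {
  ari_at <- function(effect) {
    ch <- simulate_cohort(sim_config(n_samples = 80, n_genes = 400,
                                     n_signature_genes = 80,
                                     effect_size = effect, n_epitopes = 2,
                                     frac_mixed = 0.15, seed = 101))
    d <- discover_subtypes(ch$expression, n_features = 250,
                           n_iterations = 120, seed = 102)
    lab <- d$assignment$label
    lab[lab == "unassigned"] <- NA
    a <- adjusted_rand(lab, ch$truth$subtype)
    if (is.na(a)) 0 else a
  }
  curve <- vapply(c(0, 1, 2.5), ari_at, numeric(1))
  expect_gte(curve[2], curve[1] - 0.1)
  expect_gte(curve[3], curve[2] - 0.1)
  expect_gt(curve[3], 0.8)
  expect_lt(curve[1], 0.5)
})
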