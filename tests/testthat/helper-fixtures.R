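## Shared fixtures, all generated in code.

## Two well-separated Gaussian sample blobs (genes x samples).
make_blobs <- function(n1 = 10, n2 = 10, g = 50, sep = 4, seed = 1) {
  set.seed(seed)
  pattern <- sep / 2 * rep_len(c(1, -1), g)
  x <- cbind(matrix(rnorm(g * n1, mean = pattern), g, n1),
             matrix(rnorm(g * n2, mean = -pattern), g, n2))
  dimnames(x) <- list(paste0("g", seq_len(g)),
                      paste0("s", seq_len(n1 + n2)))
  attr(x, "truth") <- rep(c(1L, 2L), c(n1, n2))
  x
}

## A small simulated cohort for module tests (fast).
small_cohort <- function(seed = 1, n = 60, effect_size = 2, ...) {
  simulate_cohort(sim_config(n_samples = n, n_genes = 300,
                             n_signature_genes = 60,
                             effect_size = effect_size, n_epitopes = 6,
                             seed = seed, ...))
}

## Exact Benjamini-Hochberg step-up adjusted p-values from the definition:
## q_(i) = min_{j >= i} m * p_(j) / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

## Two-sided Fisher p by explicit hypergeometric enumeration (sum of table
## probabilities not exceeding the observed one).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- dhyper(support, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Exact two-sided rank-sum p by enumerating all group assignments.
wilcox_oracle <- function(a, b) {
  v <- c(a, b)
  n1 <- length(a)
  r <- rank(v)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # observed U
  combs <- combn(length(v), n1)
  us <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mu <- n1 * (length(b)) / 2
  min(1, sum(abs(us - mu) >= abs(obs - mu) - 1e-9) / ncol(combs))
}

## Weighted running-sum enrichment score by direct accumulation.
es_oracle <- function(scores, hits, p = 1) {
  n <- length(scores)
  nh <- sum(hits)
  nr <- sum(abs(scores[hits])^p)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hits[i]) abs(scores[i])^p / nr else -1 / (n - nh)
    if (abs(run) > abs(best)) best <- run
  }
  best
}

## Two-group log-rank chi-square from the O-E table accumulated time by
## time (simultaneous risk sets at tied times).
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  o_minus_e <- 0
  v <- 0
  for (u in sort(unique(time[event == 1]))) {
    at_risk <- time >= u
    n <- sum(at_risk)
    n1 <- sum(at_risk & g == 1)
    d <- sum(time == u & event == 1)
    d1 <- sum(time == u & event == 1 & g == 1)
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (o_minus_e)^2 / v
}

## All n! permutations of 1..n as rows (small n only).
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
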