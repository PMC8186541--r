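# Fixtures built in code: unrelated Hardy-Weinberg genotypes (with a fixed
# frequency base so G is invertible when m >= n), phenotypes drawn from the
# GBLUP model, and random valid pedigrees for property tests.

hwe_genotypes <- function(n, m, seed, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p0 <- runif(m, maf[1], maf[2])
  M <- matrix(rbinom(n * m, 2, rep(p0, each = n)), n, m)
  genotypes(M, ids = paste0("id", seq_len(n)), freqs = p0)
}

# phenotype drawn from y = X beta + a + e, a ~ N(0, G sigma2_a)
gblup_phenotype <- function(G, X, beta, sigma2_a, sigma2_e, seed) {
  set.seed(seed)
  n <- nrow(G)
  L <- chol(G * sigma2_a + diag(1e-10, n))
  a <- as.numeric(t(L) %*% rnorm(n))
  drop(X %*% beta) + a + rnorm(n, 0, sqrt(sigma2_e))
}

# random pedigree in birth order; parents sampled among earlier animals
random_pedigree <- function(n, seed, n_founders = max(4, n %/% 5)) {
  set.seed(seed)
  sire <- dam <- rep("0", n)
  for (i in (n_founders + 1):n) {
    cand <- seq_len(i - 1)
    if (runif(1) < 0.85) sire[i] <- paste0("p", sample(cand, 1))
    if (runif(1) < 0.85) dam[i] <- paste0("p", sample(cand, 1))
  }
  pedigree(paste0("p", seq_len(n)), sire, dam)
}

# single-locus gene-dropping oracle: empirical additive relationship as
# twice the kinship (probability two random alleles are IBD)
gene_drop_relationship <- function(ped, id1, id2, reps = 20000, seed = 1) {
  set.seed(seed)
  n <- ped$n
  hits <- 0L
  for (r in seq_len(reps)) {
    al <- matrix(0L, n, 2)
    cnt <- 0L
    for (i in seq_len(n)) {
      s <- ped$sire[i]; d <- ped$dam[i]
      al[i, 1] <- if (s > 0) al[s, sample(2, 1)] else (cnt <- cnt + 1L)
      al[i, 2] <- if (d > 0) al[d, sample(2, 1)] else (cnt <- cnt + 1L)
    }
    a <- match(id1, ped$id); b <- match(id2, ped$id)
    hits <- hits + (al[a, sample(2, 1)] == al[b, sample(2, 1)])
  }
  2 * hits / reps
}
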