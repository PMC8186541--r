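test_that("single-record system shrinks halfway at lambda = 1", {
  K <- matrix(1, 1, 1, dimnames = list("a1", "a1"))
  sys <- solve_mme(assemble_mme(3, NULL, "a1", solve(K), 1, 1))
  expect_equal(unname(sys$u[[1]]), 3 / 2)
  expect_equal(extract_pev_block(sys)[1, 1], 0.5)
})

test_that("breeding values vanish in the infinite-shrinkage limit", {
  set.seed(1)
  n <- 12
  K <- diag(n); dimnames(K) <- list(paste0("a", 1:n), paste0("a", 1:n))
  y <- rnorm(n)
  sys <- solve_mme(assemble_mme(y, matrix(1, n, 1), rownames(K), K,
                                sigma2_a = 1e-10, sigma2_e = 1))
  expect_lt(max(abs(sys$u[[1]])), 1e-6)
})

test_that("MME solutions equal the generalized-least-squares oracle", {
  ped <- random_pedigree(20, seed = 5)
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped, F = attr(A, "F"))
  set.seed(6)
  X <- cbind(1, rnorm(20), sample(0:1, 20, TRUE))
  beta <- c(2, 0.5, -1)
  s2a <- 0.4; s2e <- 0.6
  y <- drop(X %*% beta) + drop(t(chol(as.matrix(A) * s2a)) %*% rnorm(20)) +
    rnorm(20, 0, sqrt(s2e))
  sys <- solve_mme(assemble_mme(y, X, ped$id, Ainv, s2a, s2e))
  ## GLS via dense V
  V <- as.matrix(A) * s2a + diag(s2e, 20)
  Vi <- solve(V)
  bgls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  agls <- s2a * as.matrix(A) %*% Vi %*% (y - X %*% bgls)
  expect_equal(unname(sys$beta), unname(drop(bgls)), tolerance = 1e-8)
  expect_equal(unname(sys$u[[1]]), unname(drop(agls)), tolerance = 1e-8)
})

test_that("solve_mme is exact on identity systems and permutation invariant", {
  n <- 8
  K <- diag(n); dimnames(K) <- list(paste0("a", 1:n), paste0("a", 1:n))
  set.seed(2)
  y <- rnorm(n)
  sys1 <- solve_mme(assemble_mme(y, NULL, rownames(K), K, 1, 1))
  perm <- sample(n)
  Kp <- K[perm, perm]
  sys2 <- solve_mme(assemble_mme(y, NULL, rownames(K), Kp, 1, 1))
  expect_equal(sys2$u[[1]][names(sys1$u[[1]])], sys1$u[[1]],
               tolerance = 1e-10)
})

test_that("rank-deficient fixed effects are constrained deterministically", {
  set.seed(3)
  n <- 15
  K <- diag(n); dimnames(K) <- list(paste0("a", 1:n), paste0("a", 1:n))
  f <- factor(sample(c("g1", "g2"), n, TRUE))
  X <- cbind(1, stats::model.matrix(~ f - 1))  # intercept + both levels
  y <- rnorm(n)
  sys <- solve_mme(assemble_mme(y, X, rownames(K), K, 1, 1))
  expect_length(sys$dropped_fixed, 1)
  expect_equal(sys$beta[sys$dropped_fixed], 0)
  ## fitted fixed-part identical to the full-rank parameterisation
  X2 <- stats::model.matrix(~ f)
  sys2 <- solve_mme(assemble_mme(y, X2, rownames(K), K, 1, 1))
  expect_equal(drop(X %*% sys$beta), drop(X2 %*% sys2$beta),
               tolerance = 1e-8)
})

test_that("PEV blocks carry trait-variance units", {
  ## animal with no records and no relatives has PEV = sigma2_a
  K <- diag(2); dimnames(K) <- list(c("a1", "a2"), c("a1", "a2"))
  sys <- solve_mme(assemble_mme(5, NULL, "a1", K, sigma2_a = 0.7,
                                sigma2_e = 0.3))
  pev <- extract_pev_block(sys, c("a1", "a2"))
  expect_equal(pev["a2", "a2"], 0.7, tolerance = 1e-10)
  expect_lt(pev["a1", "a1"], 0.7)
  expect_error(extract_pev_block(sys, "nosuch"), "unknown animal")

  ## block equals the corresponding block of the dense full inverse
  ped <- random_pedigree(20, seed = 9)
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped, F = attr(A, "F"))
  set.seed(10)
  y <- rnorm(20)
  sys <- solve_mme(assemble_mme(y, matrix(1, 20, 1), ped$id, Ainv,
                                0.5, 0.5))
  Cfull <- solve(sys$lhs) * 0.5
  ids <- ped$id[c(4, 11, 17)]
  expect_equal(extract_pev_block(sys, ids),
               Cfull[1 + c(4, 11, 17), 1 + c(4, 11, 17)],
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("GBLUP breeding values equal Z times the ridge SNP solution", {
  g <- hwe_genotypes(50, 120, seed = 11)
  G <- build_G(g)
  cz <- center_genotypes(g)
  s2a <- 0.5; s2e <- 0.5
  set.seed(12)
  X <- cbind(1, rnorm(50))
  y <- gblup_phenotype(G, X, c(1, 0.3), s2a, s2e, seed = 13)
  res <- gwas_gblup(y, X, g$ids, g, s2a, s2e, G = G)
  a_hat <- attr(res, "a_hat")
  ## SNP-centric ridge system with sigma2_g = sigma2_a / k
  lam <- s2e / (s2a / cz$k)
  m <- ncol(cz$Z)
  lhs <- rbind(cbind(crossprod(X), crossprod(X, cz$Z)),
               cbind(crossprod(cz$Z, X), crossprod(cz$Z) + diag(lam, m)))
  rhs <- c(crossprod(X, y), crossprod(cz$Z, y))
  sol <- solve(lhs, rhs)
  ghat_ridge <- sol[-(1:2)]
  expect_equal(unname(a_hat), unname(drop(cz$Z %*% ghat_ridge)),
               tolerance = 1e-8)
  ## and the back-solved effects reproduce the ridge solution (Eq. 5 path)
  expect_equal(unname(res$effect[match(g$map$snp, res$snp)]),
               unname(ghat_ridge), tolerance = 1e-8)
})

test_that("EM-REML recovers variance components and is monotone", {
  ## null trait: estimated heritability is near zero
  g <- hwe_genotypes(300, 600, seed = 14)
  G <- build_G(g)
  set.seed(15)
  h2_null <- replicate(3, {
    y <- rnorm(300)
    ## near the sigma2_a = 0 boundary EM creeps; the estimate is what counts
    suppressWarnings(estimate_variance_components(y, NULL, g$ids, G)$h2)
  })
  expect_lt(stats::median(h2_null), 0.05)

  ## moderate heritability recovered on family-structured data (kinship
  ## contrasts identify h2 far better than an unrelated sample);
  ## log-likelihood never decreases; estimates invariant to a mean shift
  sim <- simulate_population(sim_config(n_founders = 120, n_generations = 2,
                                        n_snps = 600, n_qtl = 30, h2 = 0.3,
                                        seed = 16))
  Gf <- build_G(sim$geno)
  fit <- estimate_variance_components(sim$pheno$y, NULL, sim$pheno$animal, Gf)
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace$loglik) > -1e-7))
  expect_lt(abs(fit$h2 - 0.3), 0.12)
  fit2 <- estimate_variance_components(sim$pheno$y + 100, NULL,
                                       sim$pheno$animal, Gf)
  expect_equal(fit$sigma2, fit2$sigma2, tolerance = 1e-4)

  expect_error(
    estimate_variance_components(sim$pheno$y, NULL, sim$pheno$animal,
      { B <- -Gf; dimnames(B) <- dimnames(Gf); B }),
    "positive semidefinite")
})

test_that("two-component EM-REML splits equal contributions evenly", {
  g <- hwe_genotypes(250, 400, seed = 17)
  half <- seq_len(200)
  sub <- function(keep) genotypes(g$dosages[, keep, drop = FALSE],
                                  map = g$map[keep, , drop = FALSE],
                                  ids = g$ids, freqs = g$freqs[keep])
  G1 <- build_G(sub(half))
  G2 <- build_G(sub(setdiff(seq_len(400), half)))
  set.seed(18)
  a1 <- drop(t(chol(G1 + diag(1e-8, 250))) %*% rnorm(250)) * sqrt(0.3)
  a2 <- drop(t(chol(G2 + diag(1e-8, 250))) %*% rnorm(250)) * sqrt(0.3)
  y <- a1 + a2 + rnorm(250, 0, sqrt(0.4))
  fit <- estimate_variance_components(y, NULL, g$ids, list(G1, G2))
  ratio <- fit$sigma2[1] / fit$sigma2[2]
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 4)
  expect_true(all(diff(fit$trace$loglik) > -1e-7))
})
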