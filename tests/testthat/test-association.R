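# Shared toy: unrelated HWE genotypes with a fixed frequency base (G
# invertible), phenotype drawn from the GBLUP model with known components.
toy <- local({
  g <- hwe_genotypes(50, 100, seed = 21)
  G <- build_G(g)
  X <- cbind(1, stats::rnorm(50))
  y <- gblup_phenotype(G, X, c(1, -0.5), 0.4, 0.6, seed = 22)
  list(g = g, G = G, Ginv = chol2inv(chol(G)), X = X, y = y,
       s2a = 0.4, s2e = 0.6, cz = center_genotypes(g))
})

test_that("back-solving recovers the ridge SNP-BLUP solution", {
  ## zero breeding values give zero effects
  z0 <- backsolve_snp_effects(stats::setNames(rep(0, 50), toy$g$ids),
                              toy$g, toy$Ginv)
  expect_true(all(z0$effects == 0))

  res <- gwas_gblup(toy$y, toy$X, toy$g$ids, toy$g, toy$s2a, toy$s2e,
                    G = toy$G)
  ## ridge-regression oracle for Eq.-5-style SNP effects
  lam <- toy$s2e / (toy$s2a / toy$cz$k)
  Zc <- toy$cz$Z
  lhs <- rbind(cbind(crossprod(toy$X), crossprod(toy$X, Zc)),
               cbind(crossprod(Zc, toy$X), crossprod(Zc) + diag(lam, 100)))
  rhs <- c(crossprod(toy$X, toy$y), crossprod(Zc, toy$y))
  ghat <- solve(lhs, rhs)[-(1:2)]
  expect_equal(unname(res$effect[match(toy$g$map$snp, res$snp)]),
               unname(ghat), tolerance = 1e-8)
})

test_that("duplicated SNP columns receive identical effects", {
  M <- toy$g$dosages
  M[, 2] <- M[, 1]
  gd <- genotypes(M, ids = toy$g$ids,
                  freqs = replace(toy$g$freqs, 2, toy$g$freqs[1]))
  Gd <- build_G(gd)
  I22 <- diag(50); dimnames(I22) <- list(gd$ids, gd$ids)
  Gs <- blend_tune_G(Gd, I22, 0.99, tune = FALSE)
  res <- gwas_gblup(toy$y, toy$X, gd$ids, gd, toy$s2a, toy$s2e, G = Gs)
  i1 <- which(res$snp == gd$map$snp[1]); i2 <- which(res$snp == gd$map$snp[2])
  expect_equal(res$effect[i1], res$effect[i2], tolerance = 1e-10)
})

test_that("SNP-effect variances: no-information edge and scale equivariance", {
  ## C = G sigma2_a (zero information) nulls every variance
  v0 <- snp_effect_variances(toy$g, toy$G, toy$Ginv, toy$G * toy$s2a,
                             toy$s2a)
  expect_true(all(abs(v0) < 1e-10))
  r0 <- gwas_tests(stats::setNames(rep(0.1, 100), toy$g$map$snp), v0)
  expect_true(all(is.na(r0$t)))
  expect_true(all(r0$flag == "zero_var"))

  ## scaling phenotypes by c scales effects by c, variances by c^2,
  ## leaves t untouched
  r1 <- gwas_gblup(toy$y, toy$X, toy$g$ids, toy$g, toy$s2a, toy$s2e,
                   G = toy$G)
  cc <- 3.7
  r2 <- gwas_gblup(cc * toy$y, toy$X, toy$g$ids, toy$g,
                   cc^2 * toy$s2a, cc^2 * toy$s2e, G = toy$G)
  expect_equal(r2$effect, cc * r1$effect, tolerance = 1e-8)
  expect_equal(r2$se, cc * r1$se, tolerance = 1e-8)
  expect_equal(r2$t, r1$t, tolerance = 1e-8)
})

test_that("t statistics map to two-tailed Gaussian P-values", {
  r <- gwas_tests(c(a = 0, b = 0.5), c(1, 1 / (1.959964^2) * 0.25))
  expect_equal(r$p[r$snp == "a"], 1)
  expect_equal(abs(r$t[r$snp == "b"]), 1.959964, tolerance = 1e-6)
  expect_equal(r$p[r$snp == "b"], 0.05, tolerance = 1e-4)
})

test_that("back-solved and fixed-SNP tests agree with fixed effects present", {
  res <- gwas_gblup(toy$y, toy$X, toy$g$ids, toy$g, toy$s2a, toy$s2e,
                    G = toy$G)
  sc <- fixed_snp_scan(toy$y, toy$X, toy$g$ids, toy$G, toy$cz$Z,
                       toy$s2a, toy$s2e)
  ord <- match(sc$snp, res$snp)
  expect_lt(max(abs(res$t[ord] - sc$t)), 1e-6)

  ## single-SNP MME route (the honest Eq.-8 fit) agrees with the batch GLS
  for (j in c(3, 57)) {
    ft <- fixed_snp_test(toy$y, toy$X, toy$g$ids, kinship = toy$G,
                         z = stats::setNames(toy$cz$Z[, j], toy$g$ids),
                         sigma2_a = toy$s2a, sigma2_e = toy$s2e)
    expect_equal(ft$t, sc$t[j], tolerance = 1e-8)
    ## proportionality between the two parameterisations
    i <- which(res$snp == toy$g$map$snp[j])
    s2g <- toy$s2a / toy$cz$k
    expect_equal(res$effect[i], s2g / ft$se^2 * ft$b_hat, tolerance = 1e-6)
    expect_equal(res$se[i]^2, s2g^2 / ft$se^2, tolerance = 1e-6)
  }

  ## monomorphic and collinear candidates are rejected
  expect_error(fixed_snp_test(toy$y, toy$X, toy$g$ids, kinship = toy$G,
                              z = rep(1, 50), sigma2_a = toy$s2a,
                              sigma2_e = toy$s2e),
               "monomorphic")
})

test_that("a simulated large QTL attains the genome-wide minimum P-value", {
  g <- hwe_genotypes(120, 150, seed = 23)
  G <- build_G(g)
  set.seed(24)
  j <- 42
  zq <- g$dosages[, j] - 2 * g$freqs[j]
  y <- 1.2 * zq + gblup_phenotype(G, matrix(1, 120, 1), 0, 0.2, 0.8,
                                  seed = 25)
  res <- gwas_gblup(y, NULL, g$ids, g, 0.5, 0.5, G = G)
  expect_equal(res$snp[which.min(res$p)], g$map$snp[j])
})

test_that("multiple-testing control: bonferroni and PFP step-up", {
  p20 <- c(0.001, seq(0.01, 0.95, length.out = 19))
  mt <- multiple_testing(p20, "bonferroni", alpha = 0.05)
  expect_equal(mt$threshold, 0.0025)
  expect_equal(sum(mt$reject), sum(p20 < 0.0025))

  expect_equal(sum(multiple_testing(rep(1, 10), "pfp")$reject), 0)
  expect_equal(sum(multiple_testing(rep(1, 10), "bonferroni")$reject), 0)

  ## step-up rule against exhaustive enumeration
  p <- c(0.001, 0.01, 0.02, 0.8, 0.9)
  mt <- multiple_testing(p, "pfp", alpha = 0.05)
  m <- length(p); sp <- sort(p)
  feasible <- which(sapply(seq_len(m), function(k) m * sp[k] / k <= 0.05))
  kstar <- if (length(feasible)) max(feasible) else 0
  expect_equal(sum(mt$reject), kstar)
  expect_true(all(p[mt$reject] <= sp[kstar]))
  ## adjusted values match the standard step-up adjustment
  expect_equal(mt$p_adj, stats::p.adjust(p, "BH"))

  expect_error(multiple_testing(numeric(0)), "empty")
  expect_error(multiple_testing(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("QQ/Manhattan tables and singleton flags", {
  set.seed(26)
  m <- 1000
  res <- gwas_tests(stats::setNames(rnorm(m), paste0("s", 1:m)),
                    rep(1, m),
                    map = data.frame(snp = paste0("s", 1:m), chr = 1,
                                     pos = seq_len(m) * 1000))
  qm <- qq_manhattan_data(res)
  expect_gt(attr(qm$qq, "slope"), 0.9)
  expect_lt(attr(qm$qq, "slope"), 1.1)
  expect_equal(nrow(qm$manhattan), m)
  expect_true(!is.unsorted(qm$manhattan$cum_pos))

  ## single significant SNP with dull flanks is flagged as a singleton
  res2 <- res
  res2$p[500] <- 1e-12
  res2$p[-500] <- pmax(res2$p[-500], 0.01)
  qm2 <- qq_manhattan_data(res2, threshold = 1e-6)
  expect_true(res2$snp[500] %in% qm2$singletons)

  ## a supported peak (neighbour also strong) is not flagged
  res2$p[501] <- 1e-7
  qm3 <- qq_manhattan_data(res2, threshold = 1e-6)
  expect_false(res2$snp[500] %in% qm3$singletons)

  ## empty result gives empty tables
  qe <- qq_manhattan_data(res[0, ])
  expect_equal(nrow(qe$qq), 0)
  expect_equal(nrow(qe$manhattan), 0)
})

test_that("genotype QC removes by MAF, carrier count and HWE, flags Mendelian conflicts", {
  set.seed(27)
  n <- 60
  M <- cbind(
    rbinom(n, 2, 0.3),              # fine
    rbinom(n, 2, 0.02),             # low MAF
    c(rep(1, 9), rep(0, n - 9)),    # 9 carriers
    c(rep(0, 30), rep(2, 30))       # gross HWE violation
  )
  ## ensure the low-MAF column is truly below the cut
  M[, 2] <- c(rep(1, 2), rep(0, n - 2))
  g <- genotypes(M)
  qc <- genotype_qc(g, maf_cut = 0.05, carrier_min = 10, hwe_alpha = 1e-8)
  expect_true(qc$report$removed[2])
  expect_equal(qc$report$reason[2], "maf")
  expect_true(qc$report$removed[3])
  expect_true(qc$report$removed[4])
  expect_equal(qc$report$reason[4], "hwe")
  expect_false(qc$report$removed[1])
  expect_equal(nrow(qc$geno$map), 1)

  ## opposing homozygotes between offspring and parent
  ped <- pedigree(c("P", "O"), c("0", "P"), c("0", "0"))
  M2 <- rbind(P = c(0, 2), O = c(2, 2))
  g2 <- genotypes(M2, ids = c("P", "O"))
  qc2 <- genotype_qc(g2, maf_cut = 0, carrier_min = 0, hwe_alpha = 0,
                     ped = ped)
  expect_equal(nrow(qc2$mendelian_conflicts), 1)
  expect_equal(qc2$mendelian_conflicts$snp, g2$map$snp[1])

  expect_error(genotype_qc(g, maf_cut = 0.9), "all SNPs removed")
})

test_that("test statistics are invariant under affine phenotype transforms", {
  r1 <- gwas_gblup(toy$y, toy$X, toy$g$ids, toy$g, toy$s2a, toy$s2e,
                   G = toy$G)
  a <- 2.5; b <- -7
  r2 <- gwas_gblup(a * toy$y + b, toy$X, toy$g$ids, toy$g,
                   a^2 * toy$s2a, a^2 * toy$s2e, G = toy$G)
  expect_equal(r1$t, r2$t, tolerance = 1e-8)
  expect_equal(r1$p, r2$p, tolerance = 1e-8)
})
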