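#' Back-solve SNP effects from breeding values
#'
#' Converts animal-level breeding-value solutions into SNP-level effect
#' estimates: `g_hat = Z' G^-1 a_hat / k`, where `Z` is the 2p-centered
#' dosage matrix of the genotyped animals, `G` the (possibly blended)
#' genomic relationship matrix used in the evaluation, and
#' `k = 2 sum(p_i q_i)` its scale constant.
#'
#' @param a_hat named vector of breeding values for the genotyped animals.
#' @param geno [genotypes()] for the same animals.
#' @param G_inv inverse of the genomic relationship matrix used in the
#'   model, over the same animals (same order as `geno$ids`).
#' @param k scale constant; defaults to `2 sum(p q)` from `geno`.
#' @return list of class `snp_effects` with `effects` (named by SNP), `k`,
#'   and the centering frequencies.
#' @export
backsolve_snp_effects <- function(a_hat, geno, G_inv, k = NULL) {
  cz <- center_genotypes(geno)
  if (is.null(k)) k <- cz$k
  a_hat <- a_hat[geno$ids]
  if (anyNA(a_hat)) stop("a_hat must cover every genotyped animal")
  if (!all(dim(G_inv) == length(geno$ids)))
    stop("G_inv dimension does not match the genotyped animals")
  g <- as.numeric(crossprod(cz$Z, G_inv %*% a_hat)) / k
  structure(list(effects = stats::setNames(g, geno$map$snp), k = k,
                 freqs = geno$freqs),
            class = "snp_effects")
}

#' Sampling variances of back-solved SNP effects
#'
#' Computes `var(g_hat_i) = z_i' G^-1 (G sigma2_a - C) G^-1 z_i / k^2` for
#' every SNP, where `C` is the prediction-error (co)variance block of the
#' genotyped animals in trait-variance units. Only diagonal products are
#' formed (one matrix-vector pass per SNP, vectorised across SNPs). Small
#' negative values from floating-point cancellation are clipped to zero.
#'
#' @param geno [genotypes()] of the genotyped animals.
#' @param G the genomic relationship matrix used in the model.
#' @param G_inv its inverse.
#' @param C_block prediction-error covariance block over the genotyped
#'   animals (trait-variance units), from [extract_pev_block()].
#' @param sigma2_a additive genetic variance used in the model.
#' @param k scale constant; defaults to the value stored on `G`.
#' @return numeric vector of per-SNP variances (squared trait units).
#' @export
snp_effect_variances <- function(geno, G, G_inv, C_block, sigma2_a,
                                 k = NULL) {
  cz <- center_genotypes(geno)
  if (is.null(k)) k <- attr(G, "k")
  if (is.null(k)) k <- cz$k
  n <- length(geno$ids)
  if (!all(dim(C_block) == n) || !all(dim(G) == n))
    stop("C_block and G must both span the genotyped animals")
  mid <- G * sigma2_a - C_block
  Tmat <- G_inv %*% mid %*% G_inv
  TZ <- Tmat %*% cz$Z
  v <- colSums(cz$Z * TZ) / k^2
  neg <- v < 0
  if (any(v < -1e-12 * max(abs(v), 1)))
    warning("negative SNP-effect variances beyond tolerance were clipped to 0")
  v[neg] <- 0
  stats::setNames(v, geno$map$snp)
}

#' Per-SNP association tests from back-solved effects
#'
#' Forms `t_i = g_hat_i / sqrt(var(g_hat_i))` and two-tailed standard
#' Gaussian P-values `p_i = 2 (1 - Phi(|t_i|))`. SNPs with zero variance
#' (no information) get missing t and p and are flagged.
#'
#' @param effects `snp_effects` from [backsolve_snp_effects()], or a plain
#'   numeric vector.
#' @param variances per-SNP variances from [snp_effect_variances()].
#' @param map marker map (`snp`, `chr`, `pos`); optional.
#' @param freq per-SNP allele frequency to report; optional.
#' @param model provenance label stored on the result.
#' @return data.frame of class `gwas_result` with columns `snp`, `chr`,
#'   `pos`, `freq`, `effect`, `se`, `t`, `p`, `p_adj`, `flag`, sorted by
#'   (chr, pos).
#' @export
gwas_tests <- function(effects, variances, map = NULL, freq = NULL,
                       model = "GBLUP") {
  g <- if (inherits(effects, "snp_effects")) effects$effects else effects
  stopifnot(length(g) == length(variances))
  m <- length(g)
  if (is.null(map))
    map <- data.frame(snp = if (is.null(names(g))) paste0("snp", seq_len(m))
                            else names(g),
                      chr = 1L, pos = seq_len(m))
  if (is.null(freq)) {
    freq <- if (inherits(effects, "snp_effects")) effects$freqs
            else rep(NA_real_, m)
  }
  se <- sqrt(pmax(variances, 0))
  tt <- ifelse(se > 0, g / se, NA_real_)
  p <- 2 * stats::pnorm(abs(tt), lower.tail = FALSE)
  res <- data.frame(snp = map$snp, chr = map$chr, pos = map$pos,
                    freq = unname(freq), effect = unname(g), se = unname(se),
                    t = unname(tt), p = unname(p), p_adj = NA_real_,
                    flag = ifelse(se > 0, "", "zero_var"),
                    stringsAsFactors = FALSE)
  res <- res[order(res$chr, res$pos), ]
  rownames(res) <- NULL
  class(res) <- c("gwas_result", "data.frame")
  attr(res, "model") <- model
  res
}

#' GBLUP genome-wide association scan
#'
#' Runs the full back-solving pipeline for genotyped, phenotyped animals:
#' assembles the GBLUP mixed-model equations with `K = G`, solves them,
#' extracts the prediction-error covariance block, back-solves SNP effects
#' and their variances, and returns the per-SNP tests.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix (`NULL` = intercept only).
#' @param animal animal id per record (must all be genotyped).
#' @param geno [genotypes()] object.
#' @param sigma2_a,sigma2_e variance components (e.g. from
#'   [estimate_variance_components()]).
#' @param G optional prebuilt genomic relationship matrix; by default
#'   [build_G()] on `geno`. Supply a blended matrix when observed
#'   frequencies make G singular.
#' @return A `gwas_result` data.frame; the solved `mme` system and the
#'   breeding values are attached as attributes `system` and `a_hat`.
#' @export
gwas_gblup <- function(y, X = NULL, animal = NULL, geno, sigma2_a, sigma2_e,
                       G = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  if (is.null(animal)) animal <- geno$ids
  if (is.null(G)) G <- build_G(geno)
  Ginv <- tryCatch(chol2inv(chol(G)), error = function(e)
    stop("G is singular; blend it with A22 (or identity) via blend_tune_G()"))
  if (max(abs(G %*% Ginv[, 1] - c(1, rep(0, nrow(G) - 1)))) > 1e-6)
    stop("G is numerically singular; blend it via blend_tune_G() ",
         "before running the scan")
  dimnames(Ginv) <- dimnames(G)
  sys <- assemble_mme(y, X, animal, Ginv, sigma2_a, sigma2_e)
  sys <- solve_mme(sys)
  a_hat <- sys$u[[1]]
  C <- extract_pev_block(sys, geno$ids)
  eff <- backsolve_snp_effects(a_hat, geno, Ginv, k = attr(G, "k"))
  v <- snp_effect_variances(geno, G, Ginv, C, sigma2_a, k = attr(G, "k"))
  res <- gwas_tests(eff, v, map = geno$map, freq = geno$freqs,
                    model = "GBLUP")
  attr(res, "system") <- sys
  attr(res, "a_hat") <- a_hat
  res
}

#' Single-step GBLUP genome-wide association scan
#'
#' Runs the six-step single-step association algorithm: build the ssGBLUP
#' equations with H-inverse (pedigree plus blended genomic information),
#' solve, extract the prediction-error covariance block of the genotyped
#' animals, back-solve SNP effects with the blended G, compute their
#' variances, and test. Phenotypes of ungenotyped animals contribute
#' through the pedigree.
#'
#' @param y,X,animal records over any pedigree animals.
#' @param ped [pedigree()] containing every genotyped animal.
#' @param geno [genotypes()] of the genotyped subset.
#' @param sigma2_a,sigma2_e variance components.
#' @param blend_weight,tune passed to [blend_tune_G()].
#' @return A `gwas_result` data.frame with attributes `system`, `a_hat`
#'   (all animals) as for [gwas_gblup()].
#' @export
gwas_ssgblup <- function(y, X = NULL, animal, ped, geno, sigma2_a, sigma2_e,
                         blend_weight = 0.95, tune = TRUE) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  A <- build_A(ped)
  Ainv <- build_A_inverse(ped, F = attr(A, "F"))
  A22 <- extract_A22(A, geno$ids)
  G <- build_G(geno)
  Gs <- blend_tune_G(G, A22, blend_weight = blend_weight, tune = tune)
  Hinv <- build_H_inverse(Ainv, Gs, A22)
  sys <- assemble_mme(y, X, animal, Hinv, sigma2_a, sigma2_e)
  sys <- solve_mme(sys)
  a_hat <- sys$u[[1]]
  C22 <- extract_pev_block(sys, geno$ids)
  Gsinv <- chol2inv(chol(Gs))
  dimnames(Gsinv) <- dimnames(Gs)
  eff <- backsolve_snp_effects(a_hat[geno$ids], geno, Gsinv, k = attr(G, "k"))
  v <- snp_effect_variances(geno, Gs, Gsinv, C22, sigma2_a, k = attr(G, "k"))
  res <- gwas_tests(eff, v, map = geno$map, freq = geno$freqs,
                    model = "ssGBLUP")
  attr(res, "system") <- sys
  attr(res, "a_hat") <- a_hat
  res
}

#' Fixed-SNP mixed-model association test (EMMAX-style)
#'
#' Tests one candidate SNP as a fixed covariate in the animal model,
#' reusing the null-model variance components: the mixed-model equations of
#' the augmented model are solved at the null variance ratio and the test
#' is `t = b_hat / se(b_hat)`. Mathematically equivalent to the
#' back-solving test of [gwas_tests()] when `K = G = Z Z'/k` contains the
#' tested SNP.
#'
#' @param y,X,animal as in [assemble_mme()].
#' @param kinship kinship matrix K (id dimnames); its inverse is taken
#'   internally (pass `kinship_inverse` to reuse one).
#' @param z centered dosage vector for the candidate SNP, named by (or
#'   ordered as) the kinship ids.
#' @param sigma2_a,sigma2_e null-model variance components.
#' @param kinship_inverse optional precomputed inverse.
#' @param snp label used in error messages.
#' @return list with `b_hat`, `se`, `t`, `p`.
#' @export
fixed_snp_test <- function(y, X = NULL, animal, kinship = NULL, z,
                           sigma2_a, sigma2_e, kinship_inverse = NULL,
                           snp = "snp") {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (is.null(kinship_inverse)) {
    kinship_inverse <- chol2inv(chol(kinship))
    dimnames(kinship_inverse) <- dimnames(kinship)
  }
  ids <- rownames(kinship_inverse)
  zrec <- if (!is.null(names(z))) z[as.character(animal)]
          else z[match(as.character(animal), ids)]
  if (anyNA(zrec)) stop("SNP dosages missing for some records")
  if (stats::sd(zrec) == 0)
    stop("candidate SNP ", snp, " is constant across records (monomorphic)")
  Xa <- cbind(X, snp = zrec)
  sys <- assemble_mme(y, Xa, animal, kinship_inverse, sigma2_a, sigma2_e)
  j <- ncol(Xa)
  if (j %in% sys$dropped_fixed)
    stop("candidate SNP ", snp, " is collinear with the fixed effects")
  sys <- solve_mme(sys)
  b <- sys$beta[j]
  R <- sys$chol
  e <- numeric(nrow(sys$lhs)); e[j] <- 1
  cj <- backsolve(R, forwardsolve(t(R), e))[j]
  se <- sqrt(cj * sigma2_e)
  tt <- b / se
  list(b_hat = unname(b), se = unname(se), t = unname(tt),
       p = 2 * stats::pnorm(abs(tt), lower.tail = FALSE))
}

#' Batch fixed-SNP scan via generalised least squares
#'
#' The EMMAX test for every SNP at once: with
#' `V = K sigma2_a + I sigma2_e` over the records and
#' `P = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1`, each SNP's fixed-effect
#' estimate is `b_hat = z'Py / z'Pz` with `se = 1/sqrt(z'Pz)`. This is an
#' algebraically independent route to the same statistics as the
#' back-solved test and is used as its oracle in the test-suite.
#'
#' @param y,X,animal as in [fixed_snp_test()].
#' @param kinship kinship matrix over ids.
#' @param Z centered dosage matrix (animals x SNPs), rows named/ordered as
#'   the kinship ids.
#' @param sigma2_a,sigma2_e null variance components.
#' @return data.frame with `snp`, `b_hat`, `se`, `t`, `p`.
#' @export
fixed_snp_scan <- function(y, X = NULL, animal, kinship, Z, sigma2_a,
                           sigma2_e) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  ids <- rownames(kinship)
  pos <- match(as.character(animal), ids)
  if (anyNA(pos)) stop("record animal(s) missing from kinship")
  V <- kinship[pos, pos, drop = FALSE] * sigma2_a + diag(sigma2_e, n)
  Vinv <- chol2inv(chol(V))
  M <- Vinv %*% X
  XtVX <- crossprod(X, M)
  P <- Vinv - M %*% solve(XtVX, t(M))
  Py <- as.numeric(P %*% y)
  Zr <- Z[pos, , drop = FALSE]
  zPz <- colSums(Zr * (P %*% Zr))
  ## z'Pz is nonnegative in exact arithmetic; clip rounding noise and mark
  ## SNPs with no usable variation in these records
  zPz[zPz < 0] <- 0
  num <- as.numeric(crossprod(Zr, Py))
  ok <- zPz > 0
  b <- ifelse(ok, num / zPz, NA_real_)
  se <- ifelse(ok, 1 / sqrt(zPz), NA_real_)
  tt <- ifelse(ok, num / sqrt(zPz), NA_real_)
  data.frame(snp = colnames(Z) %||% paste0("snp", seq_along(b)),
             b_hat = b, se = se, t = tt,
             p = 2 * stats::pnorm(abs(tt), lower.tail = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
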