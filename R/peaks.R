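#' Detect association peaks in a GWAS result
#'
#' Greedy scan for local P-value minima below a significance threshold:
#' SNPs are visited in order of increasing P-value and accepted as peaks
#' when at least `min_separation_bp` away (same chromosome) from every
#' previously accepted peak.
#'
#' @param result a `gwas_result` data.frame (sorted by chr, pos).
#' @param threshold raw P-value threshold.
#' @param min_separation_bp minimum distance between peaks; default 1e6.
#' @return data.frame with `peak_id`, `snp`, `chr`, `pos`, `p` (possibly
#'   zero rows).
#' @export
detect_peaks <- function(result, threshold, min_separation_bp = 1e6) {
  cand <- which(!is.na(result$p) & result$p < threshold)
  cand <- cand[order(result$p[cand], result$chr[cand], result$pos[cand])]
  keep <- integer(0)
  for (i in cand) {
    if (!length(keep) ||
        all(result$chr[keep] != result$chr[i] |
              abs(result$pos[keep] - result$pos[i]) >= min_separation_bp))
      keep <- c(keep, i)
  }
  keep <- keep[order(result$chr[keep], result$pos[keep])]
  data.frame(peak_id = seq_along(keep), snp = result$snp[keep],
             chr = result$chr[keep], pos = result$pos[keep],
             p = result$p[keep])
}

#' Jackknife confidence interval for a QTL peak position
#'
#' Repeatedly splits the phenotyped records into two random halves,
#' re-runs the association scan on each half restricted to the SNPs of the
#' peak region, and records the two peak positions `v1k`, `v2k`. The
#' standard error of the peak position is
#' `se = sqrt( sum_k (v1k - v2k)^2 / (4K) )` and the 95% confidence
#' interval is `v +/- z_.975 * se` with the 97.5th standard-Gaussian
#' percentile (1.96). Halves are scored with the fixed-SNP mixed-model
#' scan, using the genome-wide genomic relationship matrix (restricted to
#' each half's animals) to control for background relatedness.
#'
#' @param y,X,animal phenotype records (animals must be genotyped).
#' @param geno [genotypes()] object.
#' @param region list or vector with `chr`, `start`, `end` in bp.
#' @param sigma2_a,sigma2_e variance components (reused for every half).
#' @param K number of jackknife iterations; default 30.
#' @param seed random seed (mandatory: the splits are random).
#' @param v peak position from the full-data analysis; when `NULL` it is
#'   computed from the full data with the same regional scan.
#' @param G optional prebuilt genome-wide relationship matrix.
#' @param min_records minimum records per half; an iteration whose half
#'   falls below it is resampled (logged in the report).
#' @return list of class `peak_ci` with `v`, `se`, `ci` (length 2), `K`,
#'   `z` (the 1.96 multiplier), `splits` (data.frame `v1`, `v2`) and
#'   `resampled` (count of discarded iterations).
#' @export
jackknife_peak_ci <- function(y, X = NULL, animal = NULL, geno, region,
                              sigma2_a, sigma2_e, K = 30, seed,
                              v = NULL, G = NULL, min_records = 20) {
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  stopifnot(K >= 1)
  set.seed(seed)
  n <- length(y)
  if (is.null(animal)) animal <- geno$ids
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  region <- as.list(region)
  inside <- geno$map$chr == region$chr & geno$map$pos >= region$start &
    geno$map$pos <= region$end
  if (!any(inside)) stop("region contains no SNPs")
  if (is.null(G)) G <- build_G(geno)
  cz <- center_genotypes(geno)
  Zreg <- cz$Z[, inside, drop = FALSE]
  pos_reg <- geno$map$pos[inside]
  scan_half <- function(rows) {
    sc <- fixed_snp_scan(y[rows], X[rows, , drop = FALSE], animal[rows],
                         kinship = G, Z = Zreg,
                         sigma2_a = sigma2_a, sigma2_e = sigma2_e)
    o <- order(sc$p, pos_reg)  # ties broken by smaller coordinate
    pos_reg[o[1]]
  }
  if (is.null(v)) v <- scan_half(seq_len(n))
  v1 <- v2 <- numeric(K)
  resampled <- 0L
  for (k in seq_len(K)) {
    repeat {
      half <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (sum(half) >= min_records && sum(!half) >= min_records) break
      resampled <- resampled + 1L
      if (resampled > 100 * K)
        stop("could not draw halves with at least ", min_records,
             " records each")
    }
    v1[k] <- scan_half(which(half))
    v2[k] <- scan_half(which(!half))
  }
  se <- sqrt(sum((v1 - v2)^2) / (4 * K))
  z <- stats::qnorm(0.975)
  structure(list(v = v, se = se, ci = c(v - z * se, v + z * se),
                 K = K, z = z, splits = data.frame(v1 = v1, v2 = v2),
                 resampled = resampled),
            class = "peak_ci")
}

#' @exportS3Method base::print
print.peak_ci <- function(x, ...) {
  cat(sprintf("peak at %g bp, se %.1f bp, 95%% CI [%.1f, %.1f] (K = %d)\n",
              x$v, x$se, x$ci[1], x$ci[2], x$K))
  invisible(x)
}

#' Proportion of variance explained by a QTL window
#'
#' Builds a genomic relationship matrix `G_w` from the SNPs inside the
#' window and `G_-w` from all remaining SNPs, fits the two-component
#' animal model `y = X beta + a_-w + a_w + e` by EM-REML, and returns the
#' window heritability
#' `h2_w = sigma2_w / (sigma2_-w + sigma2_w + sigma2_e)`. The window
#' matrix is used unblended (it is fitted jointly with the genome-wide
#' component); the complement matrix is blended with the identity to stay
#' invertible-free of the observed-frequency singularity.
#'
#' @param y,X,animal phenotype records over genotyped animals.
#' @param geno [genotypes()] object.
#' @param window list or vector with `chr`, `start`, `end` in bp.
#' @param blend_weight blending weight for the complement matrix.
#' @param ... further arguments to [estimate_variance_components()].
#' @return list of class `window_variance` with `window`, `n_snps_window`,
#'   `sigma2_w`, `sigma2_nw`, `sigma2_e`, `h2_w`, and the REML `fit`.
#' @export
window_variance <- function(y, X = NULL, animal = NULL, geno, window,
                            blend_weight = 0.95, ...) {
  window <- as.list(window)
  if (is.null(animal)) animal <- geno$ids
  inside <- geno$map$chr == window$chr & geno$map$pos >= window$start &
    geno$map$pos <= window$end
  if (!any(inside)) stop("empty window: no SNPs inside")
  if (sum(!inside) < 2) stop("complement must contain at least 2 SNPs")
  sub_geno <- function(keep) {
    genotypes(geno$dosages[, keep, drop = FALSE],
              map = geno$map[keep, , drop = FALSE], ids = geno$ids,
              freqs = if (geno$freq_source == "fixed") geno$freqs[keep]
                      else NULL)
  }
  Gw <- build_G(sub_geno(inside))
  Gnw <- build_G(sub_geno(!inside))
  I22 <- diag(nrow(Gnw)); dimnames(I22) <- dimnames(Gnw)
  Gnw <- blend_tune_G(Gnw, I22, blend_weight = blend_weight, tune = FALSE)
  fit <- estimate_variance_components(y, X, animal,
                                      kinship = list(w = Gw, nw = Gnw), ...)
  s <- fit$sigma2
  structure(list(window = window, n_snps_window = sum(inside),
                 sigma2_w = unname(s[1]), sigma2_nw = unname(s[2]),
                 sigma2_e = unname(s["e"]),
                 h2_w = unname(s[1] / sum(s)), fit = fit),
            class = "window_variance")
}

#' Variance explained by a fixed SNP effect
#'
#' The quick approximation `sigma2_i = var(z_i) * b_hat_i^2`, with
#' `var(z_i)` the sample variance of the SNP's centered dosages and
#' `b_hat_i` its fixed-effect estimate from [fixed_snp_test()]. A gross
#' approximation that tends to overestimate the variance tagged by the
#' peak; useful for ranking QTLs, not for reporting heritabilities.
#'
#' @param b_hat fixed SNP effect estimate.
#' @param z dosage (or centered dosage) vector of the SNP.
#' @return The approximated variance (single number).
#' @export
fixed_snp_variance <- function(b_hat, z) {
  stats::var(as.numeric(z)) * b_hat^2
}
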