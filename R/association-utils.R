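#' Multiple-testing control for GWAS P-values
#'
#' Two procedures: classical Bonferroni (reject `p < alpha / m`) and the
#' proportion-of-false-positives (PFP) step-up rule, which rejects the k*
#' smallest P-values where `k* = max{k : m p_(k) / k <= alpha}` — the
#' estimated expected proportion of false positives among the rejections
#' is then at most `alpha`. PFP is the recommended default for the highly
#' correlated tests typical of dense SNP panels, where Bonferroni is
#' overly conservative.
#'
#' @param p numeric vector of P-values in `[0, 1]` (`NA` allowed; never
#'   rejected, counted in m).
#' @param method `"pfp"` (default) or `"bonferroni"`.
#' @param alpha target level; default 0.05.
#' @return list with `method`, `alpha`, `threshold` (largest rejected
#'   per-test P-value, or the nominal per-test cutoff for Bonferroni),
#'   `reject` (logical vector) and `p_adj` (adjusted P-values, `min 1`).
#' @export
multiple_testing <- function(p, method = c("pfp", "bonferroni"),
                             alpha = 0.05) {
  method <- match.arg(method)
  if (length(p) == 0) stop("empty P-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("P-values must lie in [0, 1]")
  m <- length(p)
  if (method == "bonferroni") {
    p_adj <- pmin(1, p * m)
    thr <- alpha / m
    reject <- !is.na(p) & p < thr
  } else {
    o <- order(p, na.last = TRUE)
    ranked <- p[o]
    k <- seq_len(m)
    crit <- m * ranked / k
    p_adj_sorted <- rev(cummin(rev(pmin(1, crit))))
    p_adj <- numeric(m)
    p_adj[o] <- p_adj_sorted
    p_adj[is.na(p)] <- NA_real_
    ok <- which(!is.na(crit) & crit <= alpha)
    kstar <- if (length(ok)) max(ok) else 0L
    reject <- rep(FALSE, m)
    if (kstar > 0) reject[o[seq_len(kstar)]] <- TRUE
    thr <- if (kstar > 0) ranked[kstar] else 0
  }
  list(method = method, alpha = alpha, threshold = thr, reject = reject,
       p_adj = p_adj)
}

#' Adjust a GWAS result for multiple testing
#'
#' Fills the `p_adj` column of a `gwas_result` and records the method.
#'
#' @param result a `gwas_result` data.frame.
#' @param method,alpha passed to [multiple_testing()].
#' @return The result with `p_adj` filled and attributes `mt_method`,
#'   `mt_threshold`.
#' @export
adjust_gwas <- function(result, method = c("pfp", "bonferroni"),
                        alpha = 0.05) {
  mt <- multiple_testing(result$p, method = method, alpha = alpha)
  result$p_adj <- mt$p_adj
  attr(result, "mt_method") <- mt$method
  attr(result, "mt_threshold") <- mt$threshold
  result
}

#' QQ and Manhattan plotting tables
#'
#' Returns the data behind the two standard GWAS diagnostic plots, plus a
#' singleton-signal flag: a significant SNP with no neighbouring SNP
#' lending support (no other SNP within `neighbor_bp` on the same
#' chromosome with `p < support_p`) is likely an artifact rather than a
#' causal-variant cluster in LD.
#'
#' @param result a `gwas_result` data.frame.
#' @param threshold significance threshold on raw P-values used for the
#'   singleton flag; default `0.05 / m` (Bonferroni at 0.05).
#' @param neighbor_bp window for neighbour support; default 1e6.
#' @param support_p P-value a neighbour must beat to count as support;
#'   default `min(1e-3, 100 * threshold)`.
#' @return list with `qq` (data.frame `expected`, `observed`, -log10
#'   scale, and `slope` attribute from their least-squares fit through the
#'   origin-intercept line), `manhattan` (`snp`, `chr`, `pos`, `cum_pos`,
#'   `neglog10p`) and `singletons` (character vector of flagged SNP ids).
#' @export
qq_manhattan_data <- function(result, threshold = NULL, neighbor_bp = 1e6,
                              support_p = NULL) {
  m <- nrow(result)
  if (m == 0) {
    return(list(qq = data.frame(expected = numeric(0), observed = numeric(0)),
                manhattan = data.frame(snp = character(0), chr = numeric(0),
                                       pos = numeric(0), cum_pos = numeric(0),
                                       neglog10p = numeric(0)),
                singletons = character(0)))
  }
  if (is.null(threshold)) threshold <- 0.05 / m
  if (is.null(support_p)) support_p <- min(1e-3, 100 * threshold)
  p <- result$p
  ok <- !is.na(p)
  po <- sort(p[ok])
  qq <- data.frame(expected = -log10((seq_along(po) - 0.5) / length(po)),
                   observed = -log10(pmax(po, 1e-300)))
  fit <- stats::lm(observed ~ expected, data = qq)
  attr(qq, "slope") <- unname(stats::coef(fit)[2])
  ## cumulative genome coordinate
  chrs <- unique(result$chr)
  offset <- stats::setNames(numeric(length(chrs)), chrs)
  run <- 0
  for (ch in chrs) {
    offset[as.character(ch)] <- run
    run <- run + max(result$pos[result$chr == ch]) + 1
  }
  man <- data.frame(snp = result$snp, chr = result$chr, pos = result$pos,
                    cum_pos = result$pos + offset[as.character(result$chr)],
                    neglog10p = -log10(pmax(p, 1e-300)))
  sig <- which(ok & p < threshold)
  singletons <- character(0)
  for (i in sig) {
    near <- which(result$chr == result$chr[i] &
                    abs(result$pos - result$pos[i]) <= neighbor_bp)
    near <- setdiff(near, i)
    if (!length(near) || all(is.na(p[near]) | p[near] >= support_p))
      singletons <- c(singletons, result$snp[i])
  }
  list(qq = qq, manhattan = man, singletons = singletons)
}

#' Genotype quality control
#'
#' Removes SNPs failing minor-allele-frequency, minor-allele-carrier-count
#' or Hardy-Weinberg-equilibrium filters, and (when a pedigree is given)
#' flags trio Mendelian conflicts: SNPs where an animal and one of its
#' genotyped parents are opposing homozygotes. Small samples should use a
#' stringent MAF cutoff so that enough animals carry the minor allele.
#'
#' @param geno a [genotypes()] object.
#' @param maf_cut minimum minor allele frequency; default 0.05.
#' @param carrier_min minimum number of animals carrying at least one copy
#'   of the minor allele; default 10.
#' @param hwe_alpha chi-square HWE test level; default 1e-8.
#' @param ped optional [pedigree()] for Mendelian checks.
#' @return list with `geno` (filtered), `report` (per-SNP data.frame with
#'   `maf`, `carriers`, `hwe_p`, `removed`, `reason`) and
#'   `mendelian_conflicts` (data.frame `snp`, `animal`, `parent`).
#' @export
genotype_qc <- function(geno, maf_cut = 0.05, carrier_min = 10,
                        hwe_alpha = 1e-8, ped = NULL) {
  M <- geno$dosages
  n_obs <- colSums(!is.na(M))
  pobs <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(pobs, 1 - pobs)
  minor_is_counted <- pobs <= 0.5
  carriers <- sapply(seq_len(ncol(M)), function(j) {
    x <- M[, j]
    if (minor_is_counted[j]) sum(x > 0, na.rm = TRUE)
    else sum(x < 2, na.rm = TRUE)
  })
  hwe_p <- sapply(seq_len(ncol(M)), function(j) {
    x <- M[, j]
    obs <- c(sum(x == 0, na.rm = TRUE), sum(x == 1, na.rm = TRUE),
             sum(x == 2, na.rm = TRUE))
    nn <- sum(obs)
    pj <- (2 * obs[3] + obs[2]) / (2 * nn)
    expd <- nn * c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    keep <- expd > 0
    stat <- sum((obs[keep] - expd[keep])^2 / expd[keep])
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  })
  reason <- character(ncol(M))
  reason[hwe_p < hwe_alpha] <- "hwe"
  reason[carriers < carrier_min] <- "carriers"
  reason[maf < maf_cut] <- "maf"
  removed <- reason != ""
  report <- data.frame(snp = geno$map$snp, maf = maf, carriers = carriers,
                       hwe_p = hwe_p, removed = removed, reason = reason)
  if (all(removed))
    stop("all SNPs removed by QC; relax the thresholds")
  conflicts <- data.frame(snp = character(0), animal = character(0),
                          parent = character(0))
  if (!is.null(ped)) {
    gidx <- stats::setNames(match(ped$id, geno$ids), ped$id)
    for (i in seq_len(ped$n)) {
      ci <- gidx[ped$id[i]]
      if (is.na(ci)) next
      for (par in c(ped$sire[i], ped$dam[i])) {
        if (par == 0) next
        pi <- gidx[ped$id[par]]
        if (is.na(pi)) next
        opp <- which((M[ci, ] == 0 & M[pi, ] == 2) |
                       (M[ci, ] == 2 & M[pi, ] == 0))
        if (length(opp))
          conflicts <- rbind(conflicts, data.frame(
            snp = geno$map$snp[opp], animal = ped$id[i],
            parent = ped$id[par]))
      }
    }
  }
  keep <- which(!removed)
  fgeno <- genotypes(M[, keep, drop = FALSE],
                     map = geno$map[keep, , drop = FALSE],
                     ids = geno$ids,
                     freqs = if (geno$freq_source == "fixed")
                       geno$freqs[keep] else NULL)
  list(geno = fgeno, report = report, mendelian_conflicts = conflicts)
}
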