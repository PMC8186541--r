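#' Genotype matrix container
#'
#' Holds additive dosages (counts of the counted allele, 0/1/2, `NA`
#' allowed), the marker map, and the allele-frequency base used for
#' centering. The map must be sorted by (chromosome, position); positions
#' are stored 1-based as read.
#'
#' @param dosages numeric matrix, animals x SNPs; dimnames optional.
#' @param map data.frame with columns `snp`, `chr`, `pos` (base pairs).
#'   Defaults to a single chromosome with unit spacing.
#' @param ids animal identifiers; default rownames or `paste0("id", i)`.
#' @param freqs optional fixed per-SNP frequencies of the counted allele to
#'   use as centering base; when `NULL` observed frequencies are used.
#' @return Object of class `genotypes`: list with `dosages`, `map`, `ids`,
#'   `freqs` (the centering base actually in force) and `freq_source`
#'   (`"observed"` or `"fixed"`).
#' @export
genotypes <- function(dosages, map = NULL, ids = NULL, freqs = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (any(!is.na(dosages) & !(dosages %in% 0:2)))
    stop("dosages must be 0, 1, 2 or NA")
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(ids)) ids <- rownames(dosages)
  if (is.null(ids)) ids <- paste0("id", seq_len(n))
  if (is.null(map)) {
    snp <- colnames(dosages)
    if (is.null(snp)) snp <- paste0("snp", seq_len(m))
    map <- data.frame(snp = snp, chr = rep(1L, m), pos = seq_len(m))
  }
  stopifnot(all(c("snp", "chr", "pos") %in% names(map)), nrow(map) == m)
  o <- order(map$chr, map$pos)
  if (!identical(o, seq_len(m))) {
    map <- map[o, , drop = FALSE]
    dosages <- dosages[, o, drop = FALSE]
    if (!is.null(freqs)) freqs <- freqs[o]
  }
  rownames(dosages) <- ids
  colnames(dosages) <- map$snp
  obs <- colMeans(dosages, na.rm = TRUE) / 2
  if (is.null(freqs)) {
    freqs <- obs
    freq_source <- "observed"
  } else {
    stopifnot(length(freqs) == m)
    freq_source <- "fixed"
  }
  structure(list(dosages = dosages, map = map, ids = ids,
                 freqs = unname(freqs), freq_source = freq_source),
            class = "genotypes")
}

#' @exportS3Method base::print
print.genotypes <- function(x, ...) {
  cat("genotypes:", length(x$ids), "animals x", nrow(x$map), "SNPs on",
      length(unique(x$map$chr)), "chromosome(s);",
      x$freq_source, "allele frequencies\n")
  invisible(x)
}

#' @export
dim.genotypes <- function(x) dim(x$dosages)

#' Centered genotype matrix Z and scale constant k
#'
#' Missing dosages are imputed to `2 p_i` (so they center to zero), then
#' each column is centered by `2 p_i`. The scale constant is
#' `k = 2 * sum(p_i * q_i)`.
#'
#' @param geno a [genotypes()] object.
#' @return list with `Z` (n x m matrix) and `k`.
#' @export
center_genotypes <- function(geno) {
  stopifnot(inherits(geno, "genotypes"))
  p <- geno$freqs
  Z <- geno$dosages
  if (anyNA(Z)) {
    for (j in which(colSums(is.na(Z)) > 0))
      Z[is.na(Z[, j]), j] <- 2 * p[j]
  }
  Z <- sweep(Z, 2, 2 * p)
  list(Z = Z, k = 2 * sum(p * (1 - p)))
}

#' Genomic relationship matrix (VanRaden)
#'
#' `G = Z Z' / k` with `Z` the 2p-centered dosage matrix and the single
#' scale constant `k = 2 * sum(p_i q_i)`; this choice keeps the constant
#' `1/k` of the SNP-effect back-solving step consistent with G. With
#' observed frequencies the mean diagonal is close to 1 under
#' Hardy-Weinberg proportions. A per-SNP-standardized variant
#' (`scaling = "per_snp"`) divides each column by `sqrt(2 p_i q_i)` and
#' scales by the SNP count instead.
#'
#' @param geno a [genotypes()] object (its `freqs` are the centering base).
#' @param scaling `"single_constant"` (default) or `"per_snp"`.
#' @return Symmetric n x n matrix with attributes `k`, `kind = "G"` and
#'   `scaling`.
#' @export
build_G <- function(geno, scaling = c("single_constant", "per_snp")) {
  scaling <- match.arg(scaling)
  if (length(geno$ids) < 2) stop("need at least 2 animals")
  mono <- geno$freqs <= 0 | geno$freqs >= 1
  if (any(mono))
    stop(sum(mono), " monomorphic SNP(s) present; run genotype_qc() first")
  allmiss <- rowSums(!is.na(geno$dosages)) == 0
  if (any(allmiss))
    stop("animal(s) with all dosages missing: ",
         paste(geno$ids[allmiss], collapse = ", "))
  cz <- center_genotypes(geno)
  if (scaling == "single_constant") {
    G <- tcrossprod(cz$Z) / cz$k
  } else {
    p <- geno$freqs
    Zs <- sweep(cz$Z, 2, sqrt(2 * p * (1 - p)), "/")
    G <- tcrossprod(Zs) / ncol(Zs)
  }
  dimnames(G) <- list(geno$ids, geno$ids)
  structure(G, k = cz$k, kind = "G", scaling = scaling)
}

#' Blend and tune the genomic relationship matrix
#'
#' Optionally rescales G (tuning) so that its mean diagonal and mean
#' off-diagonal match those of the pedigree block A22, by solving for
#' `alpha`, `beta` in `G_tuned = alpha + beta * G`, then blends:
#' `G* = w * G_tuned + (1 - w) * A22`. Blending with `w < 1` removes the
#' singularity of G that arises with observed allele frequencies (the
#' all-ones vector is then in the null space of Z').
#'
#' @param G matrix from [build_G()].
#' @param A22 pedigree block over the same animals ([extract_A22()]); for a
#'   purely genotyped analysis with no pedigree an identity matrix is the
#'   conventional stand-in.
#' @param blend_weight w in (0, 1]; default 0.95.
#' @param tune logical; default TRUE.
#' @return Blended matrix with attributes `blend_weight`, `tune_alpha`,
#'   `tune_beta`, `k` (carried through), `kind = "G_blended"`.
#' @export
blend_tune_G <- function(G, A22, blend_weight = 0.95, tune = TRUE) {
  if (!is.null(rownames(G)) && !is.null(rownames(A22)) &&
      !identical(rownames(G), rownames(A22)))
    stop("G and A22 must cover the same animals in the same order")
  if (!all(dim(G) == dim(A22)))
    stop("G and A22 must cover the same animals in the same order")
  if (blend_weight <= 0 || blend_weight > 1)
    stop("blend_weight must be in (0, 1]")
  n <- nrow(G)
  alpha <- 0; beta <- 1
  Gt <- G
  if (tune && n > 1) {
    off <- row(G) != col(G)
    ## mean(diag) and mean(offdiag) of alpha + beta G match A22
    md_g <- mean(diag(G)); mo_g <- mean(G[off])
    md_a <- mean(diag(A22)); mo_a <- mean(A22[off])
    if (abs(md_g - mo_g) < 1e-12) {
      warning("G diagonal and off-diagonal means coincide; tuning skipped")
    } else {
      beta <- (md_a - mo_a) / (md_g - mo_g)
      alpha <- md_a - beta * md_g
      Gt <- alpha + beta * G
    }
  }
  Gs <- blend_weight * Gt + (1 - blend_weight) * A22
  structure(Gs, blend_weight = blend_weight, tune_alpha = alpha,
            tune_beta = beta, k = attr(G, "k"), kind = "G_blended")
}

#' Inverse of the single-step relationship matrix H
#'
#' `H^-1 = A^-1 + [0 0; 0 G*^-1 - A22^-1]` over the full pedigree, with the
#' nonzero block on the genotyped animals. With no genotyped animals the
#' result is A-inverse itself.
#'
#' @param A_inv sparse pedigree inverse ([build_A_inverse()]).
#' @param G_blended blended genomic matrix over the genotyped animals.
#' @param A22 pedigree block over the genotyped animals.
#' @return Sparse symmetric matrix over all pedigree animals, attribute
#'   `genotyped_ids`.
#' @export
build_H_inverse <- function(A_inv, G_blended, A22 = NULL) {
  ids <- rownames(A_inv)
  if (is.null(G_blended) || nrow(G_blended) == 0) {
    attr(A_inv, "kind") <- "H_inverse"
    attr(A_inv, "genotyped_ids") <- character(0)
    return(A_inv)
  }
  gids <- rownames(G_blended)
  if (is.null(gids)) stop("G_blended must carry animal ids as dimnames")
  if (!all(gids %in% ids))
    stop("genotyped animals absent from the pedigree: ",
         paste(utils::head(setdiff(gids, ids), 5), collapse = ", "))
  if (is.null(A22)) stop("A22 over the genotyped animals is required")
  ev <- eigen(G_blended, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(abs(ev), 1))
    stop("G* is singular or near-singular; blend with A22 first ",
         "(see blend_tune_G)")
  Ginv <- chol2inv(chol(G_blended))
  A22inv <- chol2inv(chol(A22))
  delta <- Ginv - A22inv
  pos <- match(gids, ids)
  H <- as(A_inv, "TsparseMatrix")
  ii <- c(H@i + 1L, rep(pos, each = length(pos)))
  jj <- c(H@j + 1L, rep(pos, times = length(pos)))
  xx <- c(H@x, as.vector(delta))
  Hinv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                               dims = dim(A_inv), dimnames = list(ids, ids))
  Hinv <- Matrix::forceSymmetric(Matrix::drop0(Hinv))
  attr(Hinv, "kind") <- "H_inverse"
  attr(Hinv, "genotyped_ids") <- gids
  Hinv
}
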