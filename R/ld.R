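#' Three-locus haplotype frequency table
#'
#' Frequencies over the 8 haplotypes of three biallelic loci A/a, B/b, C/c
#' in the fixed order (abc, abC, aBc, aBC, Abc, AbC, ABc, ABC) — the
#' capital allele of locus A varies slowest, of locus C fastest. All
#' derived quantities (allele frequencies, pairwise and third-order
#' disequilibria) depend on this labelling convention.
#'
#' @param freqs numeric vector of length 8 (non-negative, summing to 1
#'   within `tol`), in the order above; names are ignored.
#' @param tol tolerance on the sum constraint.
#' @return object of class `haplotype_table`: list with `freqs` (named),
#'   `p` (allele frequencies of A, B, C) and the indicator matrix used
#'   internally.
#' @export
haplotype_table <- function(freqs, tol = 1e-8) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 8) stop("need 8 haplotype frequencies")
  if (any(freqs < -tol)) stop("negative haplotype frequency")
  if (abs(sum(freqs) - 1) > tol) stop("haplotype frequencies must sum to 1")
  freqs <- pmax(freqs, 0)
  freqs <- freqs / sum(freqs)
  names(freqs) <- haplotype_names()
  x <- hap_indicators()
  p <- as.numeric(crossprod(x, freqs))
  names(p) <- c("A", "B", "C")
  structure(list(freqs = freqs, p = p), class = "haplotype_table")
}

haplotype_names <- function() {
  c("abc", "abC", "aBc", "aBC", "Abc", "AbC", "ABc", "ABC")
}

#' Capital-allele indicator matrix for the 8 three-locus haplotypes
#'
#' 8 x 3 matrix of 0/1 indicators (columns A, B, C), rows in the package's
#' fixed haplotype order (abc, abC, ..., ABC). Useful for constructing
#' haplotype tables with prescribed moment structure.
#'
#' @return integer matrix.
#' @export
hap_indicators <- function() {
  g <- expand.grid(C = 0:1, B = 0:1, A = 0:1)
  as.matrix(g[, c("A", "B", "C")])
}

#' @exportS3Method base::print
print.haplotype_table <- function(x, ...) {
  cat("three-locus haplotype table\n")
  print(round(x$freqs, 6))
  cat(sprintf("p_A=%.4f p_B=%.4f p_C=%.4f  D_ABC=%.6f\n",
              x$p["A"], x$p["B"], x$p["C"], third_order_D(x)))
  invisible(x)
}

#' Pairwise linkage disequilibrium coefficient
#'
#' `D_XY = p_XY - p_X p_Y` for a pair of the three loci.
#'
#' @param table a [haplotype_table()].
#' @param pair two of `"A"`, `"B"`, `"C"`, e.g. `c("A","B")` or `"AB"`.
#' @return The coefficient (single number).
#' @export
pairwise_D <- function(table, pair = c("A", "B")) {
  if (length(pair) == 1) pair <- strsplit(pair, "")[[1]]
  stopifnot(all(pair %in% c("A", "B", "C")), length(pair) == 2)
  x <- hap_indicators()
  pxy <- sum(table$freqs[x[, pair[1]] == 1 & x[, pair[2]] == 1])
  pxy - table$p[[pair[1]]] * table$p[[pair[2]]]
}

#' Third-order linkage disequilibrium coefficient
#'
#' `D_ABC = p_ABC - p_A D_BC - p_B D_AC - p_C D_AB - p_A p_B p_C`, the
#' non-independence among the three loci not accounted for by allele
#' frequencies and pairwise disequilibria. Equals the third mixed central
#' moment of the three capital-allele indicators and ranges over
#' [-1/8, 1/8].
#'
#' @param table a [haplotype_table()].
#' @return The coefficient (single number).
#' @export
third_order_D <- function(table) {
  x <- hap_indicators()
  p <- table$p
  pABC <- sum(table$freqs[rowSums(x) == 3])
  unname(pABC - p["A"] * pairwise_D(table, c("B", "C")) -
           p["B"] * pairwise_D(table, c("A", "C")) -
           p["C"] * pairwise_D(table, c("A", "B")) -
           p["A"] * p["B"] * p["C"])
}

#' Extremize the third-order LD coefficient under constraints
#'
#' Finds the minimum and maximum of `D_ABC` over the haplotype simplex
#' subject to fixed allele frequencies and fixed pairwise disequilibria
#' (all linear constraints). The constrained feasible set is an affine
#' slice of the simplex; it is parameterised through its null space,
#' searched on a deterministic grid (step 1/400 per free coordinate, for
#' up to two free dimensions; coarser above), and polished with
#' Nelder-Mead refinement from the best grid points. At intermediate
#' allele frequencies with all pairwise D = 0 the extrema are -1/8 and
#' +1/8.
#'
#' @param p allele frequencies (A, B, C); default `c(0.5, 0.5, 0.5)`.
#' @param D pairwise disequilibria (AB, AC, BC); default zero. Use `NULL`
#'   to leave them unconstrained.
#' @param independence additionally force `p_ABC = p_A p_B p_C` (which
#'   pins `D_ABC` at 0 when pairwise D are 0).
#' @param grid_step grid resolution on the free coordinates.
#' @return list with `min`, `max`, `argmin`, `argmax`
#'   ([haplotype_table()]s).
#' @export
extremize_third_order_D <- function(p = c(0.5, 0.5, 0.5), D = c(0, 0, 0),
                                    independence = FALSE,
                                    grid_step = 1 / 400) {
  x <- hap_indicators()
  ## linear constraints Cf = b on the 8 frequencies
  Cmat <- rbind(rep(1, 8), t(x))
  b <- c(1, p)
  if (!is.null(D)) {
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    for (k in 1:3) {
      pr <- pairs[[k]]
      Cmat <- rbind(Cmat, as.numeric(x[, pr[1]] == 1 & x[, pr[2]] == 1))
      b <- c(b, D[k] + p[pr[1]] * p[pr[2]])
    }
  }
  if (independence) {
    Cmat <- rbind(Cmat, as.numeric(rowSums(x) == 3))
    b <- c(b, prod(p))
  }
  ## particular solution + null space
  sv <- svd(Cmat, nv = 8)
  r <- sum(sv$d > 1e-10 * sv$d[1])
  part <- sv$v[, seq_len(r), drop = FALSE] %*%
    ((crossprod(sv$u[, seq_len(r), drop = FALSE], b)) / sv$d[seq_len(r)])
  if (max(abs(Cmat %*% part - b)) > 1e-8)
    stop("infeasible constraints")
  Nmat <- sv$v[, -seq_len(r), drop = FALSE]
  nfree <- ncol(Nmat)
  objective <- function(coef) {
    f <- as.numeric(part + Nmat %*% coef)
    if (any(f < -1e-9)) return(NA_real_)
    third_order_D(haplotype_table(pmax(f, 0) / sum(pmax(f, 0))))
  }
  if (nfree == 0) {
    tab <- haplotype_table(pmax(as.numeric(part), 0))
    d <- third_order_D(tab)
    return(list(min = d, max = d, argmin = tab, argmax = tab))
  }
  ## bounding box of the polytope in null-space coordinates: any feasible
  ## point is within Euclidean distance 2 of the min-norm solution
  lim <- 2
  steps <- if (nfree <= 2) grid_step else 1 / 40
  grid1 <- seq(-lim, lim, by = steps * 2 * lim)
  grids <- rep(list(grid1), nfree)
  pts <- as.matrix(expand.grid(grids))
  vals <- apply(pts, 1, objective)
  ok <- which(!is.na(vals))
  if (!length(ok)) stop("no feasible point found on the grid")
  refine <- function(i0, sense) {
    start <- pts[i0, ]
    fn <- function(coef) {
      val <- objective(coef)
      if (is.na(val)) return(1e6)
      sense * val
    }
    if (nfree == 1) {
      opt <- stats::optimize(function(z) fn(z),
                             interval = c(start - 2 * steps * lim,
                                          start + 2 * steps * lim),
                             tol = 1e-10)
      list(value = sense * opt$objective, par = opt$minimum)
    } else {
      opt <- stats::optim(start, fn, method = "Nelder-Mead",
                          control = list(reltol = 1e-12, maxit = 2000))
      list(value = sense * opt$value, par = opt$par)
    }
  }
  imax <- ok[which.max(vals[ok])]
  imin <- ok[which.min(vals[ok])]
  rmax <- refine(imax, -1)
  rmin <- refine(imin, +1)
  to_table <- function(coef) {
    f <- pmax(as.numeric(part + Nmat %*% coef), 0)
    haplotype_table(f / sum(f))
  }
  list(min = rmin$value, max = rmax$value,
       argmin = to_table(rmin$par), argmax = to_table(rmax$par))
}

#' Bulmer effect in the haploid two-locus model
#'
#' The classic demonstration that directional selection builds negative
#' LD: gametes ab, aB, Ab, AB start at frequency 1/4 each with phenotypic
#' values 0, 1, 1, 2 and fitnesses `(1-s), 1, 1, (1+s)`. Before selection
#' D = 0; after selection the gamete frequencies are
#' `0.25(1-s), 0.25, 0.25, 0.25(1+s)` (they still sum to one: the +/- s
#' terms cancel) and the disequilibrium is exactly `-s^2/16`.
#'
#' @param s selection coefficient in `[0, 1)`.
#' @return list with `freqs_before`, `D_before` (0), `freqs_after`,
#'   `D_after` (= `-s^2/16`).
#' @export
bulmer_haploid_ld <- function(s) {
  if (s < 0 || s >= 1) stop("s must lie in [0, 1)")
  before <- c(ab = 0.25, aB = 0.25, Ab = 0.25, AB = 0.25)
  after <- c(ab = 0.25 * (1 - s), aB = 0.25, Ab = 0.25,
             AB = 0.25 * (1 + s))
  Dof <- function(f) {
    pA <- f["Ab"] + f["AB"]; pB <- f["aB"] + f["AB"]
    unname(f["AB"] - pA * pB)
  }
  list(freqs_before = before, D_before = Dof(before),
       freqs_after = after, D_after = Dof(after))
}

#' Cumulative selection response with and without recombination
#'
#' Response to truncation selection after `t` generations when additive by
#' additive variance contributes:
#' `R_t = i sigma_P (t h2 + V_AA / V_P)` with free recombination (the
#' epistatic contribution is transient) and
#' `R_t = i sigma_P (t h2 + t V_AA / (2 V_P))` with no recombination (it
#' accumulates at half rate but every generation).
#'
#' @param i selection intensity.
#' @param sigma_P phenotypic standard deviation.
#' @param h2 narrow-sense heritability.
#' @param VAA_over_VP ratio of additive-by-additive to phenotypic variance.
#' @param t generation number (>= 1).
#' @param recombination `"free"` or `"none"`.
#' @return Response `R_t` in trait units (vectorised over `t`).
#' @export
selection_response <- function(i, sigma_P, h2, VAA_over_VP, t,
                               recombination = c("free", "none")) {
  recombination <- match.arg(recombination)
  stopifnot(sigma_P > 0, h2 >= 0, h2 <= 1, VAA_over_VP >= 0,
            h2 + VAA_over_VP <= 1)
  if (recombination == "free") i * sigma_P * (t * h2 + VAA_over_VP)
  else i * sigma_P * (t * h2 + t * VAA_over_VP / 2)
}

#' Read/write a haplotype frequency table
#'
#' Plain 8-row delimited text with columns `haplotype`, `frequency`.
#'
#' @param path file path.
#' @param table a [haplotype_table()] (for writing).
#' @return [haplotype_table()] for the reader; invisible path for the
#'   writer.
#' @export
read_haplotype_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  stopifnot(all(c("haplotype", "frequency") %in% names(d)))
  f <- d$frequency[match(haplotype_names(), d$haplotype)]
  if (anyNA(f)) stop("file must contain all 8 haplotypes")
  haplotype_table(f)
}

#' @rdname read_haplotype_table
#' @export
write_haplotype_table <- function(table, path) {
  utils::write.table(
    data.frame(haplotype = names(table$freqs), frequency = table$freqs),
    path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}
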