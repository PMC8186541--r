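#' Construct a validated pedigree
#'
#' A pedigree is a set of (animal, sire, dam) triples with unknown parents
#' coded as `"0"` (or `NA`). Identifiers are opaque strings; internally they
#' are mapped to dense indices in topological order (every parent precedes
#' its progeny). Construction reorders records when needed and fails with a
#' structural error naming the offending cycle if an animal is its own
#' ancestor.
#'
#' @param animal,sire,dam character (or coercible) vectors of equal length.
#'   Parents that never appear as animals are added as founder records.
#' @return An object of class `pedigree`: a list with elements
#'   `id` (character), `sire`, `dam` (integer indices, 0 = unknown), and
#'   `n`. Inbreeding coefficients are attached by [build_A()].
#' @examples
#' ped <- pedigree(c("S", "D", "O"), c("0", "0", "S"), c("0", "0", "D"))
#' build_A(ped)
#' @export
pedigree <- function(animal, sire, dam) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  if (length(animal) != length(sire) || length(animal) != length(dam))
    stop("animal, sire and dam must have equal length")
  sire[is.na(sire)] <- "0"
  dam[is.na(dam)] <- "0"
  if (anyDuplicated(animal))
    stop("duplicated animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  ## parents that never occur as animals become founders
  extra <- setdiff(setdiff(c(sire, dam), "0"), animal)
  if (length(extra)) {
    animal <- c(extra, animal)
    sire <- c(rep("0", length(extra)), sire)
    dam <- c(rep("0", length(extra)), dam)
  }
  ord <- topo_order(animal, sire, dam)
  animal <- animal[ord]; sire <- sire[ord]; dam <- dam[ord]
  idx <- stats::setNames(seq_along(animal), animal)
  lookup <- function(p) ifelse(p == "0", 0L, unname(idx[p]))
  structure(
    list(id = animal, sire = lookup(sire), dam = lookup(dam),
         n = length(animal)),
    class = "pedigree")
}

## Kahn topological sort; reports a cycle by its member ids on failure.
topo_order <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- stats::setNames(seq_len(n), animal)
  parents <- cbind(ifelse(sire == "0", 0L, unname(idx[sire])),
                   ifelse(dam == "0", 0L, unname(idx[dam])))
  indeg <- rowSums(parents > 0)
  children <- vector("list", n)
  for (i in seq_len(n)) for (p in parents[i, ]) if (p > 0)
    children[[p]] <- c(children[[p]], i)
  ## stable Kahn sort: always take the smallest available index, so input
  ## that is already topologically ordered keeps its order
  queue <- which(indeg == 0)
  out <- integer(0)
  while (length(queue)) {
    v <- min(queue); queue <- queue[queue != v]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    cyc <- animal[setdiff(seq_len(n), out)]
    stop("pedigree contains a cycle involving: ", paste(cyc, collapse = ", "))
  }
  out
}

#' @exportS3Method base::print
print.pedigree <- function(x, ...) {
  cat("pedigree with", x$n, "animals,",
      sum(x$sire == 0 & x$dam == 0), "founders\n")
  invisible(x)
}

#' Pedigree relationship matrix A
#'
#' Computes the additive (numerator) relationship matrix by the tabular
#' method: for animal i with parents s and d, `A[i, j] = (A[s, j] + A[d, j])/2`
#' for previous animals j, and `A[i, i] = 1 + F_i` where the inbreeding
#' coefficient `F_i = A[s, d]/2`. Founders are non-inbred and mutually
#' unrelated.
#'
#' @param ped a [pedigree()] object.
#' @return A symmetric positive semidefinite matrix with dimnames the animal
#'   ids, and attributes `F` (per-animal inbreeding coefficients) and
#'   `kind = "A"`.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (i > 1) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0) row <- row + 0.5 * A[s, j]
      if (d > 0) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  structure(A, F = diag(A) - 1, kind = "A")
}

#' Per-animal inbreeding coefficients
#'
#' @param ped a [pedigree()] object.
#' @return Named numeric vector of F coefficients.
#' @export
inbreeding <- function(ped) {
  attr(build_A(ped), "F")
}

#' Sparse inverse of the pedigree relationship matrix
#'
#' Builds A-inverse directly by Henderson's rules, accounting for inbreeding
#' through the parental coefficients (the Mendelian-sampling variance of
#' animal i is `d_i = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one, and 1 with none). Each animal contributes at
#' most nine nonzero cells, over the 3x3 block spanned by itself and its
#' known parents: `+1/d_i` to (i,i), `-1/(2 d_i)` to animal-parent cells and
#' `+1/(4 d_i)` to parent-parent cells.
#'
#' @param ped a [pedigree()] object.
#' @param F optional precomputed inbreeding coefficients; computed via
#'   [build_A()] when missing.
#' @return A sparse symmetric [Matrix::dsCMatrix-class] with attribute
#'   `cells_per_animal`, the number of cells each animal's update touched
#'   (1, 4 or 9).
#' @export
build_A_inverse <- function(ped, F = NULL) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  if (is.null(F)) F <- inbreeding(ped)
  Fpad <- c(0, F)  # index parent 0 -> F = 0 contribution unused
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  cells <- integer(n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    known <- c(s, d)[c(s, d) > 0L]
    di <- 1 - 0.25 * sum(1 + Fpad[known + 1L])
    ai <- 1 / di
    members <- c(i, known)
    coef <- c(1, rep(-0.5, length(known)))
    block <- outer(coef, coef) * ai
    ii <- c(ii, rep(members, each = length(members)))
    jj <- c(jj, rep(members, times = length(members)))
    xx <- c(xx, as.vector(block))
    cells[i] <- length(members)^2
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::forceSymmetric(Matrix::drop0(Ainv))
  attr(Ainv, "cells_per_animal") <- cells
  attr(Ainv, "kind") <- "A_inverse"
  Ainv
}

#' Pedigree relationship block for a subset of animals
#'
#' Extracts A22, the block of A over (typically genotyped) animals.
#'
#' @param A the full matrix from [build_A()].
#' @param ids animal identifiers to keep.
#' @return Dense symmetric matrix over `ids` in the order given.
#' @export
extract_A22 <- function(A, ids) {
  miss <- setdiff(ids, rownames(A))
  if (length(miss))
    stop("ids absent from A: ", paste(utils::head(miss, 5), collapse = ", "))
  out <- A[ids, ids, drop = FALSE]
  attr(out, "kind") <- "A22"
  out
}
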