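#' Assemble Henderson's mixed-model equations
#'
#' Builds the coefficient matrix and right-hand side for the animal model
#' `y = X beta + W a + e` with one or two genetic components sharing the
#' animal incidence `W`, each `a_r ~ N(0, K_r sigma2_r)`. The left-hand
#' side is the standard Henderson form with `K_r^-1 * lambda_r` added to
#' the corresponding random block, `lambda_r = sigma2_e / sigma2_r`.
#' Solutions are in trait units; the inverse left-hand side times
#' `sigma2_e` gives prediction-error (co)variances.
#'
#' Rank deficiency in X is resolved by constraining the solutions of the
#' dependent columns (as found by the QR pivot order) to zero, which keeps
#' the system deterministic and the remaining equations unchanged.
#'
#' @param y numeric response vector (one record per element).
#' @param X fixed-effect design matrix (`nrow(X) == length(y)`), or `NULL`
#'   for a model with no fixed effects.
#' @param animal character vector mapping each record to an animal id.
#' @param kinship_inverse matrix (dense or sparse, dimnames = animal ids)
#'   or list of such matrices for a two-component model; all components
#'   must span the same id set.
#' @param sigma2_a numeric vector of genetic variances, one per component.
#' @param sigma2_e residual variance.
#' @return Object of class `mme`: list with `lhs`, `rhs`, `X`, `W`, ids and
#'   bookkeeping needed by [solve_mme()] and [extract_pev_block()].
#' @export
assemble_mme <- function(y, X, animal, kinship_inverse, sigma2_a, sigma2_e) {
  y <- as.numeric(y)
  nrec <- length(y)
  if (is.null(X)) X <- matrix(0, nrec, 0)
  X <- as.matrix(X)
  stopifnot(nrow(X) == nrec, length(animal) == nrec)
  if (!is.list(kinship_inverse)) kinship_inverse <- list(kinship_inverse)
  ncomp <- length(kinship_inverse)
  stopifnot(length(sigma2_a) == ncomp, all(sigma2_a > 0), sigma2_e > 0)
  ids <- rownames(kinship_inverse[[1]])
  if (is.null(ids)) stop("kinship inverse must carry animal ids as dimnames")
  animal <- as.character(animal)
  miss <- setdiff(animal, ids)
  if (length(miss))
    stop("phenotyped animal(s) missing from the relationship structure: ",
         paste(utils::head(miss, 5), collapse = ", "))
  q <- length(ids)
  aidx <- match(animal, ids)
  W <- Matrix::sparseMatrix(i = seq_len(nrec), j = aidx, x = 1,
                            dims = c(nrec, q))
  lambda <- sigma2_e / sigma2_a
  p <- ncol(X)
  ntot <- p + ncomp * q
  XtX <- crossprod(X)
  XtW <- as.matrix(Matrix::crossprod(X, W))
  WtW <- as.matrix(Matrix::crossprod(W))
  lhs <- matrix(0, ntot, ntot)
  if (p > 0) lhs[seq_len(p), seq_len(p)] <- XtX
  rhs <- numeric(ntot)
  if (p > 0) rhs[seq_len(p)] <- crossprod(X, y)
  Wty <- as.numeric(Matrix::crossprod(W, y))
  for (r in seq_len(ncomp)) {
    rows <- p + (r - 1L) * q + seq_len(q)
    if (p > 0) {
      lhs[seq_len(p), rows] <- XtW
      lhs[rows, seq_len(p)] <- t(XtW)
    }
    rhs[rows] <- Wty
    for (s in seq_len(ncomp)) {
      cols <- p + (s - 1L) * q + seq_len(q)
      lhs[rows, cols] <- WtW
    }
    Kinv <- kinship_inverse[[r]]
    if (!identical(rownames(Kinv), ids))
      stop("all kinship components must span the same animals in the same order")
    lhs[rows, rows] <- lhs[rows, rows] + as.matrix(Kinv) * lambda[r]
  }
  ## fixed-effect rank handling
  dropped <- integer(0)
  if (p > 1) {
    qrX <- qr(X)
    if (qrX$rank < p) {
      dropped <- sort(qrX$pivot[(qrX$rank + 1L):p])
      for (jc in dropped) {
        lhs[jc, ] <- 0; lhs[, jc] <- 0; lhs[jc, jc] <- 1; rhs[jc] <- 0
      }
    }
  }
  structure(list(lhs = lhs, rhs = rhs, X = X, W = W, ids = ids,
                 animal_index = aidx, n_fixed = p, n_comp = ncomp,
                 q = q, lambda = lambda, sigma2_a = sigma2_a,
                 sigma2_e = sigma2_e, dropped_fixed = dropped,
                 y = y),
            class = "mme")
}

#' Solve assembled mixed-model equations
#'
#' Exact dense Cholesky solve. The residual `max|lhs x - rhs|` is checked
#' against `1e-8 * max|rhs|`.
#'
#' @param system an `mme` object from [assemble_mme()].
#' @return The system with elements `beta` (fixed-effect solutions), `u`
#'   (list of per-component breeding-value vectors named by animal id) and
#'   `chol` (Cholesky factor of the LHS, reused for inverse blocks).
#' @export
solve_mme <- function(system) {
  stopifnot(inherits(system, "mme"))
  R <- tryCatch(chol(system$lhs), error = function(e)
    stop("left-hand side is singular beyond fixed-effect constraints: ",
         conditionMessage(e)))
  x <- backsolve(R, forwardsolve(t(R), system$rhs))
  res <- max(abs(system$lhs %*% x - system$rhs))
  scale <- max(abs(system$rhs), 1e-300)
  if (res > 1e-8 * scale)
    warning(sprintf("solve residual %.3g exceeds 1e-8 relative tolerance", res / scale))
  p <- system$n_fixed; q <- system$q
  system$beta <- if (p > 0) x[seq_len(p)] else numeric(0)
  system$u <- lapply(seq_len(system$n_comp), function(r)
    stats::setNames(x[p + (r - 1L) * q + seq_len(q)], system$ids))
  system$solution <- x
  system$chol <- R
  system
}

#' Prediction-error (co)variance block
#'
#' Extracts `Var(a - a_hat)` over the requested animals for one genetic
#' component, in trait-variance units: the corresponding block of the
#' inverse left-hand side multiplied by `sigma2_e`.
#'
#' @param system a solved (or at least assembled) `mme` object.
#' @param ids animal identifiers; defaults to all.
#' @param component genetic component index (1 or 2).
#' @return Symmetric matrix over `ids`.
#' @export
extract_pev_block <- function(system, ids = NULL, component = 1L) {
  stopifnot(inherits(system, "mme"))
  if (is.null(ids)) ids <- system$ids
  pos <- match(ids, system$ids)
  if (anyNA(pos))
    stop("unknown animal id(s): ",
         paste(utils::head(ids[is.na(pos)], 5), collapse = ", "))
  R <- system$chol
  if (is.null(R)) R <- chol(system$lhs)
  cols <- system$n_fixed + (component - 1L) * system$q + pos
  E <- diag(nrow(system$lhs))[, cols, drop = FALSE]
  Cinv_cols <- backsolve(R, forwardsolve(t(R), E))
  blk <- Cinv_cols[cols, , drop = FALSE] * system$sigma2_e
  dimnames(blk) <- list(ids, ids)
  (blk + t(blk)) / 2
}
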