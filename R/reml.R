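#' Estimate variance components by EM-REML
#'
#' Fits the animal model `y = X beta + sum_r W a_r + e`,
#' `a_r ~ N(0, K_r sigma2_r)`, by expectation-maximisation REML. The EM
#' update never decreases the REML log-likelihood and keeps all variances
#' positive; convergence is declared when the maximum relative parameter
#' change drops below `tol`. A single-component model uses an
#' eigendecomposition of the observed-animal kinship so each iteration is
#' linear in the number of records; the two-component model (e.g. window
#' plus rest-of-genome) uses dense inversions and is intended for
#' desk-scale data (n up to a few thousand).
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix; `NULL` means intercept-only.
#' @param animal character vector of animal ids, one per record.
#' @param kinship kinship matrix with id dimnames, or list of such matrices
#'   (one per genetic component).
#' @param start optional starting values `c(sigma2_a..., sigma2_e)`;
#'   defaults to equal split of the phenotypic variance.
#' @param max_iter,tol iteration controls.
#' @return list with `sigma2` (named vector: one per genetic component plus
#'   `e`), `h2` (per-component share of the total variance), `loglik`
#'   (final REML log-likelihood), `trace` (data.frame of iterates),
#'   `converged`, `iterations`.
#' @export
estimate_variance_components <- function(y, X = NULL, animal, kinship,
                                         start = NULL, max_iter = 1000,
                                         tol = 1e-6) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (!is.list(kinship)) kinship <- list(kinship)
  ncomp <- length(kinship)
  stopifnot(ncomp %in% 1:2, nrow(X) == n, length(animal) == n)
  ## reduce X to full column rank for REML
  qrX <- qr(X)
  X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  p <- ncol(X)
  ## observed-animal kinship blocks (record level)
  Kt <- lapply(kinship, function(K) {
    ids <- rownames(K)
    if (is.null(ids)) stop("kinship must carry animal ids as dimnames")
    pos <- match(as.character(animal), ids)
    if (anyNA(pos)) stop("record animal(s) missing from kinship")
    K <- as.matrix(K)[pos, pos, drop = FALSE]
    ev <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-6 * max(1, max(abs(K))))
      stop("kinship matrix is not positive semidefinite (min eigenvalue ",
           signif(ev, 3), ")")
    K
  })
  vy <- stats::var(y)
  if (is.null(start)) start <- rep(vy / (ncomp + 1), ncomp + 1)
  stopifnot(length(start) == ncomp + 1, all(start > 0))
  theta <- start
  if (ncomp == 1) {
    fit <- em_reml_single(y, X, Kt[[1]], theta, max_iter, tol)
  } else {
    fit <- em_reml_dense(y, X, Kt, theta, max_iter, tol)
  }
  if (!fit$converged)
    warning("EM-REML did not converge in ", max_iter,
            " iterations; returning last iterate")
  sigma2 <- fit$theta
  names(sigma2) <- c(paste0("a", if (ncomp > 1) seq_len(ncomp) else ""), "e")
  h2 <- sigma2[seq_len(ncomp)] / sum(sigma2)
  list(sigma2 = sigma2, h2 = unname(h2), loglik = fit$loglik,
       trace = fit$trace, converged = fit$converged,
       iterations = fit$iterations)
}

## Single genetic component: rotate by eigenvectors of the record-level
## kinship; every EM step is then O(n p^2).
em_reml_single <- function(y, X, K, theta, max_iter, tol) {
  n <- length(y); p <- ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  Xt <- crossprod(eg$vectors, X)
  trace <- matrix(NA_real_, max_iter + 1L, 3)
  colnames(trace) <- c("sigma2_a", "sigma2_e", "loglik")
  objective <- function(th) {
    v <- th[1] * d + th[2]
    M <- Xt / v
    XtVX <- crossprod(Xt, M)
    w <- yt / v - M %*% solve(XtVX, crossprod(M, yt))
    ll <- -0.5 * (sum(log(v)) + determinant(XtVX)$modulus + sum(yt * w))
    list(ll = as.numeric(ll), w = as.numeric(w), v = v, M = M, XtVX = XtVX)
  }
  ob <- objective(theta)
  trace[1, ] <- c(theta, ob$ll)
  converged <- FALSE
  it <- 0
  fac <- 4
  flat <- 0L
  for (it in seq_len(max_iter)) {
    w <- ob$w; v <- ob$v; M <- ob$M
    B <- solve(ob$XtVX)
    ## tr(P K) = sum(d/v) - tr(B X'V-1 K V-1 X); same with K -> I
    MdM <- crossprod(M, d * M)
    MM <- crossprod(M)
    trPK <- sum(d / v) - sum(B * MdM)
    trP <- sum(1 / v) - sum(B * MM)
    yPKPy <- sum(d * w^2)
    yPPy <- sum(w^2)
    new <- c(theta[1] + theta[1]^2 / n * (yPKPy - trPK),
             theta[2] + theta[2]^2 / n * (yPPy - trP))
    new <- pmax(new, 1e-10)
    ob_new <- objective(new)
    ## guarded log-space extrapolation of the EM step (EM creeps
    ## geometrically near boundaries); accepted only when the REML
    ## log-likelihood improves, so monotonicity is preserved
    acc <- pmax(exp(log(new) + fac * (log(new) - log(theta))), 1e-10)
    ob_acc <- objective(acc)
    if (is.finite(ob_acc$ll) && ob_acc$ll > ob_new$ll + 1e-12) {
      new <- acc; ob_new <- ob_acc
      fac <- min(fac * 2, 128)
    } else fac <- max(4, fac / 2)
    rel <- max(abs(new - theta) / pmax(abs(theta), 1e-6 * sum(theta)))
    ll_gain <- ob_new$ll - ob$ll
    flat <- if (ll_gain < 1e-9 * (1 + abs(ob_new$ll))) flat + 1L else 0L
    theta <- new
    ob <- ob_new
    trace[it + 1L, ] <- c(theta, ob$ll)
    ## converged when parameters settle, or when the REML log-likelihood
    ## has stopped improving (flat ridges let parameters jitter forever)
    if (rel < tol || flat >= 3L) { converged <- TRUE; break }
  }
  list(theta = theta, loglik = ob$ll, converged = converged,
       iterations = it,
       trace = as.data.frame(trace[!is.na(trace[, 1]), , drop = FALSE]))
}

## One or two genetic components, dense V path.
em_reml_dense <- function(y, X, Kt, theta, max_iter, tol) {
  n <- length(y)
  ncomp <- length(Kt)
  trace <- matrix(NA_real_, max_iter + 1L, ncomp + 2L)
  colnames(trace) <- c(paste0("sigma2_a", seq_len(ncomp)), "sigma2_e", "loglik")
  objective <- function(th) {
    V <- diag(th[ncomp + 1L], n)
    for (r in seq_len(ncomp)) V <- V + th[r] * Kt[[r]]
    cV <- chol(V)
    Vinv <- chol2inv(cV)
    M <- Vinv %*% X
    XtVX <- crossprod(X, M)
    w <- Vinv %*% y - M %*% solve(XtVX, crossprod(X, Vinv %*% y))
    P <- Vinv - M %*% solve(XtVX, t(M))
    ll <- -0.5 * (2 * sum(log(diag(cV))) + determinant(XtVX)$modulus +
                    sum(y * w))
    list(ll = as.numeric(ll), w = as.numeric(w), P = P)
  }
  ob <- objective(theta)
  trace[1, ] <- c(theta, ob$ll)
  converged <- FALSE
  it <- 0
  fac <- 4
  flat <- 0L
  for (it in seq_len(max_iter)) {
    w <- ob$w; P <- ob$P
    new <- theta
    for (r in seq_len(ncomp)) {
      Kw <- Kt[[r]] %*% w
      new[r] <- theta[r] + theta[r]^2 / n *
        (sum(w * Kw) - sum(P * Kt[[r]]))
    }
    new[ncomp + 1L] <- theta[ncomp + 1L] + theta[ncomp + 1L]^2 / n *
      (sum(w^2) - sum(diag(P)))
    new <- pmax(new, 1e-10)
    ob_new <- objective(new)
    acc <- pmax(exp(log(new) + fac * (log(new) - log(theta))), 1e-10)
    ob_acc <- objective(acc)
    if (is.finite(ob_acc$ll) && ob_acc$ll > ob_new$ll + 1e-12) {
      new <- acc; ob_new <- ob_acc
      fac <- min(fac * 2, 128)
    } else fac <- max(4, fac / 2)
    ## guarded average-information (AI) step: quadratic near the optimum,
    ## accepted only when it beats the EM candidate's log-likelihood
    Ku <- c(lapply(Kt, function(K) as.numeric(K %*% w)), list(w))
    score <- numeric(ncomp + 1L)
    for (r in seq_len(ncomp))
      score[r] <- -0.5 * (sum(P * Kt[[r]]) - sum(w * Ku[[r]]))
    score[ncomp + 1L] <- -0.5 * (sum(diag(P)) - sum(w^2))
    PKu <- lapply(Ku, function(u) as.numeric(P %*% u))
    AI <- matrix(0, ncomp + 1L, ncomp + 1L)
    for (i in seq_len(ncomp + 1L)) for (j in i:(ncomp + 1L))
      AI[i, j] <- AI[j, i] <- 0.5 * sum(Ku[[i]] * PKu[[j]])
    ai_cand <- tryCatch(theta + solve(AI, score), error = function(e) NULL)
    if (!is.null(ai_cand)) {
      ## components driven negative sit at the boundary: clamp, as usual
      ## for AI-REML, and let the likelihood guard decide
      ai_cand <- pmax(ai_cand, 1e-10)
      ob_ai <- objective(ai_cand)
      if (is.finite(ob_ai$ll) && ob_ai$ll > ob_new$ll + 1e-12) {
        new <- ai_cand; ob_new <- ob_ai
      }
    }
    rel <- max(abs(new - theta) / pmax(abs(theta), 1e-6 * sum(theta)))
    ll_gain <- ob_new$ll - ob$ll
    flat <- if (ll_gain < 1e-9 * (1 + abs(ob_new$ll))) flat + 1L else 0L
    theta <- new
    ob <- ob_new
    trace[it + 1L, ] <- c(theta, ob$ll)
    ## converged when parameters settle, or when the REML log-likelihood
    ## has stopped improving (flat ridges let parameters jitter forever)
    if (rel < tol || flat >= 3L) { converged <- TRUE; break }
  }
  list(theta = theta, loglik = ob$ll, converged = converged,
       iterations = it,
       trace = as.data.frame(trace[!is.na(trace[, 1]), , drop = FALSE]))
}
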