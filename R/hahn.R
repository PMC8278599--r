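## Discrete orthogonal Hahn polynomial bases and 2-D Hahn moment transforms.
##
## The regularized basis is h_bar_n(x) = h_n(x) * sqrt(rho(x) / d_n^2),
## orthonormal over the integer support x = 0..N-1. Evaluating the
## gamma-ratio closed form literally overflows for N beyond ~20, and the
## plain three-term forward recurrence in the order n loses orthogonality
## catastrophically by N = 64. The production path instead uses the
## spectral identity of discrete orthogonal polynomials: the matrix
## P[n, x] = p_n(x) sqrt(w(x)) is orthogonal and its columns are the
## eigenvectors of the symmetric tridiagonal Jacobi matrix of the measure,
## with eigenvalues exactly the support points 0..N-1. A LAPACK symmetric
## eigendecomposition therefore yields the basis with machine-precision
## orthonormality at any practical N. The closed form is retained
## (hahnBasisDirect) as a small-N validation oracle.
##
## Note the weight rho(x) here pairs Gamma(beta+1+x) with the ascending
## side of the support, i.e. it equals the classical Hahn weight with the
## roles of alpha and beta interchanged; the Jacobi-matrix coefficients
## below are written for that convention.

.checkHahnParams <- function(N, alpha, beta) {
    if (length(N) != 1L || !is.finite(N) || N < 1 || N != round(N))
        stop("N must be a single positive integer")
    if (length(alpha) != 1L || !is.finite(alpha) || alpha <= -1)
        stop("alpha must be > -1")
    if (length(beta) != 1L || !is.finite(beta) || beta <= -1)
        stop("beta must be > -1")
    invisible(TRUE)
}

## log of the Hahn weight rho(x) on x = 0..N-1
.logHahnWeight <- function(N, alpha, beta) {
    x <- 0:(N - 1L)
    lgamma(N + alpha - x) + lgamma(beta + 1 + x) -
        lgamma(x + 1) - lgamma(N - x)
}

#' Regularized Hahn polynomial basis (production path)
#'
#' Computes the full \code{N x N} table of regularized Hahn polynomial
#' values \eqn{\bar h_n^{(\alpha,\beta)}(x)}, \eqn{n, x = 0..N-1}, an
#' orthonormal basis of functions on the discrete support. The table is
#' obtained from the symmetric tridiagonal Jacobi matrix of the Hahn
#' measure: its eigenvalues are exactly the support points and the
#' eigenvector belonging to eigenvalue \eqn{x} holds
#' \eqn{p_n(x)\sqrt{w(x)}} in component \eqn{n}, so a LAPACK symmetric
#' eigendecomposition yields the whole basis with machine-precision
#' orthonormality even for supports of hundreds of points, where a literal
#' evaluation of the gamma-ratio closed form overflows and a forward
#' three-term recurrence in the order loses orthogonality.
#'
#' Sign convention: each column is scaled so that the order-0 row is
#' positive (\eqn{\bar h_0(x) = \sqrt{w(x)} > 0}), which reproduces the
#' closed form's signs for all orders; in particular the value at
#' \eqn{x = 0} carries sign \eqn{(-1)^n}.
#'
#' @param N positive integer, number of support points.
#' @param alpha,beta Hahn shape parameters, both \eqn{> -1}. The default
#'   \code{alpha = beta = 0} gives the symmetric member of the family.
#' @return a [HahnBasis-class] object.
#'
#' @examples
#' b <- hahnBasis(8)
#' max(abs(tcrossprod(basisValues(b)) - diag(8)))  # orthonormality
#' @seealso [hahnBasisDirect()] for the closed-form evaluation,
#'   [hahnMoments2D()] for the 2-D transform.
#' @export
hahnBasis <- function(N, alpha = 0, beta = 0) {
    .checkHahnParams(N, alpha, beta)
    N <- as.integer(N)
    if (N == 1L) {
        ## a one-point orthonormal basis is forced to unit magnitude
        return(new("HahnBasis", N = 1L, alpha = as.numeric(alpha),
                   beta = as.numeric(beta), values = matrix(1, 1L, 1L)))
    }
    ## Jacobi-matrix coefficients; the weight rho(x) equals the classical
    ## Hahn weight with alpha and beta interchanged, hence aa/bb below.
    Ntop <- N - 1L
    aa <- beta; bb <- alpha
    An <- function(n) (n + aa + bb + 1) * (n + aa + 1) * (Ntop - n) /
        ((2 * n + aa + bb + 1) * (2 * n + aa + bb + 2))
    Cn <- function(n) if (n == 0) 0 else
        n * (n + aa + bb + Ntop + 1) * (n + bb) /
            ((2 * n + aa + bb) * (2 * n + aa + bb + 1))
    aDiag <- vapply(0:(N - 1L), function(n) An(n) + Cn(n), numeric(1))
    sb <- sqrt(vapply(seq_len(N - 1L),
                      function(n) An(n - 1) * Cn(n), numeric(1)))
    J <- diag(aDiag)
    idx <- seq_len(N - 1L)
    J[cbind(idx, idx + 1L)] <- sb
    J[cbind(idx + 1L, idx)] <- sb
    e <- eigen(J, symmetric = TRUE)
    V <- e$vectors[, order(e$values), drop = FALSE]
    vals <- sweep(V, 2L, ifelse(V[1L, ] >= 0, 1, -1), "*")
    new("HahnBasis", N = N, alpha = as.numeric(alpha),
        beta = as.numeric(beta), values = vals)
}

#' Regularized Hahn polynomial basis (closed form)
#'
#' Literal evaluation of the gamma-ratio definition of the Hahn polynomial
#' and its regularization, with every gamma factor handled in log space.
#' Intended as an independent check of [hahnBasis()]: the backward-
#' difference sum cancels catastrophically and the result is only reliable
#' for small supports (roughly \code{N <= 20}).
#'
#' @inheritParams hahnBasis
#' @return a [HahnBasis-class] object.
#' @export
hahnBasisDirect <- function(N, alpha = 0, beta = 0) {
    .checkHahnParams(N, alpha, beta)
    N <- as.integer(N)
    lw <- .logHahnWeight(N, alpha, beta)
    vals <- matrix(0, N, N)
    for (n in 0:(N - 1L)) {
        ## log d_n^2
        ld2 <- lgamma(alpha + n + 1) + lgamma(beta + n + 1) +
            lgamma(alpha + beta + n + 1 + N) -
            log(alpha + beta + 2 * n + 1) - lgamma(n + 1) -
            lgamma(N - n) - lgamma(alpha + beta + n + 1)
        for (x in 0:(N - 1L)) {
            acc <- 0
            for (k in 0:n) {
                t <- x - k
                if (t < 0 || N - n - t <= 0) next  # 1/Gamma(<=0 integer) = 0
                lrho_n <- lgamma(N + alpha - t) + lgamma(n + beta + 1 + t) -
                    lgamma(t + 1) - lgamma(N - n - t)
                acc <- acc + (-1)^k *
                    exp(lchoose(n, k) + lrho_n - 0.5 * lw[x + 1L] - 0.5 * ld2)
            }
            ## B_n = (-1)^n / n!
            vals[n + 1L, x + 1L] <- (-1)^n * exp(-lgamma(n + 1)) * acc
        }
    }
    new("HahnBasis", N = N, alpha = as.numeric(alpha),
        beta = as.numeric(beta), values = vals)
}

#' 2-D Hahn moments of an image block
#'
#' Projects a block onto the tensor-product Hahn basis:
#' \deqn{H_{mn} = \sum_x \sum_y \bar h_m(y)\, \bar h_n(x)\, f(x, y),}
#' with \eqn{y} running over rows and \eqn{x} over columns, so that
#' \code{coeffs[m+1, n+1]} carries vertical order \eqn{m} and horizontal
#' order \eqn{n}. The transform is orthonormal: total energy is conserved
#' and [inverseHahn2D()] inverts it exactly at full order.
#'
#' @param block numeric matrix of pixel intensities.
#' @param basisRow [HahnBasis-class] for the row (vertical) direction;
#'   its \code{N} must equal \code{nrow(block)}.
#' @param basisCol [HahnBasis-class] for the column direction; defaults to
#'   \code{basisRow}. Its \code{N} must equal \code{ncol(block)}.
#' @return numeric moment matrix of the same shape as \code{block}.
#'
#' @examples
#' b <- hahnBasis(8)
#' f <- matrix(runif(64), 8)
#' H <- hahnMoments2D(f, b)
#' sum(H^2) - sum(f^2)   # Parseval: ~0
#' @export
hahnMoments2D <- function(block, basisRow, basisCol = basisRow) {
    .assertMatrix(block, "block")
    stopifnot(is(basisRow, "HahnBasis"), is(basisCol, "HahnBasis"))
    if (nrow(block) != basisRow@N || ncol(block) != basisCol@N)
        stop(sprintf(
            "block is %d x %d but bases have N = %d (rows), %d (cols)",
            nrow(block), ncol(block), basisRow@N, basisCol@N))
    basisRow@values %*% block %*% t(basisCol@values)
}

#' Inverse 2-D Hahn moment transform
#'
#' Reconstructs a block from its full-order Hahn moment matrix. With all
#' orders retained this is the exact inverse of [hahnMoments2D()]
#' (orthonormal transform).
#'
#' @param moments numeric moment matrix.
#' @inheritParams hahnMoments2D
#' @return the reconstructed pixel matrix.
#' @export
inverseHahn2D <- function(moments, basisRow, basisCol = basisRow) {
    .assertMatrix(moments, "moments")
    stopifnot(is(basisRow, "HahnBasis"), is(basisCol, "HahnBasis"))
    if (nrow(moments) != basisRow@N || ncol(moments) != basisCol@N)
        stop(sprintf(
            "moments are %d x %d but bases have N = %d (rows), %d (cols)",
            nrow(moments), ncol(moments), basisRow@N, basisCol@N))
    t(basisRow@values) %*% moments %*% basisCol@values
}
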