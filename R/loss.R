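## Composite training loss: pixel cross-entropy + (1 - MS-SSIM) + total
## variation. Each term is implemented with an analytic gradient with
## respect to the network output so the autoencoder trains by plain
## backpropagation; the gradients are finite-difference-checked in the
## test suite.

.CLAMP_EPS <- 1e-7

## ---- cross entropy ---------------------------------------------------

.ceLoss <- function(I, O, reduce = "mean", grad = FALSE) {
    Ic <- pmin(pmax(I, .CLAMP_EPS), 1 - .CLAMP_EPS)
    inside <- O > .CLAMP_EPS & O < 1 - .CLAMP_EPS
    Oc <- pmin(pmax(O, .CLAMP_EPS), 1 - .CLAMP_EPS)
    n <- if (reduce == "mean") length(O) else 1
    value <- -sum(Ic * log(Oc) + (1 - Ic) * log(1 - Oc)) / n
    if (!grad) return(list(value = value))
    g <- (-Ic / Oc + (1 - Ic) / (1 - Oc)) / n
    g[!inside] <- 0  # clamped pixels carry no gradient
    list(value = value, grad = g)
}

#' Pixel cross-entropy loss
#'
#' Treats each pixel of the input \code{I} as a Bernoulli target for the
#' output \code{O}:
#' \deqn{L = -\sum \big[I \log O + (1 - I)\log(1 - O)\big],}
#' mean-reduced over pixels and channels by default (\code{reduce =
#' "sum"} gives the literal sum). Both images are clamped to
#' \eqn{[10^{-7}, 1 - 10^{-7}]}. For fixed \code{I} the minimum over
#' \code{O} is at \code{O = I}, where the loss equals the binary entropy
#' of \code{I} (not zero).
#'
#' @param I,O numeric arrays of equal shape with values in \[0, 1\].
#' @param reduce \code{"mean"} (default) or \code{"sum"}.
#' @return nonnegative scalar.
#'
#' @examples
#' lossCrossEntropy(0.5, 0.5)  # log(2)
#' @export
lossCrossEntropy <- function(I, O, reduce = c("mean", "sum")) {
    reduce <- match.arg(reduce)
    if (!identical(dim(I) %||% length(I), dim(O) %||% length(O)))
        stop("I and O must have the same shape")
    .ceLoss(I, O, reduce)$value
}

## ---- (multi-scale) structural similarity ------------------------------

.MSSSIM_WEIGHTS <- c(0.0448, 0.2856, 0.3001, 0.2363, 0.1333)

## 2x2 average pooling (stride 2, floor), and its adjoint.
.pool2 <- function(x) {
    nr <- 2L * (nrow(x) %/% 2L); nc <- 2L * (ncol(x) %/% 2L)
    x <- x[seq_len(nr), seq_len(nc), drop = FALSE]
    (x[seq(1L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
     x[seq(2L, nr, 2L), seq(1L, nc, 2L), drop = FALSE] +
     x[seq(1L, nr, 2L), seq(2L, nc, 2L), drop = FALSE] +
     x[seq(2L, nr, 2L), seq(2L, nc, 2L), drop = FALSE]) / 4
}

.pool2Adj <- function(g, dimFine) {
    out <- matrix(0, dimFine[1], dimFine[2])
    nr <- 2L * nrow(g); nc <- 2L * ncol(g)
    gi <- g / 4
    out[seq(1L, nr, 2L), seq(1L, nc, 2L)] <- gi
    out[seq(2L, nr, 2L), seq(1L, nc, 2L)] <-
        out[seq(2L, nr, 2L), seq(1L, nc, 2L)] + gi
    out[seq(1L, nr, 2L), seq(2L, nc, 2L)] <-
        out[seq(1L, nr, 2L), seq(2L, nc, 2L)] + gi
    out[seq(2L, nr, 2L), seq(2L, nc, 2L)] <-
        out[seq(2L, nr, 2L), seq(2L, nc, 2L)] + gi
    out
}

## Per-scale SSIM statistics under a Gaussian window G (zero-pad "same",
## self-adjoint). Returns the luminance and contrast-structure maps and
## everything the gradient needs.
.ssimStats <- function(x, y, win, sigma, C1 = 0.01^2, C2 = 0.03^2) {
    G <- function(m) .gaussFilter(m, size = win, sigma = sigma)
    mx <- G(x); my <- G(y)
    sxx <- G(x * x) - mx * mx
    syy <- G(y * y) - my * my
    sxy <- G(x * y) - mx * my
    A1 <- 2 * mx * my + C1; B1 <- mx^2 + my^2 + C1
    A2 <- 2 * sxy + C2;     B2 <- sxx + syy + C2
    list(mx = mx, my = my, l = A1 / B1, cs = A2 / B2, B1 = B1, B2 = B2,
         G = G)
}

## Gradient of mean(cs) with respect to y.
.csBarGrad <- function(x, y, st) {
    n <- length(y)
    (2 / n) * (x * st$G(1 / st$B2) - st$G(st$mx / st$B2) -
               y * st$G(st$cs / st$B2) + st$G(st$cs * st$my / st$B2))
}

## Gradient of mean(l) with respect to y.
.lBarGrad <- function(y, st) {
    n <- length(y)
    (2 / n) * st$G((st$mx - st$l * st$my) / st$B1)
}

## Multi-scale SSIM of two matrices, optionally with d(MS)/dy.
.msSsimMat <- function(x, y, grad = FALSE, win = 11L, sigma = 1.5) {
    minDim <- min(dim(x))
    if (minDim < win) {
        win <- max(3L, minDim - (1L - minDim %% 2L))  # largest odd <= dim
        .noteOnce(paste0("msssim-win-", win),
                  "image smaller than the SSIM window; window reduced to ",
                  win)
    }
    M <- max(1L, min(length(.MSSSIM_WEIGHTS),
                     floor(log2(minDim / win)) + 1L))
    if (M < length(.MSSSIM_WEIGHTS))
        .noteOnce(paste0("msssim-scales-", M),
                  "image supports only ", M, " MS-SSIM scale(s); ",
                  "weights renormalized")
    w <- .MSSSIM_WEIGHTS[seq_len(M)]
    w <- w / sum(w)

    xs <- list(x); ys <- list(y)
    for (s in seq_len(M - 1L)) {
        xs[[s + 1L]] <- .pool2(xs[[s]])
        ys[[s + 1L]] <- .pool2(ys[[s]])
    }
    stats <- vector("list", M)
    csBar <- numeric(M)
    eps <- 1e-6
    for (s in seq_len(M)) {
        stats[[s]] <- .ssimStats(xs[[s]], ys[[s]], win, sigma)
        csBar[s] <- max(mean(stats[[s]]$cs), eps)
    }
    lBar <- max(mean(stats[[M]]$l), eps)
    ms <- lBar^w[M] * prod(csBar^w)
    if (!grad) return(list(value = ms))

    ## chain rule down the pooling pyramid, coarsest first
    gy <- w[M] * ms / csBar[M] * .csBarGrad(xs[[M]], ys[[M]], stats[[M]]) +
        w[M] * ms / lBar * .lBarGrad(ys[[M]], stats[[M]])
    if (M > 1L) for (s in (M - 1L):1L) {
        gy <- .pool2Adj(gy, dim(ys[[s]])) +
            w[s] * ms / csBar[s] * .csBarGrad(xs[[s]], ys[[s]], stats[[s]])
    }
    list(value = ms, grad = gy)
}

#' Multi-scale structural similarity
#'
#' Standard MS-SSIM: contrast-structure similarity at up to five dyadic
#' scales (2x2 average pooling between scales) and luminance similarity at
#' the coarsest, combined with the usual exponents (0.0448, 0.2856,
#' 0.3001, 0.2363, 0.1333, renormalized when the image supports fewer
#' scales). Local statistics use an 11x11 Gaussian window with
#' \eqn{\sigma = 1.5} and stability constants \eqn{C_1 = 0.01^2},
#' \eqn{C_2 = 0.03^2} for a dynamic range of 1. Multi-channel inputs are
#' averaged over channels.
#'
#' @param X,Y numeric matrices or \code{H x W x C} arrays in \[0, 1\].
#' @return scalar in (0, 1\]; 1 iff the images are structurally identical.
#' @export
msSsim <- function(X, Y) {
    if (!identical(dim(X), dim(Y)))
        stop("X and Y must have the same shape")
    if (is.matrix(X)) return(.msSsimMat(X, Y)$value)
    mean(vapply(seq_len(dim(X)[3]), function(ch)
        .msSsimMat(X[, , ch], Y[, , ch])$value, numeric(1)))
}

.msLoss <- function(I, O, grad = FALSE) {
    if (is.matrix(I)) {
        r <- .msSsimMat(I, O, grad = grad)
        return(list(value = 1 - r$value,
                    grad = if (grad) -r$grad else NULL))
    }
    C <- dim(I)[3]
    val <- 0
    g <- if (grad) array(0, dim(I)) else NULL
    for (ch in seq_len(C)) {
        r <- .msSsimMat(I[, , ch], O[, , ch], grad = grad)
        val <- val + (1 - r$value) / C
        if (grad) g[, , ch] <- -r$grad / C
    }
    list(value = val, grad = g)
}

#' MS-SSIM loss
#'
#' \eqn{1 - \mathrm{MS\mbox{-}SSIM}(I, O)}; zero iff the images are
#' structurally identical.
#'
#' @inheritParams lossCrossEntropy
#' @return scalar in \[0, 1).
#' @export
lossMsSsim <- function(I, O) {
    if (!identical(dim(I), dim(O)))
        stop("I and O must have the same shape")
    .msLoss(I, O)$value
}

## ---- total variation ---------------------------------------------------

.tvLossMat <- function(F, reduce = "mean", grad = FALSE) {
    nr <- nrow(F); nc <- ncol(F)
    dh <- F[, -1L, drop = FALSE] - F[, -nc, drop = FALSE]
    dv <- F[-1L, , drop = FALSE] - F[-nr, , drop = FALSE]
    n <- if (reduce == "mean") length(F) else 1
    value <- (sum(dh^2) + sum(dv^2)) / n
    if (!grad) return(list(value = value))
    g <- matrix(0, nr, nc)
    g[, -1L] <- g[, -1L, drop = FALSE] + 2 * dh
    g[, -nc] <- g[, -nc, drop = FALSE] - 2 * dh
    g[-1L, ] <- g[-1L, , drop = FALSE] + 2 * dv
    g[-nr, ] <- g[-nr, , drop = FALSE] - 2 * dv
    list(value = value, grad = g / n)
}

.tvLoss <- function(O, reduce = "mean", grad = FALSE) {
    if (is.matrix(O)) return(.tvLossMat(O, reduce, grad))
    C <- dim(O)[3]
    val <- 0
    g <- if (grad) array(0, dim(O)) else NULL
    for (ch in seq_len(C)) {
        r <- .tvLossMat(O[, , ch], reduce, grad)
        val <- val + r$value
        if (grad) g[, , ch] <- r$grad
    }
    list(value = val, grad = g)
}

#' Total variation loss
#'
#' Sum of squared horizontal and vertical first differences,
#' \deqn{\sum_{i,j} (F(i,j-1) - F(i,j))^2 + (F(i+1,j) - F(i,j))^2,}
#' mean-reduced over pixels by default (\code{reduce = "sum"} gives the
#' literal sum). Penalizes noise; zero for a constant image.
#'
#' @param F numeric matrix or \code{H x W x C} array.
#' @param reduce \code{"mean"} (default) or \code{"sum"}.
#' @return nonnegative scalar.
#'
#' @examples
#' lossTV(matrix(c(0, 0, 1, 1), 2), reduce = "sum")  # 2
#' @export
lossTV <- function(F, reduce = c("mean", "sum")) {
    reduce <- match.arg(reduce)
    .tvLoss(F, reduce)$value
}

#' Composite training loss
#'
#' \deqn{L_{total} = w_1 L_{cross\_entropy} + w_2 L_{MS\mbox{-}SSIM}
#'   + w_3 L_{TV},}
#' with unit weights by default. The cross-entropy and TV terms are
#' mean-reduced so the three components share a scale.
#'
#' @inheritParams lossCrossEntropy
#' @param weights numeric(3): weights of the cross-entropy, MS-SSIM and TV
#'   terms.
#' @return a list with elements \code{total}, \code{crossEntropy},
#'   \code{msSsim} and \code{tv}; the components always sum (weighted) to
#'   the total.
#'
#' @examples
#' l <- lossTotal(array(0.5, c(16, 16, 3)), array(0.5, c(16, 16, 3)))
#' l$total - log(2)   # MS-SSIM and TV terms vanish for identical constants
#' @export
lossTotal <- function(I, O, weights = c(1, 1, 1)) {
    if (!identical(dim(I), dim(O)))
        stop("I and O must have the same shape")
    stopifnot(length(weights) == 3L, all(is.finite(weights)))
    ce <- .ceLoss(I, O)$value
    ms <- .msLoss(I, O)$value
    tv <- .tvLoss(O)$value
    list(total = weights[1] * ce + weights[2] * ms + weights[3] * tv,
         crossEntropy = ce, msSsim = ms, tv = tv)
}

## Value and gradient of the composite loss with respect to O.
.totalLossGrad <- function(I, O, weights = c(1, 1, 1)) {
    ce <- .ceLoss(I, O, grad = TRUE)
    ms <- .msLoss(I, O, grad = TRUE)
    tv <- .tvLoss(O, grad = TRUE)
    list(value = weights[1] * ce$value + weights[2] * ms$value +
             weights[3] * tv$value,
         grad = weights[1] * ce$grad + weights[2] * ms$grad +
             weights[3] * tv$grad)
}
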