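## The six fusion-quality metrics: spatial frequency (SF), SSIM, cross
## entropy (CE, histogram sense), Q_AB/F edge-transfer, pixel-domain
## visual information fidelity (VIF), and feature mutual information
## (FMI). The field names these metrics but their formulas live in their
## canonical references; the constants used here are the published
## standard ones and are pinned below. All metrics reduce color images to
## ITU-R 601 luminance first.

#' Spatial frequency
#'
#' \eqn{SF = \sqrt{RF^2 + CF^2}} where \eqn{RF} and \eqn{CF} are the
#' root-mean-square horizontal and vertical first differences (normalized
#' by the total pixel count). An overall activity/sharpness measure;
#' higher is sharper, 0 for a constant image, and linear in intensity
#' scaling.
#'
#' @param F numeric matrix (or 3-channel array, reduced to luminance),
#'   at least 2 x 2.
#' @return nonnegative scalar.
#'
#' @examples
#' metricSF(matrix(c(0, 0, 1, 1), 2))  # sqrt(2/4) ~ 0.7071
#' @export
metricSF <- function(F) {
    F <- .luminance(F)
    .assertMatrix(F, "F")
    if (nrow(F) < 2L || ncol(F) < 2L) stop("F must be at least 2 x 2")
    n <- length(F)
    rf2 <- sum((F[, -1L, drop = FALSE] - F[, -ncol(F), drop = FALSE])^2) / n
    cf2 <- sum((F[-1L, , drop = FALSE] - F[-nrow(F), , drop = FALSE])^2) / n
    sqrt(rf2 + cf2)
}

#' Structural similarity (single scale)
#'
#' Mean local SSIM with the standard 11x11 Gaussian window
#' (\eqn{\sigma = 1.5}) and constants \eqn{C_1 = 0.01^2, C_2 = 0.03^2}
#' (dynamic range 1). The mean is taken over the interior region where the
#' window fits entirely.
#'
#' @param X,Y numeric matrices (or 3-channel arrays, reduced to luminance)
#'   of equal shape.
#' @return scalar in \[-1, 1\]; 1 iff \code{X == Y}.
#' @export
metricSSIM <- function(X, Y) {
    X <- .luminance(X); Y <- .luminance(Y)
    if (!identical(dim(X), dim(Y))) stop("X and Y must have the same shape")
    win <- 11L
    if (min(dim(X)) < win)
        win <- max(3L, min(dim(X)) - (1L - min(dim(X)) %% 2L))
    st <- .ssimStats(X, Y, win = win, sigma = 1.5)
    ssimMap <- st$l * st$cs
    half <- (win - 1L) %/% 2L
    rows <- (half + 1L):(nrow(X) - half)
    cols <- (half + 1L):(ncol(X) - half)
    mean(ssimMap[rows, cols])
}

## 256-bin gray-level histogram as a probability vector.
.grayHist <- function(x, bins = 256L) {
    q <- pmin(pmax(floor(x * bins) + 1L, 1L), bins)
    tabulate(q, nbins = bins) / length(q)
}

## KL divergence in bits between two probability vectors, eps-smoothed.
.klBits <- function(p, q, eps = 1e-12) {
    p <- (p + eps) / sum(p + eps)
    q <- (q + eps) / sum(q + eps)
    sum(p * log2(p / q))
}

#' Cross entropy between source and fused histograms
#'
#' Mean over the sources of the Kullback-Leibler divergence (in bits,
#' epsilon-smoothed) between each source's 256-bin gray-level histogram
#' and the fused image's. Lower is better: 0 when the fused image has
#' exactly the sources' gray-level distribution.
#'
#' @param A,B source images; \code{F} the fused image (color inputs are
#'   reduced to luminance). Additional sources may be supplied via
#'   \code{sources}.
#' @param F fused image.
#' @param sources optional list of source images overriding \code{A, B}
#'   (for tri-modal scoring).
#' @return nonnegative scalar.
#' @export
metricCE <- function(A, B, F, sources = NULL) {
    srcs <- if (is.null(sources)) list(A, B) else sources
    Fl <- .luminance(F)
    hf <- .grayHist(Fl)
    mean(vapply(srcs, function(s) {
        sl <- .luminance(s)
        if (!identical(dim(sl), dim(Fl)))
            stop("sources and fused image must have the same size")
        .klBits(.grayHist(sl), hf)
    }, numeric(1)))
}

#' Edge-information transfer (Q_AB/F)
#'
#' The edge-transfer fusion metric: Sobel edge strength and orientation of
#' the fused image are compared against each source; strength and
#' orientation preservation are mapped through the published sigmoids
#' (\eqn{\Gamma_g = 0.9994, \kappa_g = -15, \sigma_g = 0.5};
#' \eqn{\Gamma_\alpha = 0.9879, \kappa_\alpha = -22,
#' \sigma_\alpha = 0.8}) and the per-pixel products are averaged with the
#' sources' edge strengths as weights.
#'
#' @inheritParams metricCE
#' @return scalar in \[0, 1\]; near 1 when all source edges appear in the
#'   fused image.
#' @export
metricQABF <- function(A, B, F) {
    Al <- .luminance(A); Bl <- .luminance(B); Fl <- .luminance(F)
    if (!identical(dim(Al), dim(Fl)) || !identical(dim(Bl), dim(Fl)))
        stop("A, B and F must have the same size")
    edge <- function(x) {
        s <- .sobel(x)
        g <- sqrt(s$gx^2 + s$gy^2)
        a <- atan2(s$gy, s$gx)
        a[a > pi / 2] <- a[a > pi / 2] - pi    # fold to (-pi/2, pi/2]
        a[a <= -pi / 2] <- a[a <= -pi / 2] + pi
        list(g = g, a = a)
    }
    eA <- edge(Al); eB <- edge(Bl); eF <- edge(Fl)
    qxf <- function(eX) {
        G <- ifelse(eX$g > eF$g,
                    ifelse(eX$g > 0, eF$g / eX$g, 0),
                    ifelse(eF$g > 0, eX$g / eF$g, 0))
        AA <- 1 - abs(eX$a - eF$a) / (pi / 2)
        Qg <- 0.9994 / (1 + exp(-15 * (G - 0.5)))
        Qa <- 0.9879 / (1 + exp(-22 * (AA - 0.8)))
        Qg * Qa
    }
    wA <- eA$g; wB <- eB$g
    den <- sum(wA + wB)
    if (den == 0) return(0)
    sum(qxf(eA) * wA + qxf(eB) * wB) / den
}

#' Pixel-domain visual information fidelity (VIF)
#'
#' Four-scale pixel-domain VIF under a Gaussian scale-space and a
#' Gaussian-source/additive-noise channel model with noise variance
#' \eqn{\sigma_n^2 = 2} (intensities are mapped to the conventional
#' 0-255 range internally). Equals 1 when the images are identical,
#' decreases with distortion, and can exceed 1 for contrast-enhanced
#' images.
#'
#' @inheritParams metricSSIM
#' @return nonnegative scalar.
#' @export
metricVIF <- function(X, Y) {
    ref <- .luminance(X) * 255
    dist <- .luminance(Y) * 255
    if (!identical(dim(ref), dim(dist)))
        stop("X and Y must have the same shape")
    sigmaNsq <- 2
    num <- 0; den <- 0
    for (scale in 1:4) {
        N <- 2^(4 - scale + 1) + 1
        if (scale > 1) {
            k <- .gaussKernel1d(N, N / 5)
            ref <- .filterSep(ref, k)
            dist <- .filterSep(dist, k)
            ref <- ref[seq(1L, nrow(ref), 2L), seq(1L, ncol(ref), 2L),
                       drop = FALSE]
            dist <- dist[seq(1L, nrow(dist), 2L), seq(1L, ncol(dist), 2L),
                         drop = FALSE]
        }
        if (min(dim(ref)) < N) break
        G <- function(m) .filterSep(m, .gaussKernel1d(N, N / 5))
        mu1 <- G(ref); mu2 <- G(dist)
        s1 <- pmax(G(ref * ref) - mu1^2, 0)
        s2 <- pmax(G(dist * dist) - mu2^2, 0)
        s12 <- G(ref * dist) - mu1 * mu2
        eps <- 1e-10
        g <- s12 / (s1 + eps)
        sv <- s2 - g * s12
        g[s1 < eps] <- 0; sv[s1 < eps] <- s2[s1 < eps]; s1[s1 < eps] <- 0
        g[s2 < eps] <- 0; sv[s2 < eps] <- 0
        sv[g < 0] <- s2[g < 0]; g[g < 0] <- 0
        sv[sv <= eps] <- eps
        num <- num + sum(log10(1 + g^2 * s1 / (sv + sigmaNsq)))
        den <- den + sum(log10(1 + s1 / sigmaNsq))
    }
    if (den == 0) return(1)
    num / den
}

## joint 256-bin histogram mutual information machinery for FMI
.miBits <- function(x, y, bins = 256L) {
    qx <- pmin(pmax(floor(x * bins) + 1L, 1L), bins)
    qy <- pmin(pmax(floor(y * bins) + 1L, 1L), bins)
    joint <- tabulate((qx - 1L) * bins + qy, nbins = bins * bins)
    joint <- joint / sum(joint)
    px <- .grayHist(x, bins); py <- .grayHist(y, bins)
    jm <- matrix(joint, bins, bins)  # rows: qy, cols: qx
    hx <- -sum(px[px > 0] * log2(px[px > 0]))
    hy <- -sum(py[py > 0] * log2(py[py > 0]))
    hxy <- -sum(jm[jm > 0] * log2(jm[jm > 0]))
    list(mi = hx + hy - hxy, hx = hx, hy = hy)
}

#' Feature mutual information (FMI)
#'
#' Normalized mutual information between gradient-magnitude feature images
#' of each source and of the fused image (256-bin joint histograms, each
#' feature image min-max scaled), averaged over the sources:
#' \deqn{FMI = \mathrm{mean}_s \; 2 I(s; F) / (H(s) + H(F)).}
#' Bounded in \[0, 1\]; maximal when the fused image carries exactly the
#' sources' gradient structure.
#'
#' @inheritParams metricCE
#' @return scalar in \[0, 1\].
#' @export
metricFMI <- function(A, B, F, sources = NULL) {
    srcs <- if (is.null(sources)) list(A, B) else sources
    feat <- function(img) {
        s <- .sobel(.luminance(img))
        .minMax(sqrt(s$gx^2 + s$gy^2))
    }
    fF <- feat(F)
    mean(vapply(srcs, function(s) {
        fs <- feat(s)
        if (!identical(dim(fs), dim(fF)))
            stop("sources and fused image must have the same size")
        m <- .miBits(fs, fF)
        if (m$hx + m$hy == 0) return(1)
        2 * m$mi / (m$hx + m$hy)
    }, numeric(1)))
}

#' Score a fusion result with all six metrics
#'
#' Computes Q_AB/F, SSIM, VIF, FMI, SF and CE for a fused image against
#' its two sources (SSIM and VIF are averaged over the two sources). All
#' images are reduced to luminance.
#'
#' @inheritParams metricCE
#' @param csv optional path; when given, the score row is appended as CSV
#'   (with a header if the file does not yet exist).
#' @param id identifier written in the CSV row.
#' @return a one-row \code{data.frame} with columns \code{qabf, ssim, vif,
#'   fmi, sf, ce}.
#'
#' @examples
#' A <- matrix(runif(64^2), 64); scoreAll(A, A, A)
#' @export
scoreAll <- function(A, B, F, csv = NULL, id = NA_character_) {
    Al <- .luminance(A); Bl <- .luminance(B); Fl <- .luminance(F)
    out <- data.frame(
        qabf = metricQABF(Al, Bl, Fl),
        ssim = mean(c(metricSSIM(Al, Fl), metricSSIM(Bl, Fl))),
        vif = mean(c(metricVIF(Al, Fl), metricVIF(Bl, Fl))),
        fmi = metricFMI(Al, Bl, Fl),
        sf = metricSF(Fl),
        ce = metricCE(Al, Bl, Fl))
    if (!is.null(csv)) {
        row <- cbind(data.frame(id = id), out)
        utils::write.table(row, csv, sep = ",", row.names = FALSE,
                           col.names = !file.exists(csv), append = file.exists(csv))
    }
    out
}
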