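## Complexity-weighted saliency proxy and its reduction to the block grid.
##
## The fusion rule modulates each PCNN neuron's link strength by how
## visually salient its region is. The saliency field used here weights
## local complexity (entropy of the gray-level distribution in a small
## window) by local contrast (Gaussian-smoothed gradient magnitude), then
## rescales to [0, 1]; textured, high-contrast regions score high and the
## flat background scores ~0.

#' Complexity-weighted saliency of a grayscale image
#'
#' Computes a per-pixel saliency map in \[0, 1\] as the min-max-scaled
#' product of (i) local gray-level entropy over a square window and (ii)
#' the Gaussian-smoothed gradient magnitude. A constant image has no
#' structure anywhere and maps to uniform (zero) saliency.
#'
#' @param image numeric matrix in \[0, 1\] (reduce color images to
#'   luminance first, e.g. with the internal ITU-R 601 weights used across
#'   the package).
#' @param window odd integer side of the entropy window (default 7).
#' @param bins number of gray-level bins for the entropy term (default 32).
#' @param sigma standard deviation of the Gaussian used to smooth the
#'   gradient magnitude, in pixels.
#' @return numeric matrix of the same shape, values in \[0, 1\].
#'
#' @examples
#' s <- cwsSaliency(matrix(runif(64^2), 64))
#' range(s)
#' @export
cwsSaliency <- function(image, window = 7L, bins = 32L, sigma = 2) {
    .assertMatrix(image, "image")
    window <- as.integer(window); bins <- as.integer(bins)
    if (window < 3L || window %% 2L == 0L)
        stop("window must be an odd integer >= 3")
    ## local entropy via box-filtered bin indicators
    q <- pmin(pmax(floor(image * bins) + 1L, 1L), bins)
    total <- .boxSum(matrix(1, nrow(image), ncol(image)), window)
    ent <- matrix(0, nrow(image), ncol(image))
    for (b in seq_len(bins)) {
        cb <- .boxSum((q == b) * 1, window)
        p <- cb / total
        nz <- p > 0
        ent[nz] <- ent[nz] - p[nz] * log2(p[nz])
    }
    ## contrast: smoothed central-difference gradient magnitude
    g <- .sobel(image)
    gm <- sqrt(g$gx^2 + g$gy^2)
    size <- 2L * ceiling(3 * sigma) + 1L
    gm <- .gaussFilter(gm, size = size, sigma = sigma)
    .minMax(ent * gm)
}

#' Reduce a saliency field to per-block link strengths
#'
#' The PCNN runs one neuron per block, but saliency is a pixel field; the
#' link strength of block \eqn{(i, j)} is the mean saliency over that
#' block (zero-padded pixels, if any, count as zero saliency, consistent
#' with the zero-fill partition).
#'
#' @param saliency numeric matrix in \[0, 1\] (as from [cwsSaliency()]).
#' @param D block side.
#' @return numeric matrix of shape (blocks down) x (blocks across), values
#'   in \[0, 1\].
#' @export
blockLinkStrength <- function(saliency, D) {
    grid <- partitionBlocks(saliency, D)
    d <- dim(grid@blocks)
    apply(grid@blocks, c(3L, 4L), mean)
}
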