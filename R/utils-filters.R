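## Small image-filtering utilities shared across modules.
## Convention everywhere: images are numeric matrices (rows = y, origin
## top-left) or H x W x C arrays, intensities in [0, 1], 0-based pixel
## coordinates in the mathematics, 1-based R indexing in code.

#' @keywords internal
.assertMatrix <- function(x, what = "image") {
    if (!is.matrix(x) || !is.numeric(x) || length(x) == 0L)
        stop(what, " must be a non-empty numeric matrix")
    if (!all(is.finite(x)))
        stop(what, " contains non-finite values")
    invisible(TRUE)
}

## 1-D Gaussian kernel, normalized to sum 1.
.gaussKernel1d <- function(size, sigma) {
    half <- (size - 1) / 2
    x <- seq(-half, half, length.out = size)
    k <- exp(-x^2 / (2 * sigma^2))
    k / sum(k)
}

## Separable 2-D filtering with zero padding ("same" output size).
## The operator is self-adjoint for symmetric kernels, which the
## structural-similarity gradients rely on. Production path is compiled;
## .filterSepR is the pure-R reference kept as a test oracle.
.filterSep <- function(x, k) {
    .cppSepFilter(x, as.numeric(k))
}

.filterSepR <- function(x, k) {
    n <- length(k)
    half <- (n - 1L) %/% 2L
    nr <- nrow(x); nc <- ncol(x)
    ## filter along rows (vertical direction)
    out <- matrix(0, nr, nc)
    for (t in seq_len(n)) {
        off <- t - 1L - half
        src <- seq_len(nr) + off
        ok <- src >= 1L & src <= nr
        out[ok, ] <- out[ok, ] + k[t] * x[src[ok], ]
    }
    ## then along columns (horizontal direction)
    out2 <- matrix(0, nr, nc)
    for (t in seq_len(n)) {
        off <- t - 1L - half
        src <- seq_len(nc) + off
        ok <- src >= 1L & src <= nc
        out2[, ok] <- out2[, ok] + k[t] * out[, src[ok]]
    }
    out2
}

.gaussFilter <- function(x, size = 11L, sigma = 1.5) {
    .filterSep(x, .gaussKernel1d(size, sigma))
}

## Box-filter local sums via integral images; window w x w, zero padding.
.boxSum <- function(x, w) {
    half <- (w - 1L) %/% 2L
    nr <- nrow(x); nc <- ncol(x)
    pad <- matrix(0, nr + 2L * half, nc + 2L * half)
    pad[half + seq_len(nr), half + seq_len(nc)] <- x
    ii <- apply(apply(pad, 2L, cumsum), 1L, cumsum)  # transposed integral image
    ii <- t(ii)
    ii <- rbind(0, cbind(0, ii))
    r1 <- seq_len(nr); c1 <- seq_len(nc)
    ii[r1 + w, c1 + w, drop = FALSE] - ii[r1, c1 + w, drop = FALSE] -
        ii[r1 + w, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

## Sobel derivatives; returns list(gx, gy) with zero padding at borders.
.sobel <- function(x) {
    shift <- function(m, dr, dc) {
        nr <- nrow(m); nc <- ncol(m)
        out <- matrix(0, nr, nc)
        rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
        okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
        out[okr, okc] <- m[rs[okr], cs[okc]]
        out
    }
    ## gx: horizontal derivative, gy: vertical derivative
    gx <- (shift(x, 0, 1) - shift(x, 0, -1)) * 2 +
        (shift(x, 1, 1) - shift(x, 1, -1)) +
        (shift(x, -1, 1) - shift(x, -1, -1))
    gy <- (shift(x, 1, 0) - shift(x, -1, 0)) * 2 +
        (shift(x, 1, 1) - shift(x, -1, 1)) +
        (shift(x, 1, -1) - shift(x, -1, -1))
    list(gx = gx, gy = gy)
}

## Min-max scaling to [0, 1]; a constant input maps to all zeros.
.minMax <- function(x) {
    rng <- range(x)
    if (rng[2] - rng[1] < .Machine$double.eps) return(array(0, dim(x) %||% length(x)))
    (x - rng[1]) / (rng[2] - rng[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## session-level once-only diagnostics (e.g. reduced MS-SSIM scale count),
## so tight loops do not repeat the same note thousands of times
.pkgNotes <- new.env(parent = emptyenv())
.noteOnce <- function(key, ...) {
    if (!isTRUE(.pkgNotes[[key]])) {
        .pkgNotes[[key]] <- TRUE
        message(...)
    }
    invisible(NULL)
}

## ITU-R BT.601 luminance of a 3-channel array; matrices pass through.
.luminance <- function(img) {
    if (is.matrix(img)) return(img)
    if (length(dim(img)) == 3L && dim(img)[3] == 3L)
        return(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
    stop("expected a matrix or an H x W x 3 array")
}

## Evaluate an expression under a private RNG stream, restoring the
## caller's .Random.seed afterwards.
.withSeed <- function(seed, expr) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    expr
}
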