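## PNG image I/O and color handling. Images are matrices (grayscale) or
## H x W x 3 arrays (color), float in [0, 1]; quantization to 8 bits
## happens only at the file boundary.

#' Load a PNG image
#'
#' Reads a PNG into a float image in \[0, 1\]. Grayscale files come back
#' as a matrix, color files as an \code{H x W x 3} array (an alpha
#' channel, if present, is dropped).
#'
#' @param path path to a PNG file.
#' @return numeric matrix or \code{H x W x 3} array.
#' @export
loadImage <- function(path) {
    if (!file.exists(path))
        stop("cannot read image: no such file: ", path)
    img <- tryCatch(png::readPNG(path),
                    error = function(e)
                        stop("cannot read image ", path, ": ",
                             conditionMessage(e)))
    if (length(dim(img)) == 3L) {
        if (dim(img)[3] == 2L) img <- img[, , 1L]          # gray + alpha
        else if (dim(img)[3] >= 4L) img <- img[, , 1:3]     # drop alpha
    }
    img
}

#' Save an image as 8-bit PNG
#'
#' @param img numeric matrix or \code{H x W x 3} array in \[0, 1\].
#' @param path destination path.
#' @return the path, invisibly.
#' @export
saveImage <- function(img, path) {
    if (any(img < 0) || any(img > 1)) stop("img must lie in [0, 1]")
    png::writePNG(img, path)
    invisible(path)
}

#' Prepare an image for the network
#'
#' The network consumes 3-channel inputs: a grayscale matrix is replicated
#' across three channels; a 3-channel array passes through unchanged.
#'
#' @param image numeric matrix or \code{H x W x 3} array.
#' @return numeric \code{H x W x 3} array.
#' @export
toNetworkInput <- function(image) {
    if (is.matrix(image)) {
        out <- array(0, c(dim(image), 3L))
        out[, , 1] <- image; out[, , 2] <- image; out[, , 3] <- image
        return(out)
    }
    if (length(dim(image)) == 3L && dim(image)[3] == 3L) return(image)
    stop("image must be a matrix or an H x W x 3 array")
}

#' Convert between RGB, HSV and YUV
#'
#' Standard conversions (HSV per the usual hexcone model; YUV per ITU-R
#' BT.601). Round trips RGB -> X -> RGB are accurate to well under 1e-3.
#'
#' @param image numeric \code{H x W x 3} array.
#' @param to target space: \code{"RGB"}, \code{"HSV"} or \code{"YUV"}.
#' @param from space of the input (default \code{"RGB"}).
#' @return numeric \code{H x W x 3} array in the target space. HSV hue is
#'   stored as a fraction of a turn in \[0, 1).
#' @export
convertColorspace <- function(image, to, from = "RGB") {
    spaces <- c("RGB", "HSV", "YUV")
    if (!(to %in% spaces)) stop("unknown target colorspace: ", to)
    if (!(from %in% spaces)) stop("unknown source colorspace: ", from)
    if (length(dim(image)) != 3L || dim(image)[3] != 3L)
        stop("image must be an H x W x 3 array")
    if (from == to) return(image)
    rgb <- switch(from, RGB = image, HSV = .hsv2rgb(image),
                  YUV = .yuv2rgb(image))
    switch(to, RGB = rgb, HSV = .rgb2hsv(rgb), YUV = .rgb2yuv(rgb))
}

.rgb2hsv <- function(img) {
    d <- dim(img)
    m <- grDevices::rgb2hsv(r = as.vector(img[, , 1]),
                            g = as.vector(img[, , 2]),
                            b = as.vector(img[, , 3]), maxColorValue = 1)
    out <- array(0, d)
    out[, , 1] <- m[1, ]; out[, , 2] <- m[2, ]; out[, , 3] <- m[3, ]
    out
}

.hsv2rgb <- function(img) {
    h <- as.vector(img[, , 1]) * 6
    s <- as.vector(img[, , 2]); v <- as.vector(img[, , 3])
    i <- floor(h) %% 6
    f <- h - floor(h)
    p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
    r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
         ifelse(i == 3, p, ifelse(i == 4, t, v)))))
    g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
         ifelse(i == 3, q, ifelse(i == 4, p, p)))))
    b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
         ifelse(i == 3, v, ifelse(i == 4, v, q)))))
    out <- array(0, dim(img))
    out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
    out
}

.rgb2yuv <- function(img) {
    r <- img[, , 1]; g <- img[, , 2]; b <- img[, , 3]
    yy <- 0.299 * r + 0.587 * g + 0.114 * b
    out <- array(0, dim(img))
    out[, , 1] <- yy
    out[, , 2] <- 0.492 * (b - yy)
    out[, , 3] <- 0.877 * (r - yy)
    out
}

.yuv2rgb <- function(img) {
    yy <- img[, , 1]; u <- img[, , 2]; v <- img[, , 3]
    r <- yy + v / 0.877
    b <- yy + u / 0.492
    g <- (yy - 0.299 * r - 0.114 * b) / 0.587
    out <- array(0, dim(img))
    out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
    out
}
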