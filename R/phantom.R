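## Seeded co-registered brain-like phantoms: a textured grayscale
## structural (MR/CT-like) image and a smooth pseudo-colored functional
## (PET/SPECT-like) image sharing one brain mask, so the whole pipeline is
## testable offline. The phantoms emulate the working corpus's image
## properties (256 x 256, 8-bit PNG on disk, float in [0, 1] in memory);
## they make no claim of anatomical realism.

## elliptical brain geometry derived deterministically from the seed
.brainGeometry <- function(size, seed) {
    .withSeed(seed, {
        cy <- size * (0.5 + runif(1, -0.02, 0.02))
        cx <- size * (0.5 + runif(1, -0.02, 0.02))
        ry <- size * (0.40 + runif(1, -0.02, 0.02))
        rx <- size * (0.34 + runif(1, -0.02, 0.02))
        list(cy = cy, cx = cx, ry = ry, rx = rx)
    })
}

.ellipseField <- function(size, geom) {
    y <- matrix(seq_len(size), size, size)
    x <- t(y)
    sqrt(((y - geom$cy) / geom$ry)^2 + ((x - geom$cx) / geom$rx)^2)
}

#' Structural (MR-like) brain phantom
#'
#' A grayscale anatomy phantom: a bright elliptical skull ring, band-pass
#' filtered noise texture standing in for cortical structure, two dark
#' ventricle-like lobes, and optionally a bright lesion disc. Values are
#' in \[0, 1\] and the image is deterministic under \code{(size, seed)}.
#' The brain-mask geometry, derived from the seed, travels in the
#' \code{"meta"} attribute so a functional phantom can be co-registered.
#'
#' @param size image side in pixels, at least 64 (default 256).
#' @param seed integer seed.
#' @param lesion \code{NULL} or \code{list(center = c(y, x), radius = r)}
#'   in pixel units; a bright disc is blended in at that location.
#' @return numeric \code{size x size} matrix with attribute \code{"meta"}.
#' @export
makeStructural <- function(size = 256L, seed = 1L, lesion = NULL) {
    size <- as.integer(size)
    if (size < 64L) stop("size must be at least 64")
    seed <- as.integer(seed)
    geom <- .brainGeometry(size, seed)
    r <- .ellipseField(size, geom)
    brain <- r <= 1
    skull <- r > 0.92 & r <= 1

    img <- .withSeed(seed + 1L, {
        noise <- matrix(rnorm(size^2), size)
        fine <- .gaussFilter(noise, 9L, 1.5)
        coarse <- .gaussFilter(noise, 25L, 6)
        tex <- fine - coarse                      # band-pass texture
        tex <- tex / max(abs(tex))
        base <- matrix(0, size, size)
        base[brain] <- 0.55 + 0.18 * tex[brain]
        base[skull] <- 0.92
        ## two dark ventricle lobes flanking the midline
        for (sgn in c(-1, 1)) {
            vy <- geom$cy - 0.08 * geom$ry
            vx <- geom$cx + sgn * 0.22 * geom$rx
            y <- matrix(seq_len(size), size, size); x <- t(y)
            vr <- sqrt(((y - vy) / (0.28 * geom$ry))^2 +
                       ((x - vx) / (0.14 * geom$rx))^2)
            vent <- vr <= 1 & brain & !skull
            base[vent] <- base[vent] * 0.3
        }
        base
    })
    if (!is.null(lesion)) {
        y <- matrix(seq_len(size), size, size); x <- t(y)
        d <- sqrt((y - lesion$center[1])^2 + (x - lesion$center[2])^2)
        disc <- d <= lesion$radius & brain
        img[disc] <- 0.95
    }
    img <- pmin(pmax(img, 0), 1)
    attr(img, "meta") <- list(seed = seed, size = size, geom = geom,
                              lesion = lesion)
    img
}

## hot-iron color map: black -> red -> yellow -> white
.hotIron <- function(a) {
    r <- pmin(pmax(3 * a, 0), 1)
    g <- pmin(pmax(3 * a - 1, 0), 1)
    b <- pmin(pmax(3 * a - 2, 0), 1)
    list(r = r, g = g, b = b)
}

#' Functional (PET/SPECT-like) brain phantom
#'
#' A 3-channel pseudo-colored activity phantom co-registered with a
#' structural phantom: two to four smooth Gaussian activity blobs (plus
#' one overlapping the lesion when the structural phantom has one), mapped
#' through a hot-iron color map and masked to the shared brain region.
#'
#' @param meta the \code{"meta"} attribute of a [makeStructural()] result.
#' @param seed integer seed for the blob layout.
#' @return numeric \code{size x size x 3} array in \[0, 1\].
#' @export
makeFunctional <- function(meta, seed = 1L) {
    if (is.null(meta$size) || is.null(meta$geom))
        stop("meta must come from makeStructural")
    size <- meta$size
    geom <- meta$geom
    r <- .ellipseField(size, geom)
    brain <- r <= 0.92   # interior, inside the skull ring
    y <- matrix(seq_len(size), size, size); x <- t(y)

    act <- .withSeed(as.integer(seed) + 101L, {
        nBlob <- sample(2:4, 1L)
        a <- matrix(0, size, size)
        for (i in seq_len(nBlob)) {
            theta <- runif(1, 0, 2 * pi)
            rad <- runif(1, 0.15, 0.6)
            by <- geom$cy + rad * geom$ry * sin(theta)
            bx <- geom$cx + rad * geom$rx * cos(theta)
            sd <- size * runif(1, 0.05, 0.1)
            amp <- runif(1, 0.6, 1)
            a <- a + amp * exp(-((y - by)^2 + (x - bx)^2) / (2 * sd^2))
        }
        a
    })
    if (!is.null(meta$lesion))
        act <- act + exp(-((y - meta$lesion$center[1])^2 +
                           (x - meta$lesion$center[2])^2) /
                             (2 * (1.5 * meta$lesion$radius)^2))
    act <- act / max(act)
    act[!brain] <- 0
    ch <- .hotIron(act)
    out <- array(0, c(size, size, 3L))
    out[, , 1] <- ch$r; out[, , 2] <- ch$g; out[, , 3] <- ch$b
    pmin(pmax(out, 0), 1)
}

#' A co-registered structural/functional phantom pair
#'
#' @inheritParams makeStructural
#' @param lesion as in [makeStructural()]; the default \code{"auto"}
#'   includes a lesion for every second seed.
#' @return a [PhantomPair-class].
#' @export
makePhantomPair <- function(size = 256L, seed = 1L, lesion = "auto") {
    seed <- as.integer(seed)
    if (identical(lesion, "auto")) {
        lesion <- if (seed %% 2L == 0L)
            list(center = round(c(0.38, 0.6) * size), radius = size * 0.04)
        else NULL
    }
    s <- makeStructural(size, seed, lesion)
    meta <- attr(s, "meta")
    f <- makeFunctional(meta, seed)
    attr(s, "meta") <- NULL
    new("PhantomPair", structural = s, functional = f, meta = meta)
}

#' A reproducible dataset of phantom pairs
#'
#' Generates \code{n} phantom pairs under independent sub-seeds derived
#' from \code{seed}, standing in for a training corpus.
#'
#' @param n number of pairs, at least 1.
#' @param size image side in pixels.
#' @param seed integer master seed.
#' @return list of [PhantomPair-class] objects.
#' @export
makeDataset <- function(n, size = 256L, seed = 1L) {
    if (length(n) != 1L || n < 1) stop("n must be >= 1")
    lapply(seq_len(n), function(i)
        makePhantomPair(size, seed = (as.integer(seed) + 7919L * i) %%
                            .Machine$integer.max))
}

#' Tri-modal phantom triple
#'
#' Three co-registered modalities sharing one brain geometry: a CT-like
#' image (bright skull, flat interior), an MR-like image (dim skull,
#' textured interior) and a PET-like pseudo-colored activity image.
#'
#' @inheritParams makeStructural
#' @return list with elements \code{ct} (matrix), \code{mri} (matrix) and
#'   \code{pet} (\code{size x size x 3} array).
#' @export
makeTriModal <- function(size = 256L, seed = 1L) {
    size <- as.integer(size)
    if (size < 64L) stop("size must be at least 64")
    seed <- as.integer(seed)
    mri <- makeStructural(size, seed)
    meta <- attr(mri, "meta")
    geom <- meta$geom
    r <- .ellipseField(size, geom)
    brain <- r <= 1
    skull <- r > 0.92 & r <= 1
    ct <- matrix(0, size, size)
    ct[brain] <- 0.35
    ct[skull] <- 1
    ct <- .gaussFilter(ct, 5L, 0.8)          # slight partial-volume blur
    ct <- pmin(pmax(ct, 0), 1)
    mri2 <- mri
    mri2[skull] <- 0.3                        # bone is dim on MR
    attr(mri2, "meta") <- NULL
    pet <- makeFunctional(meta, seed)
    list(ct = ct, mri = mri2, pet = pet)
}
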