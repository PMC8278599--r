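#' @import methods
NULL

#' Regularized discrete Hahn polynomial basis
#'
#' An orthonormal table of regularized Hahn polynomial values
#' \eqn{\bar h_n^{(\alpha,\beta)}(x)} on the integer support
#' \eqn{x = 0, \dots, N-1}. Row \code{n+1} of \code{values} holds order
#' \eqn{n}; column \code{x+1} holds sample point \eqn{x}.
#'
#' @slot N integer, number of support points (and of polynomial orders).
#' @slot alpha,beta numeric Hahn shape parameters, both \eqn{> -1}.
#' @slot values numeric \code{N x N} matrix of basis values.
#'
#' @seealso [hahnBasis()], [hahnMoments2D()]
#' @exportClass HahnBasis
setClass("HahnBasis",
    representation(N = "integer", alpha = "numeric", beta = "numeric",
                   values = "matrix"),
    validity = function(object) {
        msg <- character()
        if (length(object@N) != 1L || object@N < 1L)
            msg <- c(msg, "N must be a single positive integer")
        if (object@alpha <= -1) msg <- c(msg, "alpha must be > -1")
        if (object@beta <= -1) msg <- c(msg, "beta must be > -1")
        if (!all(dim(object@values) == object@N))
            msg <- c(msg, "values must be an N x N matrix")
        if (!all(is.finite(object@values)))
            msg <- c(msg, "values must be finite")
        if (length(msg)) msg else TRUE
    })

#' Configuration of the simplified pulse-coupled neural network
#'
#' Parameters of the simplified PCNN used for fusion arbitration: the
#' feeding input is the external stimulus itself, the linking input sums
#' pulses of the 8-neighborhood through kernel \code{W}, internal activity
#' is \eqn{U = F (1 + \beta L)}, and the firing threshold decays as
#' \eqn{\theta(n) = e^{-\alpha_T}\theta(n-1) + V_T Y(n-1)}.
#'
#' @slot alphaT positive numeric, exponential threshold decay rate.
#' @slot VT positive numeric, threshold reset magnitude after a pulse.
#' @slot W numeric 3 x 3 linking kernel; the center entry must be 0.
#' @slot nIter positive integer, number of synchronous iterations.
#' @slot theta0 positive numeric, initial threshold.
#'
#' @seealso [pcnnConfig()], [pcnnFire()]
#' @exportClass PCNNConfig
setClass("PCNNConfig",
    representation(alphaT = "numeric", VT = "numeric", W = "matrix",
                   nIter = "integer", theta0 = "numeric"),
    validity = function(object) {
        msg <- character()
        if (object@alphaT <= 0) msg <- c(msg, "alphaT must be > 0")
        if (object@VT <= 0) msg <- c(msg, "VT must be > 0")
        if (object@theta0 <= 0) msg <- c(msg, "theta0 must be > 0")
        if (object@nIter < 1L) msg <- c(msg, "nIter must be >= 1")
        if (!all(dim(object@W) == c(3L, 3L)))
            msg <- c(msg, "W must be a 3 x 3 matrix")
        else if (object@W[2L, 2L] != 0)
            msg <- c(msg, "the center entry of W must be 0")
        if (length(msg)) msg else TRUE
    })

#' Result of a PCNN run
#'
#' @slot firingCounts integer matrix, per-neuron total number of pulses
#'   emitted over the run (the "firing times" statistic used to arbitrate
#'   between sources).
#' @slot firstFire integer matrix, iteration of the first pulse;
#'   \code{NA} for neurons that never fired.
#' @slot nIter integer, the number of iterations that were run.
#'
#' @seealso [pcnnFire()]
#' @exportClass PCNNResult
setClass("PCNNResult",
    representation(firingCounts = "matrix", firstFire = "matrix",
                   nIter = "integer"),
    validity = function(object) {
        msg <- character()
        if (!identical(dim(object@firingCounts), dim(object@firstFire)))
            msg <- c(msg, "firingCounts and firstFire must have equal dims")
        fc <- object@firingCounts
        if (any(fc < 0L) || any(fc > object@nIter))
            msg <- c(msg, "firingCounts must lie in [0, nIter]")
        ff <- object@firstFire
        if (any(!is.na(ff) & (ff < 1L | ff > object@nIter)))
            msg <- c(msg, "firstFire must lie in {1..nIter} or NA")
        if (length(msg)) msg else TRUE
    })

#' Zero-padded block partition of a 2-D map
#'
#' The source map is zero-padded on its bottom/right edges to a multiple of
#' the block side \code{D}, then tiled into \code{D x D} blocks.
#' Reassembling the blocks and stripping \code{padRows}/\code{padCols}
#' reproduces the source exactly.
#'
#' @slot blocks numeric array of dimension \code{c(D, D, nI, nJ)};
#'   \code{blocks[, , i, j]} is block \eqn{C_{ij}}.
#' @slot D integer block side.
#' @slot padRows,padCols integers, number of zero rows/columns appended.
#' @slot sourceDim integer(2), dimensions of the unpadded source map.
#'
#' @seealso [partitionBlocks()], [reassembleBlocks()]
#' @exportClass BlockGrid
setClass("BlockGrid",
    representation(blocks = "array", D = "integer", padRows = "integer",
                   padCols = "integer", sourceDim = "integer"),
    validity = function(object) {
        msg <- character()
        d <- dim(object@blocks)
        if (length(d) != 4L || d[1] != object@D || d[2] != object@D)
            msg <- c(msg, "blocks must be a D x D x nI x nJ array")
        if (object@padRows < 0L || object@padCols < 0L)
            msg <- c(msg, "padding must be nonnegative")
        if (length(object@sourceDim) != 2L)
            msg <- c(msg, "sourceDim must have length 2")
        if (length(msg) == 0L) {
            if (d[3] * object@D != object@sourceDim[1] + object@padRows ||
                d[4] * object@D != object@sourceDim[2] + object@padCols)
                msg <- c(msg, "block grid inconsistent with sourceDim + padding")
        }
        if (length(msg)) msg else TRUE
    })

#' Convolutional feature-extraction / image-reconstruction network
#'
#' A five-layer convolutional network: a three-layer feature extractor
#' (64 kernels of 7x7, 5x5 and 3x3, stride 1, padding 3/2/1, ReLU) that
#' preserves spatial size, and a two-layer reconstructor (64 kernels of
#' 3x3 with padding 1 and ReLU, then 3 kernels of 1x1 with a sigmoid) that
#' maps 64-channel features back to a 3-channel image in (0, 1).
#'
#' @slot layers list of 5 layers, each \code{list(W, b, pad, activation)}
#'   with \code{W} a \code{k x k x Cin x Cout} array.
#' @slot seed integer seed the initial weights were drawn under.
#' @slot lossHistory numeric, per-epoch mean training loss (empty until
#'   trained).
#'
#' @seealso [buildNetwork()], [trainAutoencoder()]
#' @exportClass FusionNetwork
setClass("FusionNetwork",
    representation(layers = "list", seed = "integer",
                   lossHistory = "numeric"),
    validity = function(object) {
        spec <- .networkSpec()
        if (length(object@layers) != length(spec))
            return(sprintf("network must have %d layers", length(spec)))
        for (i in seq_along(spec)) {
            L <- object@layers[[i]]
            s <- spec[[i]]
            dw <- dim(L$W)
            if (!identical(dw, c(s$k, s$k, s$cin, s$cout)))
                return(sprintf(
                    "layer %d weights must be %d x %d x %d x %d", i,
                    s$k, s$k, s$cin, s$cout))
            if (length(L$b) != s$cout)
                return(sprintf("layer %d bias must have length %d", i, s$cout))
            if (L$pad != s$pad)
                return(sprintf("layer %d padding must be %d", i, s$pad))
        }
        TRUE
    })

#' A co-registered structural/functional phantom pair
#'
#' @slot structural numeric matrix in [0, 1]; MR-like anatomy phantom
#'   (skull ring, cortical texture, ventricles, optional lesion).
#' @slot functional numeric H x W x 3 array in [0, 1]; smooth pseudo-colored
#'   activity phantom masked to the same brain region.
#' @slot meta list with at least \code{seed}, \code{size}, the brain-mask
#'   geometry, and lesion parameters (or NULL).
#'
#' @seealso [makePhantomPair()], [makeDataset()]
#' @exportClass PhantomPair
setClass("PhantomPair",
    representation(structural = "matrix", functional = "array",
                   meta = "list"),
    validity = function(object) {
        msg <- character()
        ds <- dim(object@structural); df <- dim(object@functional)
        if (length(df) != 3L || df[3] != 3L)
            msg <- c(msg, "functional must be an H x W x 3 array")
        else if (!all(ds == df[1:2]))
            msg <- c(msg, "structural and functional sizes differ")
        rng <- range(object@structural, object@functional)
        if (rng[1] < 0 || rng[2] > 1)
            msg <- c(msg, "intensities must lie in [0, 1]")
        if (is.null(object@meta$seed) || is.null(object@meta$size))
            msg <- c(msg, "meta must carry seed and size")
        if (length(msg)) msg else TRUE
    })

setMethod("show", "HahnBasis", function(object) {
    cat(sprintf(
        "HahnBasis: N = %d, alpha = %g, beta = %g\n", object@N,
        object@alpha, object@beta))
    g <- tcrossprod(object@values)
    cat(sprintf("  max |Gram - I| = %.3g\n",
                max(abs(g - diag(object@N)))))
})

setMethod("show", "PCNNConfig", function(object) {
    cat(sprintf(
        "PCNNConfig: alphaT = %g, VT = %g, theta0 = %g, nIter = %d\n",
        object@alphaT, object@VT, object@theta0, object@nIter))
})

setMethod("show", "PCNNResult", function(object) {
    d <- dim(object@firingCounts)
    cat(sprintf(
        "PCNNResult: %d x %d neurons, %d iterations, counts in [%d, %d]\n",
        d[1], d[2], object@nIter, min(object@firingCounts),
        max(object@firingCounts)))
})

setMethod("show", "BlockGrid", function(object) {
    d <- dim(object@blocks)
    cat(sprintf(
        "BlockGrid: %d x %d blocks of %d x %d (source %d x %d, pad %d/%d)\n",
        d[3], d[4], object@D, object@D, object@sourceDim[1],
        object@sourceDim[2], object@padRows, object@padCols))
})

setMethod("show", "FusionNetwork", function(object) {
    cat("FusionNetwork (3-layer extractor + 2-layer reconstructor)\n")
    for (i in seq_along(object@layers)) {
        d <- dim(object@layers[[i]]$W)
        cat(sprintf("  CONV%d: %d kernels %dx%d, stride 1, pad %d, %s\n",
                    i, d[4], d[1], d[2], object@layers[[i]]$pad,
                    object@layers[[i]]$activation))
    }
    if (length(object@lossHistory))
        cat(sprintf("  trained %d epochs, final mean loss %.4f\n",
                    length(object@lossHistory),
                    tail(object@lossHistory, 1L)))
    else cat("  untrained (seeded random weights)\n")
})

setMethod("show", "PhantomPair", function(object) {
    cat(sprintf(
        "PhantomPair: %d x %d, seed %d, lesion: %s\n",
        nrow(object@structural), ncol(object@structural),
        object@meta$seed,
        if (is.null(object@meta$lesion)) "none" else "present"))
})
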