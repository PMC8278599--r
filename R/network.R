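## The convolutional feature-extraction and image-reconstruction modules.

#' Build the fusion network
#'
#' Constructs the five-layer convolutional network: a feature extractor of
#' three stride-1 layers (64 kernels of 7x7/pad 3, 5x5/pad 2, 3x3/pad 1,
#' each followed by ReLU) whose padding arithmetic preserves spatial size,
#' and a reconstructor of two layers (64 kernels of 3x3/pad 1 with ReLU,
#' then 3 kernels of 1x1 with a sigmoid squashing the output into (0, 1),
#' as the pixel cross-entropy loss requires).
#'
#' Weights are drawn under the given seed: He-scaled Gaussians before ReLU
#' layers and a Xavier-scaled Gaussian before the sigmoid output; biases
#' start at zero, so a zero input produces zero features through the
#' extractor. Builds with equal seeds are bit-identical. Externally
#' trained weights (e.g. a pretrained first layer) can be injected with
#' \code{setLayerWeights()}.
#'
#' @param seed integer seed for weight initialization.
#' @return a [FusionNetwork-class].
#'
#' @examples
#' net <- buildNetwork(seed = 1)
#' dim(extractFeatures(net, array(0.5, c(32, 32, 3))))
#' @export
buildNetwork <- function(seed = 1L) {
    spec <- .networkSpec()
    layers <- .withSeed(as.integer(seed), {
        lapply(spec, function(s) {
            fanIn <- s$k * s$k * s$cin
            sd <- if (s$activation == "relu") sqrt(2 / fanIn)
                  else sqrt(1 / fanIn)
            list(W = array(rnorm(fanIn * s$cout, sd = sd),
                           c(s$k, s$k, s$cin, s$cout)),
                 b = numeric(s$cout), pad = s$pad,
                 activation = s$activation)
        })
    })
    new("FusionNetwork", layers = layers, seed = as.integer(seed),
        lossHistory = numeric())
}

#' Replace the weights of one layer
#'
#' @param net a [FusionNetwork-class].
#' @param index layer index (1-5).
#' @param W weight array of the layer's exact shape.
#' @param b bias vector (optional; defaults to keeping the current bias).
#' @return the modified network.
#' @export
setLayerWeights <- function(net, index, W, b = NULL) {
    stopifnot(is(net, "FusionNetwork"))
    L <- net@layers[[index]]
    if (!identical(dim(W), dim(L$W)))
        stop("W has the wrong shape for layer ", index)
    L$W <- W
    if (!is.null(b)) {
        if (length(b) != length(L$b))
            stop("b has the wrong length for layer ", index)
        L$b <- b
    }
    net@layers[[index]] <- L
    validObject(net)
    net
}

#' Extract 64-channel features from an image
#'
#' Runs the three extractor layers. Spatial dimensions are preserved for
#' any input size; grayscale images must be replicated to three channels
#' first (see [toNetworkInput()]).
#'
#' @param net a [FusionNetwork-class].
#' @param image numeric \code{H x W x 3} array in \[0, 1\].
#' @return numeric \code{H x W x 64} feature array.
#' @export
extractFeatures <- function(net, image) {
    stopifnot(is(net, "FusionNetwork"))
    if (length(dim(image)) != 3L || dim(image)[3] != 3L)
        stop("image must be an H x W x 3 array (see toNetworkInput)")
    if (!all(is.finite(image))) stop("image contains non-finite values")
    .netForward(net, image, layers = 1:3)$out
}

#' Reconstruct a 3-channel image from fused features
#'
#' Runs the two reconstructor layers; the final sigmoid keeps the output
#' in (0, 1).
#'
#' @param net a [FusionNetwork-class].
#' @param features numeric \code{H x W x 64} array.
#' @return numeric \code{H x W x 3} array in (0, 1).
#' @export
reconstructImage <- function(net, features) {
    stopifnot(is(net, "FusionNetwork"))
    if (length(dim(features)) != 3L || dim(features)[3] != 64L)
        stop("features must be an H x W x 64 array")
    .netForward(net, features, layers = 4:5)$out
}
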