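## The end-to-end fusion pipeline: extract features of each co-registered
## source, arbitrate block-wise (Hahn-moment potential energy + PCNN),
## reconstruct a 3-channel fused image, optionally score it.

#' Default pipeline configuration
#'
#' All tunable knobs of the fusion pipeline in one list: block side,
#' Hahn basis parameters, PCNN parameters and saliency parameters. Values
#' can be overridden selectively via \code{...}, or loaded from a YAML
#' file with [readFusionConfig()].
#'
#' @param ... named overrides of the defaults.
#' @return named list with elements \code{blockSize}, \code{hahnAlpha},
#'   \code{hahnBeta}, \code{pcnn} (list: \code{alphaT, VT, nIter, theta0})
#'   and \code{saliency} (list: \code{window, bins}).
#' @export
fusionConfig <- function(...) {
    cfg <- list(blockSize = 8L, hahnAlpha = 0, hahnBeta = 0,
                pcnn = list(alphaT = 0.2, VT = 20, nIter = 200L,
                            theta0 = 1),
                saliency = list(window = 7L, bins = 32L))
    over <- list(...)
    for (nm in names(over)) {
        if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
            cfg[[nm]][names(over[[nm]])] <- over[[nm]]
        else cfg[[nm]] <- over[[nm]]
    }
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [fusionConfig()] keys.
#' @return a complete configuration list (missing keys take defaults).
#' @export
readFusionConfig <- function(path) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configuration requires the yaml package")
    do.call(fusionConfig, yaml::read_yaml(path))
}

#' Fuse two or three co-registered images
#'
#' Runs the full pipeline: each input (grayscale inputs replicated to 3
#' channels) passes through the feature extractor; the feature stacks are
#' fused block-wise, with each source's link-strength field computed from
#' the saliency of the source image itself; the reconstructor maps the
#' fused features to a 3-channel image. With \code{score = TRUE} (pairwise
#' mode only) the six quality metrics of the fused image against the
#' sources are attached.
#'
#' @param inputs list of 2 (pairwise) or 3 (tri-modal) images — numeric
#'   matrices / \code{H x W x 3} arrays in \[0, 1\], or paths to PNG
#'   files. All must have equal spatial size.
#' @param net a [FusionNetwork-class], normally trained with
#'   [trainAutoencoder()].
#' @param config a configuration list from [fusionConfig()].
#' @param score compute the metric report (only for 2 sources).
#' @param outputPath optional path; the fused image is written there as
#'   PNG.
#' @return list with elements \code{fused} (\code{H x W x 3} array),
#'   \code{decision} (per-block winning-source index, 0 = tie) and, when
#'   scored, \code{scores} (one-row data.frame).
#'
#' @examples
#' \donttest{
#' p <- makePhantomPair(size = 64, seed = 1)
#' net <- buildNetwork(seed = 1)
#' r <- runFusion(list(structural(p), functional(p)), net, score = FALSE)
#' dim(r$fused)
#' }
#' @export
runFusion <- function(inputs, net, config = fusionConfig(), score = TRUE,
                      outputPath = NULL) {
    if (!is.list(inputs) || length(inputs) < 2L || length(inputs) > 3L)
        stop("inputs must be a list of 2 or 3 images or paths")
    imgs <- lapply(inputs, function(x)
        if (is.character(x)) loadImage(x) else x)
    sizes <- lapply(imgs, function(x) dim(x)[1:2])
    for (s in sizes) if (!identical(s, sizes[[1L]]))
        stop("all inputs must have the same spatial size")
    stopifnot(is(net, "FusionNetwork"))

    netIn <- lapply(imgs, toNetworkInput)
    feats <- lapply(netIn, function(x) extractFeatures(net, x))
    sal <- lapply(imgs, function(x)
        cwsSaliency(.luminance(x), window = config$saliency$window,
                    bins = config$saliency$bins))
    pc <- pcnnConfig(alphaT = config$pcnn$alphaT, VT = config$pcnn$VT,
                     nIter = config$pcnn$nIter, theta0 = config$pcnn$theta0)
    fusedFeats <- fuseFeatureMaps(feats, D = config$blockSize,
                                  alpha = config$hahnAlpha,
                                  beta = config$hahnBeta,
                                  config = pc, saliency = sal)
    decision <- attr(fusedFeats, "decision")
    attr(fusedFeats, "decision") <- NULL
    fused <- reconstructImage(net, fusedFeats)
    fused <- pmin(pmax(fused, 0), 1)
    out <- list(fused = fused, decision = decision)
    if (score && length(imgs) == 2L)
        out$scores <- scoreAll(imgs[[1L]], imgs[[2L]], fused)
    if (!is.null(outputPath)) saveImage(fused, outputPath)
    out
}
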