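## Desk-scale autoencoder training: the extractor and reconstructor are
## trained end to end to reproduce their input under the composite loss
## (the fusion module is decision-only and is inserted at inference).

.adamInit <- function(layers) {
    lapply(layers, function(L)
        list(mW = array(0, dim(L$W)), vW = array(0, dim(L$W)),
             mb = numeric(length(L$b)), vb = numeric(length(L$b))))
}

#' Train the network as an autoencoder
#'
#' Minimizes the composite loss ([lossTotal()]) of the
#' extractor-reconstructor composition against its own input, by Adam on
#' mini-batches. All randomness (shuffling) is governed by \code{seed};
#' runs with identical seed, data and configuration are bit-identical.
#' With \code{epochs = 0} the network is returned unchanged (with an empty
#' loss history).
#'
#' @param net a [FusionNetwork-class] (e.g. from [buildNetwork()]).
#' @param images list of \code{H x W x 3} arrays in \[0, 1\]; grayscale
#'   matrices are accepted and replicated to 3 channels.
#' @param epochs number of passes over the data (default 50).
#' @param batchSize mini-batch size (default 8).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed integer seed for shuffling.
#' @param lossWeights numeric(3), weights of the cross-entropy, MS-SSIM
#'   and TV terms.
#' @param verbose print the per-epoch mean loss.
#' @return the trained network; \code{lossHistory(net)} holds the
#'   per-epoch mean total loss (see Details for what each entry reflects).
#'
#' @details The loss history records, for each epoch, the mean of the
#' batch losses evaluated *before* each update in that epoch; its first
#' element therefore reflects the initial weights and its last the
#' nearly-final weights.
#' @export
trainAutoencoder <- function(net, images, epochs = 50L, batchSize = 8L,
                             lr = 1e-3, seed = 1L,
                             lossWeights = c(1, 1, 1), verbose = FALSE) {
    stopifnot(is(net, "FusionNetwork"))
    if (!is.list(images) || length(images) < 1L)
        stop("images must be a non-empty list")
    images <- lapply(images, toNetworkInput)
    epochs <- as.integer(epochs)
    if (epochs < 0L) stop("epochs must be >= 0")
    if (epochs == 0L) return(net)

    layers <- net@layers
    opt <- .adamInit(layers)
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    step <- 0L
    history <- numeric(epochs)
    nImg <- length(images)

    order <- .withSeed(as.integer(seed), {
        lapply(seq_len(epochs), function(e) sample.int(nImg))
    })

    for (e in seq_len(epochs)) {
        idx <- order[[e]]
        starts <- seq(1L, nImg, by = batchSize)
        epochLoss <- 0
        for (s in starts) {
            batch <- idx[s:min(s + batchSize - 1L, nImg)]
            gW <- lapply(layers, function(L) array(0, dim(L$W)))
            gb <- lapply(layers, function(L) numeric(length(L$b)))
            batchLoss <- 0
            for (b in batch) {
                x <- images[[b]]
                ## fused forward + loss gradient + backward (compiled)
                st <- .cppNetStep(x, layers, function(out)
                    .totalLossGrad(x, out, lossWeights))
                batchLoss <- batchLoss + st$value
                for (i in seq_along(layers)) {
                    gW[[i]] <- gW[[i]] + st$dW[[i]]
                    gb[[i]] <- gb[[i]] + st$db[[i]]
                }
            }
            nb <- length(batch)
            step <- step + 1L
            for (i in seq_along(layers)) {
                dW <- gW[[i]] / nb; db <- gb[[i]] / nb
                o <- opt[[i]]
                o$mW <- beta1 * o$mW + (1 - beta1) * dW
                o$vW <- beta2 * o$vW + (1 - beta2) * dW^2
                o$mb <- beta1 * o$mb + (1 - beta1) * db
                o$vb <- beta2 * o$vb + (1 - beta2) * db^2
                mhW <- o$mW / (1 - beta1^step)
                vhW <- o$vW / (1 - beta2^step)
                mhb <- o$mb / (1 - beta1^step)
                vhb <- o$vb / (1 - beta2^step)
                layers[[i]]$W <- layers[[i]]$W - lr * mhW / (sqrt(vhW) + eps)
                layers[[i]]$b <- layers[[i]]$b - lr * mhb / (sqrt(vhb) + eps)
                opt[[i]] <- o
            }
            epochLoss <- epochLoss + batchLoss
        }
        history[e] <- epochLoss / nImg
        if (verbose)
            message(sprintf("epoch %3d  mean loss %.5f", e, history[e]))
    }
    net@layers <- layers
    net@lossHistory <- history
    net
}

#' Reconstruction fidelity of the autoencoder
#'
#' Convenience: passes each image through extractor and reconstructor and
#' returns the MS-SSIM between input and reconstruction.
#'
#' @param net a [FusionNetwork-class].
#' @param images list of images (any form [toNetworkInput()] accepts).
#' @return numeric vector of MS-SSIM values in (0, 1\].
#' @export
reconstructionFidelity <- function(net, images) {
    vapply(images, function(img) {
        x <- toNetworkInput(img)
        msSsim(x, reconstructImage(net, extractFeatures(net, x)))
    }, numeric(1))
}
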