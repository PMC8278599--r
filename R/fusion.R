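## Block-wise feature-map fusion: Hahn-moment potential energy as the PCNN
## stimulus, saliency-derived link strength, firing-count competition, and
## block selection with element-wise max on ties.

#' Fuse feature stacks by PCNN competition on Hahn-moment potential energy
#'
#' For each of \eqn{k \ge 2} co-registered feature stacks:
#' \enumerate{
#'   \item collapse the stack to an activity image (across-channel mean of
#'     absolute activations);
#'   \item partition the activity image into \code{D x D} blocks (zero
#'     fill) and compute each block's Hahn-moment potential energy;
#'   \item min-max normalize the PE maps jointly across sources to
#'     \[0, 1\] and feed each as the stimulus of a simplified PCNN whose
#'     per-neuron link strengths are the block means of that source's
#'     saliency field.
#' }
#' Each block of the output is copied, across all channels, from the
#' source whose neuron fired most; where firing counts tie, the
#' element-wise maximum of the tied sources' blocks is taken, which makes
#' the rule symmetric in its inputs and idempotent
#' (\code{fuseFeatureMaps(list(A, A))} returns \code{A} exactly).
#'
#' @param maps list of \eqn{k \ge 2} numeric arrays \code{H x W x C} (a
#'   matrix is treated as a single-channel stack), all of the same shape.
#' @param D block side (default 8).
#' @param alpha,beta Hahn basis parameters for the block transform.
#' @param config a [PCNNConfig-class] for the competition.
#' @param saliency optional list of per-source pixel saliency fields
#'   (\code{H x W}); by default the saliency of each source's activity
#'   image is used. Supply the source images' saliency to arbitrate on the
#'   originals rather than on feature activity.
#' @return a fused array of the same shape as each input (fused matrix if
#'   the inputs were matrices), together with the per-block winning-source
#'   index in attribute \code{"decision"} (0 = tie).
#'
#' @examples
#' A <- array(runif(16 * 16 * 2), c(16, 16, 2))
#' f <- fuseFeatureMaps(list(A, A), D = 8)
#' stopifnot(max(abs(f - A)) == 0)  # idempotent, exactly
#' @export
fuseFeatureMaps <- function(maps, D = 8L, alpha = 0, beta = 0,
                            config = pcnnConfig(), saliency = NULL) {
    if (!is.list(maps) || length(maps) < 2L)
        stop("maps must be a list of k >= 2 feature stacks")
    wasMatrix <- is.matrix(maps[[1L]])
    maps <- lapply(maps, function(m) {
        if (is.matrix(m)) m <- array(m, c(dim(m), 1L))
        if (length(dim(m)) != 3L) stop("each map must be H x W x C")
        m
    })
    dims <- dim(maps[[1L]])
    for (m in maps) if (!identical(dim(m), dims))
        stop("all feature stacks must have the same shape")
    if (!is.null(saliency) && length(saliency) != length(maps))
        stop("saliency must have one field per source")

    k <- length(maps)
    basis <- hahnBasis(D, alpha, beta)
    activity <- lapply(maps, function(m)
        apply(abs(m), c(1L, 2L), mean))
    grids <- lapply(activity, partitionBlocks, D = D)
    pe <- lapply(grids, .peMap, basis = basis)

    ## joint min-max normalization of PE across sources
    rng <- range(unlist(pe))
    stim <- lapply(pe, function(p) {
        if (rng[2] - rng[1] < .Machine$double.eps) p * 0
        else (p - rng[1]) / (rng[2] - rng[1])
    })

    betaMaps <- vector("list", k)
    for (s in seq_len(k)) {
        sal <- if (is.null(saliency)) cwsSaliency(activity[[s]])
               else saliency[[s]]
        betaMaps[[s]] <- blockLinkStrength(sal, D)
    }
    counts <- lapply(seq_len(k), function(s)
        firingCounts(pcnnFire(stim[[s]], betaMaps[[s]], config)))

    nI <- nrow(counts[[1L]]); nJ <- ncol(counts[[1L]])
    ## padded working copies of every stack
    padR <- nI * D - dims[1]; padC <- nJ * D - dims[2]
    padded <- lapply(maps, function(m) {
        out <- array(0, c(dims[1] + padR, dims[2] + padC, dims[3]))
        out[seq_len(dims[1]), seq_len(dims[2]), ] <- m
        out
    })
    fused <- array(0, dim(padded[[1L]]))
    decision <- matrix(0L, nI, nJ)
    for (i in seq_len(nI)) for (j in seq_len(nJ)) {
        cij <- vapply(counts, function(cc) cc[i, j], numeric(1))
        winners <- which(cij == max(cij))
        rows <- (i - 1L) * D + seq_len(D)
        cols <- (j - 1L) * D + seq_len(D)
        if (length(winners) == 1L) {
            fused[rows, cols, ] <- padded[[winners]][rows, cols, ]
            decision[i, j] <- winners
        } else {
            blk <- padded[[winners[1L]]][rows, cols, , drop = FALSE]
            for (w in winners[-1L])
                blk <- pmax(blk, padded[[w]][rows, cols, , drop = FALSE])
            fused[rows, cols, ] <- blk
        }
    }
    out <- fused[seq_len(dims[1]), seq_len(dims[2]), , drop = FALSE]
    if (wasMatrix) out <- out[, , 1L]
    attr(out, "decision") <- decision
    out
}
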