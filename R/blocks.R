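## Zero-padded block partition of 2-D maps.

#' Partition a map into D x D blocks with zero fill
#'
#' Pads the map with zeros on its bottom and right edges until both
#' dimensions are multiples of \code{D}, then tiles it into \code{D x D}
#' blocks \eqn{C_{ij}}. The amount of padding is recorded so the exact
#' source can be recovered.
#'
#' @param map numeric matrix.
#' @param D block side, an integer \eqn{\ge 2}.
#' @return a [BlockGrid-class].
#'
#' @examples
#' g <- partitionBlocks(matrix(1:100, 10), D = 8)  # padded to 16 x 16
#' padding(g)
#' @seealso [reassembleBlocks()]
#' @export
partitionBlocks <- function(map, D) {
    .assertMatrix(map, "map")
    if (length(D) != 1L || !is.finite(D) || D < 2 || D != round(D))
        stop("D must be a single integer >= 2")
    D <- as.integer(D)
    nr <- nrow(map); nc <- ncol(map)
    padR <- (D - nr %% D) %% D
    padC <- (D - nc %% D) %% D
    padded <- matrix(0, nr + padR, nc + padC)
    padded[seq_len(nr), seq_len(nc)] <- map
    nI <- (nr + padR) %/% D
    nJ <- (nc + padC) %/% D
    blocks <- array(0, c(D, D, nI, nJ))
    for (i in seq_len(nI)) for (j in seq_len(nJ))
        blocks[, , i, j] <- padded[(i - 1L) * D + seq_len(D),
                                   (j - 1L) * D + seq_len(D)]
    new("BlockGrid", blocks = blocks, D = D, padRows = as.integer(padR),
        padCols = as.integer(padC), sourceDim = c(nr, nc))
}

#' Reassemble a block grid into its source map
#'
#' Tiles the blocks back together and strips the zero padding, exactly
#' reproducing the matrix that was partitioned.
#'
#' @param grid a [BlockGrid-class].
#' @return numeric matrix with the original source dimensions.
#' @export
reassembleBlocks <- function(grid) {
    stopifnot(is(grid, "BlockGrid"))
    d <- dim(grid@blocks)
    D <- grid@D
    out <- matrix(0, d[3] * D, d[4] * D)
    for (i in seq_len(d[3])) for (j in seq_len(d[4]))
        out[(i - 1L) * D + seq_len(D), (j - 1L) * D + seq_len(D)] <-
            grid@blocks[, , i, j]
    out[seq_len(grid@sourceDim[1]), seq_len(grid@sourceDim[2]), drop = FALSE]
}

#' Potential energy of a Hahn moment matrix
#'
#' The block activity statistic of the fusion rule: the distance-weighted
#' absolute deviation of every Hahn moment from the leading moment,
#' \deqn{PE = \sum_{u,v} \frac{|H_{uv} - H_{11}|}
#'   {\sqrt{(u-1)^2 + (v-1)^2}},}
#' with 1-based order indices \eqn{u, v} and the \eqn{(1,1)} term (a 0/0
#' limit: zero deviation at zero distance) defined as 0. High-order
#' structure far from the DC moment contributes less; a block whose
#' moments all equal \eqn{H_{11}} (e.g. an all-zero or perfectly flat
#' block) has zero potential energy.
#'
#' @param moments numeric moment matrix (as from [hahnMoments2D()]).
#' @return a nonnegative scalar.
#'
#' @examples
#' potentialEnergy(matrix(c(1, 2, 3, 1), 2))  # |3-1|/1 + |2-1|/1 + 0 = 3
#' @export
potentialEnergy <- function(moments) {
    .assertMatrix(moments, "moments")
    u <- row(moments) - 1L
    v <- col(moments) - 1L
    dist <- sqrt(u^2 + v^2)
    dev <- abs(moments - moments[1L, 1L])
    dist[1L, 1L] <- 1  # (1,1) term is defined as 0; dev there is 0 anyway
    sum(dev / dist)
}

## PE map of a whole block grid under a given Hahn basis.
.peMap <- function(grid, basis) {
    d <- dim(grid@blocks)
    pe <- matrix(0, d[3], d[4])
    B <- basis@values
    for (i in seq_len(d[3])) for (j in seq_len(d[4])) {
        H <- B %*% grid@blocks[, , i, j] %*% t(B)
        pe[i, j] <- potentialEnergy(H)
    }
    pe
}
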