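## Simplified pulse-coupled neural network.
##
## Per iteration n (fully synchronous, initial Y = 0, theta(0) = theta0):
##   F       = S                               (feeding = stimulus)
##   L(n)    = sum_W Y(n-1)                    (8-neighborhood linking)
##   U(n)    = F * (1 + beta * L(n))           (internal activity)
##   theta(n)= exp(-alphaT) * theta(n-1) + VT * Y(n-1)
##   Y(n)    = [U(n) >= theta(n)]

#' Construct a PCNN configuration
#'
#' @param alphaT exponential decay rate of the firing threshold (> 0).
#' @param VT threshold reset magnitude added after each pulse (> 0); a
#'   large value enforces at most one pulse per threshold-decay cycle.
#' @param W 3 x 3 linking kernel over the 8-neighborhood; center must be 0.
#'   Default: inverse Euclidean distance weights.
#' @param nIter number of synchronous iterations.
#' @param theta0 initial threshold (> 0).
#' @return a [PCNNConfig-class] object.
#'
#' @examples
#' pcnnConfig(nIter = 50L)
#' @export
pcnnConfig <- function(alphaT = 0.2, VT = 20, W = NULL, nIter = 200L,
                       theta0 = 1) {
    if (is.null(W)) {
        s <- 1 / sqrt(2)
        W <- matrix(c(s, 1, s, 1, 0, 1, s, 1, s), 3L, 3L)
    }
    new("PCNNConfig", alphaT = alphaT, VT = VT, W = W,
        nIter = as.integer(nIter), theta0 = theta0)
}

## 8-neighborhood weighted sum of a binary pulse matrix, zero boundary.
.linkSum <- function(Y, W) {
    nr <- nrow(Y); nc <- ncol(Y)
    out <- matrix(0, nr, nc)
    for (dr in -1:1) for (dc in -1:1) {
        wgt <- W[dr + 2L, dc + 2L]
        if (wgt == 0) next
        rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
        okr <- rs >= 1L & rs <= nr; okc <- cs >= 1L & cs <= nc
        out[okr, okc] <- out[okr, okc] + wgt * Y[rs[okr], cs[okc]]
    }
    out
}

#' Run the simplified PCNN
#'
#' Iterates the simplified pulse-coupled neural network over a lattice of
#' neurons, one per entry of \code{stimulus}. Each neuron's feeding input
#' is its stimulus value; the linking input is the weighted sum of the
#' previous iteration's pulses over the 8-neighborhood (zero boundary);
#' the internal activity is \eqn{U = F(1 + \beta L)}; and the threshold
#' decays exponentially, resetting by \eqn{V_T} after a pulse. The update
#' is fully synchronous, so the result is independent of traversal order.
#'
#' The cumulative pulse count per neuron over the run is the
#' "firing times" statistic used by the fusion rule: a stronger stimulus
#' (or stronger linking support) fires earlier and more often.
#'
#' @param stimulus numeric matrix of external stimuli, in \[0, 1\].
#' @param linkStrength numeric matrix of per-neuron link strengths
#'   \eqn{\beta}, same shape as \code{stimulus} (a scalar is recycled).
#' @param config a [PCNNConfig-class].
#' @return a [PCNNResult-class] with per-neuron firing counts and the
#'   iteration of first firing (\code{NA} if the neuron never fired).
#'
#' @examples
#' r <- pcnnFire(matrix(c(0.2, 0.8), 1), matrix(0.2, 1, 2),
#'               pcnnConfig(nIter = 60L))
#' firingCounts(r)
#' @export
pcnnFire <- function(stimulus, linkStrength, config = pcnnConfig()) {
    .assertMatrix(stimulus, "stimulus")
    if (length(linkStrength) == 1L)
        linkStrength <- matrix(linkStrength, nrow(stimulus), ncol(stimulus))
    .assertMatrix(linkStrength, "linkStrength")
    if (!identical(dim(stimulus), dim(linkStrength)))
        stop("stimulus and linkStrength must have the same shape")
    if (any(stimulus < 0))
        stop("stimulus must be nonnegative")
    stopifnot(is(config, "PCNNConfig"))

    decay <- exp(-config@alphaT)
    Y <- matrix(0, nrow(stimulus), ncol(stimulus))
    theta <- matrix(config@theta0, nrow(stimulus), ncol(stimulus))
    counts <- matrix(0L, nrow(stimulus), ncol(stimulus))
    first <- matrix(NA_integer_, nrow(stimulus), ncol(stimulus))
    for (n in seq_len(config@nIter)) {
        L <- .linkSum(Y, config@W)
        U <- stimulus * (1 + linkStrength * L)
        theta <- decay * theta + config@VT * Y
        Y <- (U >= theta) * 1
        fired <- Y > 0
        counts[fired] <- counts[fired] + 1L
        newly <- fired & is.na(first)
        first[newly] <- n
    }
    new("PCNNResult", firingCounts = counts, firstFire = first,
        nIter = config@nIter)
}
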