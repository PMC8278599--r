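## Stride-1 2-D convolution layers, forward and backward. The production
## path is compiled (single-precision im2col + GEMM in src/conv.cpp);
## a pure-R shift-and-GEMM double-precision reference implementation is
## kept alongside as an independent oracle for the test suite.

## Fixed layer plan: 3-layer extractor + 2-layer reconstructor.
## CONV5's listed stride/padding of 0 is read as stride 1, padding 0 (the
## only meaning under which a convolution is defined; the 1x1 kernel then
## preserves size).
.networkSpec <- function() list(
    list(k = 7L, cin = 3L,  cout = 64L, pad = 3L, activation = "relu"),
    list(k = 5L, cin = 64L, cout = 64L, pad = 2L, activation = "relu"),
    list(k = 3L, cin = 64L, cout = 64L, pad = 1L, activation = "relu"),
    list(k = 3L, cin = 64L, cout = 64L, pad = 1L, activation = "relu"),
    list(k = 1L, cin = 64L, cout = 3L,  pad = 0L, activation = "sigmoid"))

.padArray <- function(x, pad) {
    if (pad == 0L) return(x)
    d <- dim(x)
    out <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
    out[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
    out
}

## x: H x W x Cin; W: k x k x Cin x Cout; b: Cout. Stride 1.
.convForward <- function(x, W, b, pad) {
    if (dim(x)[3] != dim(W)[3])
        stop(sprintf("input has %d channels, layer expects %d",
                     dim(x)[3], dim(W)[3]))
    .cppConvForward(x, W, as.numeric(b), as.integer(pad))
}

## Pure-R double-precision reference (shift-and-GEMM), used by the tests
## as an independent oracle for the compiled kernels.
.convForwardR <- function(x, W, b, pad) {
    d <- dim(x); k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
    if (d[3] != cin)
        stop(sprintf("input has %d channels, layer expects %d", d[3], cin))
    xp <- .padArray(x, pad)
    ho <- d[1] + 2L * pad - k + 1L
    wo <- d[2] + 2L * pad - k + 1L
    Wm <- matrix(W, k * k * cin, cout)  # rows: (dy, dx, cin) column-major
    Y <- matrix(rep(b, each = ho * wo), ho * wo, cout)
    for (dx in seq_len(k)) for (dy in seq_len(k)) {
        slice <- xp[dy + 0:(ho - 1L), dx + 0:(wo - 1L), , drop = FALSE]
        dim(slice) <- c(ho * wo, cin)
        rows <- (dx - 1L) * k + dy + (seq_len(cin) - 1L) * k * k
        Y <- Y + slice %*% Wm[rows, , drop = FALSE]
    }
    array(Y, c(ho, wo, cout))
}

## Backward pass. dy: Hout x Wout x Cout gradient. Returns list(dx, dW, db);
## set needDx = FALSE for the first layer to skip the input gradient.
.convBackward <- function(x, W, dy, pad, needDx = TRUE) {
    r <- .cppConvBackward(x, W, dy, as.integer(pad), isTRUE(needDx))
    list(dx = r$dx, dW = r$dW, db = as.numeric(r$db))
}

## Pure-R reference backward pass (test oracle).
.convBackwardR <- function(x, W, dy, pad, needDx = TRUE) {
    d <- dim(x); k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
    ho <- dim(dy)[1]; wo <- dim(dy)[2]
    xp <- .padArray(x, pad)
    dYm <- matrix(dy, ho * wo, cout)
    dW <- array(0, dim(W))
    dxp <- if (needDx) array(0, dim(xp)) else NULL
    Wm <- matrix(W, k * k * cin, cout)
    for (dx_ in seq_len(k)) for (dy_ in seq_len(k)) {
        rs <- dy_ + 0:(ho - 1L); cs <- dx_ + 0:(wo - 1L)
        slice <- xp[rs, cs, , drop = FALSE]
        dim(slice) <- c(ho * wo, cin)
        rows <- (dx_ - 1L) * k + dy_ + (seq_len(cin) - 1L) * k * k
        dW[dy_, dx_, , ] <- crossprod(slice, dYm)
        if (needDx) {
            g <- dYm %*% t(Wm[rows, , drop = FALSE])   # (ho*wo) x cin
            dim(g) <- c(ho, wo, cin)
            dxp[rs, cs, ] <- dxp[rs, cs, ] + g
        }
    }
    db <- colSums(dYm)
    dx <- NULL
    if (needDx) {
        dx <- dxp[pad + seq_len(d[1]), pad + seq_len(d[2]), , drop = FALSE]
    }
    list(dx = dx, dW = dW, db = db)
}

.actForward <- function(z, activation) {
    switch(activation,
        relu = pmax(z, 0),
        sigmoid = 1 / (1 + exp(-z)),
        stop("unknown activation: ", activation))
}

.actBackward <- function(z, a, dA, activation) {
    switch(activation,
        relu = dA * (z > 0),
        sigmoid = dA * a * (1 - a),
        stop("unknown activation: ", activation))
}

## Forward through a span of layers; returns activations (and pre-
## activations when cache = TRUE) for backprop.
.netForward <- function(net, x, layers = seq_along(net@layers),
                        cache = FALSE) {
    acts <- list(x)
    pres <- list()
    a <- x
    for (i in layers) {
        L <- net@layers[[i]]
        z <- .convForward(a, L$W, L$b, L$pad)
        a <- .actForward(z, L$activation)
        if (cache) {
            pres[[length(pres) + 1L]] <- z
            acts[[length(acts) + 1L]] <- a
        }
    }
    if (cache) list(out = a, acts = acts, pres = pres) else list(out = a)
}
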