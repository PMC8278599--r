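## Independent reference implementations used to pin the production code.
## Everything here is written as directly as possible (explicit loops, no
## shared helpers with the package), so agreement is meaningful.

## Naive direct 2-D convolution, stride 1, zero padding.
naiveConv <- function(x, W, b, pad) {
    d <- dim(x); k <- dim(W)[1]; cin <- dim(W)[3]; cout <- dim(W)[4]
    hp <- d[1] + 2 * pad; wp <- d[2] + 2 * pad
    xp <- array(0, c(hp, wp, cin))
    xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
    ho <- hp - k + 1; wo <- wp - k + 1
    out <- array(0, c(ho, wo, cout))
    for (o in seq_len(cout)) {
        acc <- matrix(b[o], ho, wo)
        for (ci in seq_len(cin)) for (dy in seq_len(k)) for (dx in seq_len(k))
            acc <- acc + W[dy, dx, ci, o] *
                xp[dy + 0:(ho - 1), dx + 0:(wo - 1), ci]
        out[, , o] <- acc
    }
    out
}

## Brute-force 2-D Hahn moment double sum over the basis value table.
bruteMoments <- function(block, vals) {
    N <- nrow(block); M <- ncol(block)
    H <- matrix(0, N, M)
    for (m in seq_len(N)) for (n in seq_len(M)) {
        acc <- 0
        for (y in seq_len(N)) for (x in seq_len(M))
            acc <- acc + vals[m, y] * vals[n, x] * block[y, x]
        H[m, n] <- acc
    }
    H
}

## Scalar PCNN iteration for a single neuron with no linking input
## (beta = 0 or no firing neighbors): closed-form threshold bookkeeping.
scalarPcnn <- function(s, alphaT, VT, theta0, nIter) {
    theta <- theta0; y <- 0; count <- 0; first <- NA_integer_
    for (n in seq_len(nIter)) {
        theta <- exp(-alphaT) * theta + VT * y
        y <- as.numeric(s >= theta)
        if (y > 0) {
            count <- count + 1
            if (is.na(first)) first <- n
        }
    }
    list(count = count, first = first)
}

## Step-by-step fusion oracle for single-channel maps (Eqs. 10-14 chain):
## activity, zero-fill blocks, Hahn-moment potential energy, joint min-max,
## PCNN competition with block-mean saliency link strengths, winner copy /
## element-wise max on ties. Deliberately re-derived, loop by loop.
oracleFuse <- function(A, B, D, config, salA, salB) {
    act <- list(abs(A), abs(B))
    nr <- nrow(A); nc <- ncol(A)
    padR <- (D - nr %% D) %% D; padC <- (D - nc %% D) %% D
    nI <- (nr + padR) / D; nJ <- (nc + padC) / D
    vals <- basisValues(hahnBasis(D))
    pe <- lapply(act, function(m) {
        mp <- matrix(0, nr + padR, nc + padC)
        mp[1:nr, 1:nc] <- m
        p <- matrix(0, nI, nJ)
        for (i in 1:nI) for (j in 1:nJ) {
            blk <- mp[(i - 1) * D + 1:D, (j - 1) * D + 1:D]
            H <- bruteMoments(blk, vals)
            acc <- 0
            for (u in 1:D) for (v in 1:D) {
                if (u == 1 && v == 1) next
                acc <- acc + abs(H[u, v] - H[1, 1]) /
                    sqrt((u - 1)^2 + (v - 1)^2)
            }
            p[i, j] <- acc
        }
        p
    })
    rng <- range(c(pe[[1]], pe[[2]]))
    stim <- lapply(pe, function(p)
        if (rng[2] - rng[1] < .Machine$double.eps) p * 0
        else (p - rng[1]) / (rng[2] - rng[1]))
    beta <- lapply(list(salA, salB), function(s) {
        sp <- matrix(0, nr + padR, nc + padC)
        sp[1:nr, 1:nc] <- s
        b <- matrix(0, nI, nJ)
        for (i in 1:nI) for (j in 1:nJ)
            b[i, j] <- mean(sp[(i - 1) * D + 1:D, (j - 1) * D + 1:D])
        b
    })
    counts <- lapply(1:2, function(s)
        firingCounts(pcnnFire(stim[[s]], beta[[s]], config)))
    fusedP <- matrix(0, nr + padR, nc + padC)
    Ap <- matrix(0, nr + padR, nc + padC); Ap[1:nr, 1:nc] <- A
    Bp <- matrix(0, nr + padR, nc + padC); Bp[1:nr, 1:nc] <- B
    decision <- matrix(0L, nI, nJ)
    for (i in 1:nI) for (j in 1:nJ) {
        rs <- (i - 1) * D + 1:D; cs <- (j - 1) * D + 1:D
        c1 <- counts[[1]][i, j]; c2 <- counts[[2]][i, j]
        if (c1 > c2) { fusedP[rs, cs] <- Ap[rs, cs]; decision[i, j] <- 1L }
        else if (c2 > c1) { fusedP[rs, cs] <- Bp[rs, cs]; decision[i, j] <- 2L }
        else fusedP[rs, cs] <- pmax(Ap[rs, cs], Bp[rs, cs])
    }
    list(fused = fusedP[1:nr, 1:nc], decision = decision)
}

## A two-block contrast pattern: left block strongly textured, right block
## near-flat (and vice versa in the partner), so the PE ordering is
## unambiguous.
twoBlockPair <- function(D = 8) {
    g <- expand.grid(y = 1:D, x = 1:D)
    tex <- matrix(0.5 + 0.45 * sin(g$y * 2.1) * cos(g$x * 1.7), D, D)
    flat <- matrix(0.5, D, D)
    A <- cbind(tex, flat)     # A: texture on the left
    B <- cbind(flat, tex)     # B: texture on the right
    list(A = A, B = B)
}
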