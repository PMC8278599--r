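test_that("compiled convolution matches a naive direct oracle", {
    set.seed(41)
    for (cfg in list(c(k = 7, pad = 3, cin = 3, cout = 4),
                     c(k = 5, pad = 2, cin = 4, cout = 6),
                     c(k = 3, pad = 1, cin = 2, cout = 5),
                     c(k = 1, pad = 0, cin = 6, cout = 3))) {
        x <- array(rnorm(10 * 13 * cfg["cin"]), c(10, 13, cfg["cin"]))
        W <- array(rnorm(cfg["k"]^2 * cfg["cin"] * cfg["cout"]) * 0.2,
                   c(cfg["k"], cfg["k"], cfg["cin"], cfg["cout"]))
        b <- rnorm(cfg["cout"]) * 0.1
        y <- HahnFusion:::.convForward(x, W, b, cfg[["pad"]])
        yo <- naiveConv(x, W, b, cfg[["pad"]])
        expect_lt(max(abs(y - yo)) / max(abs(yo)), 1e-5)
        ## pure-R reference agrees with the oracle in double precision
        yr <- HahnFusion:::.convForwardR(x, W, b, cfg[["pad"]])
        expect_lt(max(abs(yr - yo)), 1e-12)
    }
})

test_that("compiled conv backward matches finite differences", {
    set.seed(42)
    x <- array(rnorm(7 * 8 * 2), c(7, 8, 2))
    W <- array(rnorm(3 * 3 * 2 * 3) * 0.3, c(3, 3, 2, 3))
    b <- rnorm(3) * 0.1
    loss <- function(xx, WW, bb)
        sum(sin(HahnFusion:::.convForwardR(xx, WW, bb, 1L)))
    y <- HahnFusion:::.convForwardR(x, W, b, 1L)
    g <- HahnFusion:::.convBackward(x, W, cos(y), 1L, needDx = TRUE)
    h <- 1e-5
    for (idx in list(c(1, 1, 1, 1), c(2, 3, 1, 2), c(3, 2, 2, 3))) {
        Wp <- W; Wp[idx[1], idx[2], idx[3], idx[4]] <- W[idx[1], idx[2],
                                                         idx[3], idx[4]] + h
        Wm <- W; Wm[idx[1], idx[2], idx[3], idx[4]] <- W[idx[1], idx[2],
                                                         idx[3], idx[4]] - h
        fd <- (loss(x, Wp, b) - loss(x, Wm, b)) / (2 * h)
        expect_lt(abs(g$dW[idx[1], idx[2], idx[3], idx[4]] - fd), 1e-4)
    }
    for (idx in list(c(1, 1, 1), c(4, 5, 2))) {
        xp <- x; xp[idx[1], idx[2], idx[3]] <- x[idx[1], idx[2], idx[3]] + h
        xm <- x; xm[idx[1], idx[2], idx[3]] <- x[idx[1], idx[2], idx[3]] - h
        fd <- (loss(xp, W, b) - loss(xm, W, b)) / (2 * h)
        expect_lt(abs(g$dx[idx[1], idx[2], idx[3]] - fd), 1e-4)
    }
})

test_that("network construction is deterministic in the seed", {
    n1 <- buildNetwork(seed = 5)
    n2 <- buildNetwork(seed = 5)
    n3 <- buildNetwork(seed = 6)
    expect_identical(n1@layers, n2@layers)
    expect_false(identical(n1@layers[[1]]$W, n3@layers[[1]]$W))
})

test_that("network layer plan matches the documented architecture", {
    net <- buildNetwork(seed = 1)
    dims <- lapply(net@layers, function(L) dim(L$W))
    expect_identical(dims[[1]], c(7L, 7L, 3L, 64L))
    expect_identical(dims[[2]], c(5L, 5L, 64L, 64L))
    expect_identical(dims[[3]], c(3L, 3L, 64L, 64L))
    expect_identical(dims[[4]], c(3L, 3L, 64L, 64L))
    expect_identical(dims[[5]], c(1L, 1L, 64L, 3L))
    expect_output(show(net), "CONV5")
})

test_that("feature extraction and reconstruction preserve spatial size", {
    net <- buildNetwork(seed = 2)
    for (d in list(c(37L, 41L), c(64L, 64L))) {
        x <- array(runif(prod(d) * 3), c(d, 3L))
        f <- extractFeatures(net, x)
        expect_identical(dim(f), c(d, 64L))
        expect_true(all(f >= 0))                 # ReLU output
        r <- reconstructImage(net, f)
        expect_identical(dim(r), c(d, 3L))
        expect_true(all(r > 0 & r < 1))          # sigmoid output
    }
})

test_that("zero weights give zero features", {
    net <- buildNetwork(seed = 3)
    for (i in 1:3)
        net <- setLayerWeights(net, i, array(0, dim(net@layers[[i]]$W)),
                               numeric(length(net@layers[[i]]$b)))
    x <- array(runif(32 * 32 * 3), c(32, 32, 3))
    expect_true(all(extractFeatures(net, x) == 0))
})

test_that("input validation of the network API", {
    net <- buildNetwork(seed = 1)
    expect_error(extractFeatures(net, matrix(0.5, 8, 8)), "H x W x 3")
    expect_error(reconstructImage(net, array(0, c(8, 8, 3))), "64")
    expect_error(setLayerWeights(net, 1, array(0, c(3, 3, 3, 3))),
                 "wrong shape")
})
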