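test_that("cross-entropy hand values", {
    expect_equal(lossCrossEntropy(0.5, 0.5), log(2))
    half <- array(0.5, c(8, 8, 3))
    expect_equal(lossCrossEntropy(half, half), log(2))
    ## minimized at O = I
    I <- matrix(c(0.2, 0.7, 0.4, 0.9), 2)
    expect_lt(lossCrossEntropy(I, I), lossCrossEntropy(I, I * 0 + 0.5))
    expect_error(lossCrossEntropy(matrix(0.5, 2, 2), matrix(0.5, 3, 3)),
                 "same shape")
})

test_that("total variation hand values and reductions", {
    expect_equal(lossTV(matrix(c(0, 0, 1, 1), 2), reduce = "sum"), 2)
    expect_equal(lossTV(matrix(c(0, 0, 1, 1), 2), reduce = "mean"), 0.5)
    expect_equal(lossTV(matrix(3, 10, 10)), 0)
    ## channels accumulate
    a <- array(0, c(2, 2, 3)); for (ch in 1:3) a[, , ch] <- c(0, 0, 1, 1)
    expect_equal(lossTV(a, reduce = "sum"), 6)
})

test_that("MS-SSIM equals 1 on identical images and is monotone in noise", {
    set.seed(51)
    x <- matrix(runif(64 * 64), 64)
    expect_equal(msSsim(x, x), 1)
    expect_equal(lossMsSsim(x, x), 0)
    n1 <- pmin(pmax(x + rnorm(64^2, sd = 0.02), 0), 1)
    n2 <- pmin(pmax(x + rnorm(64^2, sd = 0.2), 0), 1)
    expect_gt(msSsim(x, n1), msSsim(x, n2))
    expect_lt(msSsim(x, n2), 1)
})

test_that("composite loss components sum to the total", {
    set.seed(52)
    I <- array(runif(32 * 32 * 3), c(32, 32, 3))
    O <- array(runif(32 * 32 * 3), c(32, 32, 3))
    w <- c(0.7, 1.3, 2)
    l <- lossTotal(I, O, weights = w)
    expect_equal(l$total,
                 w[1] * l$crossEntropy + w[2] * l$msSsim + w[3] * l$tv)
    expect_equal(l$crossEntropy, lossCrossEntropy(I, O))
    expect_equal(l$msSsim, lossMsSsim(I, O))
    expect_equal(l$tv, lossTV(O))
})

test_that("composite loss gradient matches finite differences", {
    set.seed(53)
    I <- array(runif(24 * 24 * 2, 0.2, 0.8), c(24, 24, 2))
    O <- array(runif(24 * 24 * 2, 0.2, 0.8), c(24, 24, 2))
    g <- HahnFusion:::.totalLossGrad(I, O)$grad
    h <- 1e-6
    for (idx in list(c(1, 1, 1), c(12, 7, 2), c(24, 24, 1), c(5, 20, 2))) {
        Op <- O; Op[idx[1], idx[2], idx[3]] <- O[idx[1], idx[2], idx[3]] + h
        Om <- O; Om[idx[1], idx[2], idx[3]] <- O[idx[1], idx[2], idx[3]] - h
        fd <- (HahnFusion:::.totalLossGrad(I, Op)$value -
               HahnFusion:::.totalLossGrad(I, Om)$value) / (2 * h)
        expect_lt(abs(g[idx[1], idx[2], idx[3]] - fd),
                  1e-4 * max(1, abs(fd)))
    }
})

test_that("compiled separable filter equals the pure-R reference", {
    set.seed(54)
    x <- matrix(rnorm(37 * 23), 37, 23)
    for (k in list(HahnFusion:::.gaussKernel1d(11, 1.5),
                   c(0.1, 0.6, 0.3),
                   c(0.25, 0.25, 0.25, 0.25))) {
        expect_identical(HahnFusion:::.filterSep(x, k),
                         HahnFusion:::.filterSepR(x, k))
    }
    ## self-adjointness for a symmetric kernel (the MS-SSIM gradient
    ## derivation relies on it)
    k <- HahnFusion:::.gaussKernel1d(7, 1.2)
    y <- matrix(rnorm(37 * 23), 37, 23)
    expect_equal(sum(HahnFusion:::.filterSep(x, k) * y),
                 sum(x * HahnFusion:::.filterSep(y, k)))
})
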