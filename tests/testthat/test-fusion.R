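test_that("fusing a stack with itself is exactly idempotent", {
    set.seed(31)
    A <- array(runif(24 * 16 * 3), c(24, 16, 3))
    f <- fuseFeatureMaps(list(A, A), D = 8)
    expect_equal(max(abs(f - A)), 0)
    expect_true(all(attr(f, "decision") == 0L))   # every block ties
})

test_that("sign-flipped sources tie and resolve by element-wise max", {
    ## |A| = |-A|, so activity, PE, saliency and counts are identical for
    ## both sources; every block must tie and yield pmax(A, -A) = |A|.
    set.seed(32)
    A <- matrix(rnorm(16 * 16), 16, 16)
    f <- fuseFeatureMaps(list(A, -A), D = 8)
    expect_true(all(attr(f, "decision") == 0L))
    expect_equal(max(abs(f - abs(A))), 0)
})

test_that("two-block contrast pattern routes each block from the right source", {
    p <- twoBlockPair(8)
    cfg <- pcnnConfig(nIter = 60L)
    sal <- lapply(list(p$A, p$B), cwsSaliency)
    f <- fuseFeatureMaps(list(p$A, p$B), D = 8, config = cfg,
                         saliency = sal)
    dec <- attr(f, "decision")
    expect_identical(as.vector(dec), c(1L, 2L))   # texture wins each block
    expect_equal(f[, 1:8], p$A[, 1:8])
    expect_equal(f[, 9:16], p$B[, 9:16])
})

test_that("fusion matches the step-by-step brute-force oracle", {
    set.seed(33)
    cfg <- pcnnConfig(nIter = 40L)
    A <- matrix(runif(20 * 12), 20, 12)   # padded to 24 x 16 at D = 8
    B <- matrix(runif(20 * 12), 20, 12)
    salA <- cwsSaliency(A); salB <- cwsSaliency(B)
    f <- fuseFeatureMaps(list(A, B), D = 8, config = cfg,
                         saliency = list(salA, salB))
    o <- oracleFuse(A, B, 8, cfg, salA, salB)
    expect_identical(attr(f, "decision"), o$decision)
    expect_equal(max(abs(f - o$fused)), 0)
})

test_that("fusion is symmetric under source permutation", {
    set.seed(34)
    A <- matrix(runif(16^2), 16); B <- matrix(runif(16^2), 16)
    cfg <- pcnnConfig(nIter = 40L)
    sal <- list(cwsSaliency(A), cwsSaliency(B))
    f1 <- fuseFeatureMaps(list(A, B), D = 8, config = cfg, saliency = sal)
    f2 <- fuseFeatureMaps(list(B, A), D = 8, config = cfg,
                          saliency = rev(sal))
    expect_equal(max(abs(f1 - f2)), 0)
})

test_that("multi-channel stacks move blocks jointly across channels", {
    p <- twoBlockPair(8)
    A <- array(c(p$A, 0.5 * p$A), c(8, 16, 2))
    B <- array(c(p$B, 0.5 * p$B), c(8, 16, 2))
    sal <- lapply(list(p$A, p$B), cwsSaliency)
    f <- fuseFeatureMaps(list(A, B), D = 8, config = pcnnConfig(nIter = 60L),
                         saliency = sal)
    expect_equal(f[, 1:8, 2], 0.5 * p$A[, 1:8])
    expect_equal(f[, 9:16, 2], 0.5 * p$B[, 9:16])
})

test_that("three sources are supported", {
    set.seed(35)
    ms <- lapply(1:3, function(i) matrix(runif(64), 8))
    f <- fuseFeatureMaps(ms, D = 8, config = pcnnConfig(nIter = 30L))
    expect_equal(dim(f), c(8L, 8L))
    expect_true(attr(f, "decision") %in% 0:3)
})

test_that("fusion validates inputs", {
    A <- matrix(runif(64), 8)
    expect_error(fuseFeatureMaps(list(A)), "k >= 2")
    expect_error(fuseFeatureMaps(list(A, matrix(0, 4, 4))), "same shape")
    expect_error(fuseFeatureMaps(list(A, A), saliency = list(A)),
                 "one field per source")
})

test_that("saliency is bounded and vanishes on constant images", {
    set.seed(36)
    s <- cwsSaliency(matrix(runif(32^2), 32))
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(cwsSaliency(matrix(0.5, 32, 32)) == 0))
    expect_error(cwsSaliency(matrix(1, 8, 8), window = 4), "odd")
})

test_that("block link strengths are block means of the saliency field", {
    sal <- matrix(rep(c(0.2, 0.8), each = 8 * 16 / 2), 8, 16)
    bl <- blockLinkStrength(sal, 8)
    expect_equal(dim(bl), c(1L, 2L))
    expect_equal(as.vector(bl), c(0.2, 0.8))
})
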