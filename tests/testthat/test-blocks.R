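test_that("partition/reassemble round-trips exactly, with and without padding", {
    set.seed(21)
    m <- matrix(runif(16 * 24), 16, 24)
    g <- partitionBlocks(m, 8)
    expect_equal(padding(g), c(rows = 0L, cols = 0L))
    expect_identical(reassembleBlocks(g), m)

    m2 <- matrix(runif(100), 10, 10)
    g2 <- partitionBlocks(m2, 8)       # padded to 16 x 16
    expect_equal(padding(g2), c(rows = 6L, cols = 6L))
    expect_equal(dim(blockArray(g2)), c(8L, 8L, 2L, 2L))
    expect_identical(reassembleBlocks(g2), m2)
    ## the pad region really is zero
    expect_true(all(blockArray(g2)[, , 2, 2][3:8, ] == 0))
})

test_that("block contents are the expected tiles", {
    m <- matrix(as.numeric(1:64), 8, 8)
    g <- partitionBlocks(m, 4)
    expect_identical(blockArray(g)[, , 1, 1], m[1:4, 1:4])
    expect_identical(blockArray(g)[, , 2, 1], m[5:8, 1:4])
    expect_identical(blockArray(g)[, , 1, 2], m[1:4, 5:8])
    expect_equal(blockSide(g), 4L)
})

test_that("partition validates inputs", {
    expect_error(partitionBlocks(matrix(1, 4, 4), 1), "D must be")
    expect_error(partitionBlocks(matrix(1, 4, 4), 2.5), "D must be")
    expect_error(partitionBlocks("x", 4), "matrix")
})

test_that("potential energy hand examples", {
    expect_equal(potentialEnergy(matrix(c(1, 2, 3, 1), 2)), 3)
    ## uniform moment matrix: all deviations are zero
    expect_equal(potentialEnergy(matrix(5, 4, 4)), 0)
    ## single additional deviation at distance sqrt(2)
    H <- matrix(0, 2, 2); H[2, 2] <- 3
    expect_equal(potentialEnergy(H), 3 / sqrt(2))
})

test_that("potential energy is invariant to adding H11 and scales linearly", {
    set.seed(22)
    H <- matrix(rnorm(36), 6)
    expect_equal(potentialEnergy(H + 7 - H[1, 1]),
                 potentialEnergy(H - H[1, 1]))
    expect_equal(potentialEnergy(2 * (H - H[1, 1])),
                 2 * potentialEnergy(H - H[1, 1]))
})
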