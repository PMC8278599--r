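test_that("zero stimulus never fires", {
    r <- pcnnFire(matrix(0, 6, 6), 0.2, pcnnConfig(nIter = 100L))
    expect_true(all(firingCounts(r) == 0))
    expect_true(all(is.na(firstFire(r))))
})

test_that("uniform stimulus fires uniformly", {
    r <- pcnnFire(matrix(0.7, 7, 5), 0.3, pcnnConfig(nIter = 150L))
    cts <- firingCounts(r)
    expect_true(all(cts == cts[1, 1]))
    expect_gt(cts[1, 1], 0)
    ff <- firstFire(r)
    expect_true(all(ff == ff[1, 1]))
})

test_that("firing counts match the scalar closed-form oracle at beta = 0", {
    cfg <- pcnnConfig(nIter = 120L)
    for (s in c(0.05, 0.2, 0.5, 0.8, 1)) {
        r <- pcnnFire(matrix(s, 1, 1), 0, cfg)
        o <- scalarPcnn(s, 0.2, 20, 1, 120L)
        expect_identical(as.integer(firingCounts(r)[1, 1]), as.integer(o$count))
        expect_identical(firstFire(r)[1, 1], o$first)
    }
})

test_that("firing is monotone in stimulus when linking is off", {
    cfg <- pcnnConfig(W = matrix(0, 3, 3), nIter = 200L)
    s <- seq(0.05, 1, length.out = 12)
    r <- pcnnFire(matrix(s, 1), matrix(0, 1, 12), cfg)
    cts <- as.vector(firingCounts(r))
    expect_true(all(diff(cts) >= 0))
    expect_gt(cts[12], cts[1])
    ff <- as.vector(firstFire(r))
    expect_true(all(diff(ff) <= 0))   # stronger stimulus fires no later
})

test_that("linking support accelerates firing", {
    cfg <- pcnnConfig(nIter = 80L)
    ## a weak neuron flanked by strong ones fires more with linking on
    s <- matrix(c(0.9, 0.4, 0.9), 1)
    linked <- firingCounts(pcnnFire(s, 1.5, cfg))[1, 2]
    alone <- firingCounts(pcnnFire(s, 0, cfg))[1, 2]
    expect_gte(linked, alone)
})

test_that("input validation", {
    expect_error(pcnnFire(matrix(-0.1, 2, 2), 0.2), "nonnegative")
    expect_error(pcnnFire(matrix(0.5, 2, 2), matrix(0.2, 3, 3)),
                 "same shape")
    expect_error(pcnnConfig(alphaT = -1), "alphaT")
    expect_error(pcnnConfig(W = matrix(1, 3, 3)), "center")
    expect_error(pcnnConfig(W = matrix(0, 2, 2)), "3 x 3")
})

test_that("PCNNResult show and accessors", {
    r <- pcnnFire(matrix(0.5, 2, 2), 0.2, pcnnConfig(nIter = 30L))
    expect_output(show(r), "PCNNResult")
    expect_equal(dim(firingCounts(r)), c(2L, 2L))
})
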