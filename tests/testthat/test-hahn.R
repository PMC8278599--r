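test_that("hahnBasis is orthonormal across sizes and parameters", {
    for (N in c(4, 8, 16, 64)) for (ab in list(c(0, 0), c(0.5, 2))) {
        b <- hahnBasis(N, ab[1], ab[2])
        G <- tcrossprod(basisValues(b))
        expect_lt(max(abs(G - diag(N))), 1e-10)
    }
})

test_that("spectral basis matches the closed form at small N", {
    for (ab in list(c(0, 0), c(0.5, 0.5), c(2, 0.5), c(0, 1.5))) {
        b1 <- hahnBasis(12, ab[1], ab[2])
        b2 <- hahnBasisDirect(12, ab[1], ab[2])
        expect_lt(max(abs(basisValues(b1) - basisValues(b2))), 1e-9)
    }
})

test_that("sign convention: value at x = 0 carries sign (-1)^n", {
    v <- basisValues(hahnBasis(9, 0.5, 1.25))
    expect_true(all(sign(v[, 1]) == (-1)^(0:8)))
    ## order-0 row is sqrt(weight): strictly positive
    expect_true(all(v[1, ] > 0))
})

test_that("degenerate and invalid inputs are handled", {
    expect_identical(basisValues(hahnBasis(1)), matrix(1, 1, 1))
    expect_error(hahnBasis(0), "positive integer")
    expect_error(hahnBasis(8, alpha = -1), "alpha")
    expect_error(hahnBasis(8, beta = -2), "beta")
    expect_error(hahnBasis(c(4, 8)), "single")
})

test_that("2-D moments match an explicit double sum and conserve energy", {
    set.seed(11)
    b <- hahnBasis(8, 0.5, 0)
    f <- matrix(runif(64), 8)
    H <- hahnMoments2D(f, b)
    expect_lt(max(abs(H - bruteMoments(f, basisValues(b)))), 1e-12)
    expect_lt(abs(sum(H^2) - sum(f^2)), 1e-10)          # Parseval
    expect_lt(max(abs(inverseHahn2D(H, b) - f)), 1e-12) # round trip
})

test_that("rectangular blocks use separate row/column bases", {
    set.seed(12)
    br <- hahnBasis(6); bc <- hahnBasis(10, 1, 0.5)
    f <- matrix(runif(60), 6, 10)
    H <- hahnMoments2D(f, br, bc)
    expect_equal(dim(H), c(6L, 10L))
    expect_lt(max(abs(inverseHahn2D(H, br, bc) - f)), 1e-12)
    expect_error(hahnMoments2D(f, bc, br), "bases have N")
})

test_that("HahnBasis accessors and show method work", {
    b <- hahnBasis(8, 0.5, 2)
    expect_equal(hahnOrder(b), 8L)
    expect_equal(dim(basisValues(b)), c(8L, 8L))
    expect_output(show(b), "HahnBasis")
    expect_output(show(b), "alpha")
})
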