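test_that("phantoms are deterministic in (size, seed)", {
    p1 <- makePhantomPair(size = 64, seed = 9)
    p2 <- makePhantomPair(size = 64, seed = 9)
    expect_identical(structural(p1), structural(p2))
    expect_identical(functional(p1), functional(p2))
    p3 <- makePhantomPair(size = 64, seed = 10)
    expect_false(identical(structural(p1), structural(p3)))
})

test_that("phantom ranges, shapes and co-registration", {
    p <- makePhantomPair(size = 96, seed = 2)
    s <- structural(p); f <- functional(p)
    expect_equal(dim(s), c(96L, 96L))
    expect_equal(dim(f), c(96L, 96L, 3L))
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(f >= 0 & f <= 1))
    ## functional activity lives inside the structural brain mask: the
    ## corners (outside any ellipse) are zero in both
    expect_equal(s[1, 1], 0); expect_true(all(f[1, 1, ] == 0))
    expect_equal(s[96, 96], 0); expect_true(all(f[96, 96, ] == 0))
    ## the structural image has a bright skull ring somewhere
    expect_gt(max(s), 0.9)
    expect_output(show(p), "PhantomPair")
})

test_that("lesion control works and 'auto' alternates by seed parity", {
    pEven <- makePhantomPair(size = 64, seed = 2)       # auto: lesion
    pOdd <- makePhantomPair(size = 64, seed = 3)        # auto: none
    expect_false(is.null(phantomMeta(pEven)$lesion))
    expect_null(phantomMeta(pOdd)$lesion)
    les <- list(center = c(20, 40), radius = 5)
    s <- makeStructural(size = 64, seed = 3, lesion = les)
    expect_equal(s[20, 40], 0.95)
})

test_that("makeDataset yields distinct deterministic pairs", {
    d1 <- makeDataset(3, size = 64, seed = 1)
    d2 <- makeDataset(3, size = 64, seed = 1)
    expect_length(d1, 3)
    expect_identical(structural(d1[[2]]), structural(d2[[2]]))
    expect_false(identical(structural(d1[[1]]), structural(d1[[2]])))
})

test_that("tri-modal phantoms share geometry and have modality signatures", {
    tm <- makeTriModal(size = 64, seed = 4)
    expect_named(tm, c("ct", "mri", "pet"))
    expect_true(all(tm$ct >= 0 & tm$ct <= 1))
    ## CT skull is bright, MR skull is dim: CT max should exceed MR at the
    ## brightest CT pixel
    i <- which.max(tm$ct)
    expect_gt(tm$ct[i], tm$mri[i])
    ## PET is colored: channels differ somewhere
    expect_gt(max(abs(tm$pet[, , 1] - tm$pet[, , 3])), 0.1)
})

test_that("size validation", {
    expect_error(makeStructural(size = 32), "at least 64")
    expect_error(makeTriModal(size = 16), "at least 64")
    expect_error(makeDataset(0), ">= 1")
})

test_that("phantom generation does not disturb the caller's RNG stream", {
    set.seed(123); before <- runif(2)
    set.seed(123)
    invisible(makePhantomPair(size = 64, seed = 8))
    expect_identical(runif(2), before)
})
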