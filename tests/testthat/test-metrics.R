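test_that("spatial frequency hand values and properties", {
    expect_equal(metricSF(matrix(c(0, 0, 1, 1), 2)), sqrt(2) / 2)
    expect_equal(metricSF(matrix(0.4, 8, 8)), 0)
    set.seed(61)
    x <- matrix(runif(32^2), 32)
    expect_equal(metricSF(0.5 * x), 0.5 * metricSF(x))  # linear in scale
})

test_that("SSIM of identical images is 1; constant shift has a closed form", {
    set.seed(62)
    x <- matrix(runif(64^2), 64)
    expect_equal(metricSSIM(x, x), 1)
    ## two distinct constants: structure terms cancel, luminance term stays
    a <- matrix(0.5, 32, 32); b <- matrix(0.6, 32, 32)
    C1 <- 0.01^2
    expected <- (2 * 0.5 * 0.6 + C1) / (0.5^2 + 0.6^2 + C1)  # ~0.8001
    expect_equal(metricSSIM(a, b), expected, tolerance = 1e-10)
    expect_lt(metricSSIM(x, matrix(rev(x), 64)), 1)
})

test_that("histogram KL divergence has the expected hand value", {
    p <- c(0.5, 0.5); q <- c(0.25, 0.75)
    expect_equal(HahnFusion:::.klBits(p, q),
                 0.5 * log2(0.5 / 0.25) + 0.5 * log2(0.5 / 0.75),
                 tolerance = 1e-6)
    expect_equal(HahnFusion:::.klBits(p, p), 0)
})

test_that("cross entropy is 0 for identical histograms, positive otherwise", {
    set.seed(63)
    x <- matrix(runif(64^2), 64)
    expect_equal(metricCE(x, x, x), 0, tolerance = 1e-9)
    y <- matrix(runif(64^2, 0.5, 1), 64)
    expect_gt(metricCE(x, x, y), 0)
})

test_that("Q_AB/F is high for perfect fusion, low against flat images", {
    p <- makePhantomPair(size = 64, seed = 3)
    A <- structural(p)
    expect_gt(metricQABF(A, A, A), 0.95)
    expect_lt(metricQABF(A, A, matrix(0.5, 64, 64)), 0.1)
    ## all-zero images have no edges at all (even at the zero-padded
    ## border), so the weighted average is empty by convention
    expect_equal(metricQABF(matrix(0, 16, 16), matrix(0, 16, 16),
                            matrix(0, 16, 16)), 0)
})

test_that("VIF is 1 for identical images and decreases with degradation", {
    p <- makePhantomPair(size = 64, seed = 4)
    A <- structural(p)
    expect_equal(metricVIF(A, A), 1, tolerance = 1e-6)
    blur1 <- HahnFusion:::.gaussFilter(A, 7L, 1)
    blur2 <- HahnFusion:::.gaussFilter(A, 11L, 2.5)
    v1 <- metricVIF(A, blur1); v2 <- metricVIF(A, blur2)
    expect_lt(v1, 1)
    expect_lt(v2, v1)
})

test_that("FMI is maximal for self-fusion and bounded in [0, 1]", {
    p <- makePhantomPair(size = 64, seed = 5)
    A <- structural(p); B <- HahnFusion:::.luminance(functional(p))
    self <- metricFMI(A, A, A)
    expect_equal(self, 1, tolerance = 1e-9)
    set.seed(64)
    noise <- matrix(runif(64^2), 64)
    v <- metricFMI(A, B, noise)
    expect_gte(v, 0); expect_lte(v, 1)
    expect_lt(v, self)
})

test_that("scoreAll returns the six metrics and writes CSV", {
    p <- makePhantomPair(size = 64, seed = 6)
    A <- structural(p); B <- HahnFusion:::.luminance(functional(p))
    F <- (A + B) / 2
    csv <- tempfile(fileext = ".csv")
    s <- scoreAll(A, B, F, csv = csv, id = "avg")
    expect_named(s, c("qabf", "ssim", "vif", "fmi", "sf", "ce"))
    expect_true(all(vapply(s, is.finite, logical(1))))
    got <- read.csv(csv)
    expect_equal(got$id, "avg")
    expect_equal(got$qabf, s$qabf, tolerance = 1e-12)
    ## appending adds a second row without a second header
    scoreAll(A, B, F, csv = csv, id = "again")
    expect_equal(nrow(read.csv(csv)), 2L)
})

test_that("metrics reduce color inputs to luminance", {
    p <- makePhantomPair(size = 64, seed = 7)
    Fc <- functional(p)
    Fl <- HahnFusion:::.luminance(Fc)
    expect_equal(metricSF(Fc), metricSF(Fl))
    expect_equal(metricSSIM(Fc, Fc), 1)
})
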