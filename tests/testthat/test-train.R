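test_that("epochs = 0 returns the network unchanged", {
    net <- buildNetwork(seed = 1)
    imgs <- list(structural(makePhantomPair(size = 64, seed = 1)))
    out <- trainAutoencoder(net, imgs, epochs = 0)
    expect_identical(out@layers, net@layers)
    expect_length(lossHistory(out), 0)
})

test_that("a short training run reduces the loss and is bit-identical", {
    imgs <- lapply(1:4, function(i)
        structural(makePhantomPair(size = 64, seed = i)))
    n1 <- trainAutoencoder(buildNetwork(seed = 1), imgs, epochs = 3,
                           batchSize = 2, seed = 11)
    h <- lossHistory(n1)
    expect_length(h, 3)
    expect_lt(h[3], h[1])
    n2 <- trainAutoencoder(buildNetwork(seed = 1), imgs, epochs = 3,
                           batchSize = 2, seed = 11)
    expect_identical(n1@layers, n2@layers)
    expect_identical(lossHistory(n1), lossHistory(n2))
})

test_that("training does not disturb the caller's RNG stream", {
    imgs <- list(structural(makePhantomPair(size = 64, seed = 2)))
    set.seed(99); before <- runif(3)
    set.seed(99)
    invisible(trainAutoencoder(buildNetwork(seed = 1), imgs, epochs = 1,
                               seed = 5))
    expect_identical(runif(3), before)
})

test_that("training validates its inputs", {
    net <- buildNetwork(seed = 1)
    expect_error(trainAutoencoder(net, list()), "non-empty")
    expect_error(trainAutoencoder(net,
        list(structural(makePhantomPair(size = 64, seed = 1))),
        epochs = -1), ">= 0")
})

test_that("reconstruction fidelity improves with training", {
    imgs <- lapply(1:4, function(i)
        structural(makePhantomPair(size = 64, seed = i + 10)))
    net0 <- buildNetwork(seed = 2)
    net1 <- trainAutoencoder(net0, imgs, epochs = 4, batchSize = 4,
                             seed = 3)
    f0 <- mean(reconstructionFidelity(net0, imgs))
    f1 <- mean(reconstructionFidelity(net1, imgs))
    expect_gt(f1, f0)
})
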