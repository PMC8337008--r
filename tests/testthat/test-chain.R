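test_that("path probabilities follow the boundary transition rules", {
    seg <- exampleSeg()
    theta <- randomChainParameters(seg, seed = 3)
    p <- startUsages(theta); q <- endUsages(theta); pi <- initialProb(theta)
    # the three worked-example isoforms, factor by factor
    expect_equal(pathProbability(c(1, 1, 0, 1, 0, 0, 1, 1), theta, seg),
                 pi * q[1] * p[2] * q[2] * (1 - p[3]) * p[4] * (1 - q[3]))
    expect_equal(pathProbability(c(0, 1, 0, 0, 0, 1, 1, 1), theta, seg),
                 (1 - pi) * p[1] * q[1] * (1 - p[2]) * p[3] * (1 - q[3]))
    expect_equal(pathProbability(c(1, 1, 0, 0, 0, 0, 1, 0), theta, seg),
                 pi * q[1] * (1 - p[2]) * (1 - p[3]) * p[4] * q[3])
    # an exon cannot end at a start site: 1 -> 0 there has probability 0
    expect_equal(pathProbability(c(1, 0, 0, 0, 0, 0, 0, 0), theta, seg), 0)
    # an exon cannot begin at an end site: 0 -> 1 there has probability 0
    expect_equal(pathProbability(c(0, 0, 0, 0, 1, 1, 1, 1), theta, seg), 0)
})

test_that("forced parameters give a degenerate single-path chain", {
    seg <- exampleSeg()
    ones <- ChainParameters(1, p = rep(1, 4), q = rep(0, 3))
    en <- enumeratePaths(ones, seg)
    expect_equal(en$prob[which(rowSums(en$paths) == 8)], 1)
    expect_equal(sum(en$prob > 0), 1)
    expect_equal(transcribedMarginals(ones, seg), rep(1, 8))
    # all p = q = 1: exons end and restart at every opportunity
    alt <- ChainParameters(1, p = rep(1, 4), q = rep(1, 3))
    enA <- enumeratePaths(alt, seg)
    expect_equal(sum(enA$prob > 0), 1)
    expect_equal(enA$paths[enA$prob > 0, ], c(1, 1, 0, 1, 0, 1, 1, 0))
})

test_that("chain normalization and M = 1 behaviour", {
    one <- new("GeneSegmentation", geneID = "g", chrom = "c", strand = "+",
               geneStart = 0L, segLengths = 300L,
               boundaryKind = character(0), boundaryParam = integer(0))
    th <- ChainParameters(0.3)
    en <- enumeratePaths(th, one)
    expect_equal(en$prob, c(0.7, 0.3))
    expect_equal(transcribedMarginals(th, one), 0.3)
    seg <- exampleSeg()
    for (s in 1:5) {
        theta <- randomChainParameters(seg, seed = s)
        expect_lt(abs(sum(enumeratePaths(theta, seg)$prob) - 1), 1e-12)
    }
    expect_error(enumeratePaths(
        randomChainParameters(randomSegmentation(10, 10, seed = 1), seed = 1),
        randomSegmentation(10, 10, seed = 1)), "M <= 20")
})

test_that("DP marginals and effective length match enumeration", {
    for (s in 1:10) {
        inst <- randomInstance(s)
        en <- enumeratePaths(inst$theta, inst$seg, L = 20)
        marg <- vapply(seq_len(nSegments(inst$seg)), function(i)
            sum(en$prob[en$paths[, i] == 1]), numeric(1))
        expect_lt(max(abs(transcribedMarginals(inst$theta, inst$seg) - marg)),
                  1e-10)
        expect_lt(abs(expectedEffectiveLength(inst$theta, inst$seg, 20) -
                      sum(en$prob * en$effLen)), 1e-10)
    }
})

test_that("expected effective length handles short and long paths", {
    seg <- exampleSeg()  # total span 1600
    ones <- ChainParameters(1, p = rep(1, 4), q = rep(0, 3))
    expect_equal(expectedEffectiveLength(ones, seg, 100), 1600 - 100 + 1)
    # all probability mass on paths shorter than L
    short <- new("GeneSegmentation", geneID = "g", chrom = "c", strand = "+",
                 geneStart = 0L, segLengths = c(30L, 40L),
                 boundaryKind = "end", boundaryParam = 1L)
    thetaShort <- ChainParameters(1, q = 1)  # only segment 1, tl = 30
    expect_equal(expectedEffectiveLength(thetaShort, short, 50), 0)
    # decomposition E[l] = E[tl; tl >= L] - (L-1) P(tl >= L)
    theta <- exampleTheta()
    en <- enumeratePaths(theta, seg)
    L <- 100
    long <- en$tl >= L
    expect_equal(expectedEffectiveLength(theta, seg, L),
                 sum(en$prob[long] * en$tl[long]) -
                     (L - 1) * sum(en$prob[long]))
})

test_that("marginal site usage agrees with enumeration and is monotone", {
    seg <- exampleSeg()
    theta <- randomChainParameters(seg, seed = 9)
    en <- enumeratePaths(theta, seg)
    u <- marginalSiteUsage(theta, seg)
    # start site s1 sits at boundary 1: exon starts there iff Z1=0, Z2=1
    expect_equal(u$marginal[1],
                 sum(en$prob[en$paths[, 1] == 0 & en$paths[, 2] == 1]))
    for (b in seq_len(nSegments(seg) - 1)) {
        z0 <- en$paths[, b]; z1 <- en$paths[, b + 1]
        truthB <- if (boundaryKinds(seg)[b] == "start")
            sum(en$prob[z0 == 0 & z1 == 1]) else sum(en$prob[z0 == 1 & z1 == 0])
        expect_lt(abs(u$marginal[b] - truthB), 1e-12)
    }
    expect_equal(u$conditional,
                 ifelse(u$kind == "start", startUsages(theta)[u$param],
                        endUsages(theta)[u$param]))
    # raising p1 weakly raises the marginal usage of s1
    grid <- seq(0, 1, by = 0.1)
    m1 <- vapply(grid, function(v) {
        th <- theta; th@p[1] <- v
        marginalSiteUsage(th, seg)$marginal[1]
    }, numeric(1))
    expect_true(all(diff(m1) >= -1e-12))
    # where no transcript reads through a start site, marginal == conditional
    thetaBlock <- ChainParameters(0, p = c(0.4, 0.5, 0.5, 0.5), q = rep(0.5, 3))
    uB <- marginalSiteUsage(thetaBlock, seg)
    expect_equal(uB$marginal[1], 0.4)  # P(Z1=0) = 1
})
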