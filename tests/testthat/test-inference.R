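test_that("EM increases the likelihood monotonically and converges", {
    seg <- exampleSeg()
    sim <- simulateReads(seg, exampleTheta(), N = 5000, L = 100, seed = 41)
    fit <- emFit(sim$counts, seg)
    expect_true(fit@converged)
    tr <- logLikTrace(fit)
    expect_true(all(diff(tr) >= -1e-8))
    expect_equal(logLik(fit), tr[length(tr)])
    th <- thetaVector(fittedTheta(fit))
    expect_true(all(th >= 0 & th <= 1))
})

test_that("EM recovers generating parameters from abundant reads", {
    seg <- exampleSeg()
    theta <- exampleTheta()
    sim <- simulateReads(seg, theta, N = 1e5, L = 100, seed = 1)
    fit <- emFit(sim$counts, seg, tol = 1e-8, maxIter = 10000)
    idf <- unlist(identifiableFlags(fit))
    err <- abs(thetaVector(fittedTheta(fit)) - thetaVector(theta))
    # bounds calibrated by repeated simulation: the per-parameter sampling
    # SD of the MLE at this depth is 0.003-0.018 (largest for the usage of
    # the fourth start site, whose non-use paths are length-down-weighted)
    expect_lt(mean(err[idf]), 0.02)
    expect_lt(max(err[idf]), 0.08)
})

test_that("the fitted optimum matches direct maximization of the enumeration likelihood", {
    skipped <- 0
    for (s in 1:6) {
        inst <- randomInstance(s + 50)
        L <- 12
        sim <- simulateReads(inst$seg, inst$theta, N = 4000, L = L,
                             seed = s + 60)
        fit <- emFit(sim$counts, inst$seg, tol = 1e-13, maxIter = 50000)
        bf <- bfLoglikFactory(sim$counts, inst$seg, L)
        d <- length(thetaVector(inst$theta))
        best <- -Inf
        for (v0 in list(rep(0.5, d), rep(0.3, d), rep(0.7, d))) {
            opt <- optim(v0, function(v) -bf(v), method = "L-BFGS-B",
                         lower = 1e-6, upper = 1 - 1e-6,
                         control = list(factr = 10, maxit = 5000))
            best <- max(best, -opt$value)
        }
        thEM <- unname(thetaVector(fittedTheta(fit)))
        llEM <- bf(thEM)
        # the EM point is a stationary point: a polish started there must
        # neither improve the likelihood nor move identifiable parameters
        opt2 <- optim(thEM, function(v) -bf(v), method = "L-BFGS-B",
                      lower = 1e-6, upper = 1 - 1e-6,
                      control = list(factr = 10, maxit = 5000))
        best <- max(best, -opt2$value)
        expect_lt(abs(llEM - best), 1e-6)
        idf <- unlist(identifiableFlags(fit))
        bnd <- unlist(fit@atBoundary)
        cmp <- idf & !bnd
        if (any(cmp)) {
            expect_lt(max(abs(thEM[cmp] - opt2$par[cmp])), 1e-4)
        } else skipped <- skipped + 1
    }
    expect_lt(skipped, 6)
})

test_that("estimation error shrinks as read depth grows", {
    seg <- exampleSeg()
    theta <- exampleTheta()
    mae <- vapply(c(1e3, 1e5), function(N) {
        sim <- simulateReads(seg, theta, N = N, L = 100, seed = 211)
        fit <- emFit(sim$counts, seg)
        idf <- unlist(identifiableFlags(fit))
        mean(abs(thetaVector(fittedTheta(fit)) -
                 thetaVector(theta))[idf])
    }, numeric(1))
    expect_lt(mae[2], mae[1])
})

test_that("single-segment genes flag pi as unidentifiable", {
    one <- new("GeneSegmentation", geneID = "g", chrom = "c", strand = "+",
               geneStart = 0L, segLengths = 300L,
               boundaryKind = character(0), boundaryParam = integer(0))
    sc <- new("SignatureCounts", geneID = "g", signatures = list(1L),
              counts = 50, readLength = 100L, nDiscarded = 0L)
    fit <- emFit(sc, one)
    expect_false(identifiableFlags(fit)$pi)
    tab <- usageTable(fit, one, sc)
    expect_true(is.na(tab$estimate[tab$boundary_kind == "TSS"]))
})

test_that("all-inclusion reads drive a cassette start usage to the boundary", {
    seg <- buildSegmentation(cassetteExons())  # boundaries e1 s1 e2 s2
    inclusion <- ChainParameters(1, p = c(1, 1), q = c(1, 1))
    sim <- simulateReads(seg, inclusion, N = 3000, L = 60, seed = 9)
    fit <- emFit(sim$counts, seg)
    # cassette exon start site = start parameter 1 (boundary 2)
    expect_gt(startUsages(fittedTheta(fit))[1], 1 - 1e-6)
    expect_true(fit@atBoundary$p[1])
})

test_that("fits are invariant to signature entry order", {
    seg <- exampleSeg()
    sim <- simulateReads(seg, exampleTheta(), N = 3000, L = 100, seed = 55)
    sc <- sim$counts
    perm <- sample(nSignatures(sc))
    scP <- new("SignatureCounts", geneID = geneID(sc),
               signatures = signatures(sc)[perm],
               counts = readCounts(sc)[perm] * 1.0,
               readLength = readLength(sc), nDiscarded = 0L)
    scP@counts <- unname(scP@counts)
    f1 <- emFit(sc, seg)
    f2 <- emFit(scP, seg)
    expect_equal(thetaVector(fittedTheta(f1)), thetaVector(fittedTheta(f2)))
})

test_that("degenerate inputs are rejected with clear errors", {
    seg <- exampleSeg()
    empty <- new("SignatureCounts", geneID = "geneA", signatures = list(),
                 counts = numeric(0), readLength = 100L, nDiscarded = 0L)
    expect_error(emFit(empty, seg), "empty")
    sc <- new("SignatureCounts", geneID = "geneA", signatures = list(1L),
              counts = 5, readLength = 2000L, nDiscarded = 0L)
    expect_error(emFit(sc, seg), "shorter than the read length")
})
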