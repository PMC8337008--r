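test_that("signatures of single and junction alignments are correct", {
    seg <- exampleSeg()   # gene starts at 1001; cuts at 1200, 1500, 1660, ...
    # fully inside segment 2
    expect_equal(signatureOfAlignment(cbind(1210, 1250), seg), 2L)
    # contiguous read straddling segments 1 and 2
    expect_equal(signatureOfAlignment(cbind(1180, 1220), seg), c(1L, 2L))
    # junction read: block ends at end of X2 (1500), next starts at X4 (1661)
    expect_equal(signatureOfAlignment(rbind(c(1450, 1500), c(1661, 1700)),
                                      seg), c(2L, 4L))
    # junction at an unmodeled boundary is discarded
    expect_null(signatureOfAlignment(rbind(c(1450, 1490), c(1661, 1700)),
                                     seg))
    # read overhanging the gene span is discarded
    expect_null(signatureOfAlignment(cbind(950, 1049), seg))
    # overlapping blocks are an input error
    expect_error(signatureOfAlignment(rbind(c(1400, 1500), c(1450, 1550)),
                                      seg), "overlap")
})

test_that("accepted signatures match base-level segment overlap", {
    seg <- exampleSeg()
    set.seed(42)
    for (i in 1:200) {
        # random contiguous or junction footprint inside the gene
        if (runif(1) < 0.5) {
            s <- sample(1001:2500, 1)
            blocks <- cbind(s, min(s + sample(20:120, 1), 2600))
        } else {
            cuts <- 1000 + cumsum(segmentLengths(seg))
            b1e <- sample(cuts[-8], 1)
            cand <- cuts[cuts > b1e & cuts < 2600]
            if (length(cand) == 0) next
            b2s <- cand[sample.int(length(cand), 1)] + 1
            blocks <- rbind(c(max(1001, b1e - sample(10:60, 1)), b1e),
                            c(b2s, min(b2s + sample(10:60, 1), 2600)))
        }
        sig <- signatureOfAlignment(blocks, seg)
        if (!is.null(sig))
            expect_equal(sig, bfOverlapSegments(blocks, seg))
    }
})

test_that("minus-strand signatures are reported in transcription order", {
    ex <- exampleTranscripts()
    flip <- ex
    flip$start <- 3000 - ex$end
    flip$end <- 3000 - ex$start
    flip$strand <- "-"
    segM <- buildSegmentation(flip)
    # genomic interval mirroring a plus-strand (1,2)-straddling read
    expect_equal(signatureOfAlignment(cbind(3000 - 1220, 3000 - 1180), segM),
                 c(1L, 2L))
})

test_that("start position counts match brute force", {
    seg <- new("GeneSegmentation", geneID = "g", chrom = "c", strand = "+",
               geneStart = 0L, segLengths = c(200L, 50L, 300L, 10L),
               boundaryKind = c("end", "start", "end"),
               boundaryParam = c(1L, 1L, 2L))
    # single segment of length 200, L = 100 -> 101
    expect_equal(startPositionCount(1, seg, 100), 101L)
    # adjacent pair lengths 50,300 with L = 100 -> 50
    expect_equal(startPositionCount(c(2, 3), seg, 100), 50L)
    # skip: lengths 50,10 reachable only by short reads: L = 20 -> 10
    expect_equal(startPositionCount(c(2, 4), seg, 20), 10L)
    expect_equal(bfStartPositionCount(c(2, 4), seg, 20), 10L)
    # geometrically impossible at L = 100 (only 60 bases available)
    expect_equal(startPositionCount(c(2, 4), seg, 100), 0L)
    # brute force across random signatures and read lengths
    set.seed(7)
    segR <- randomSegmentation(2, 2, lengthRange = c(5, 40), seed = 11)
    for (i in 1:40) {
        k <- sample(1:3, 1)
        sig <- sort(sample(1:5, k))
        L <- sample(3:30, 1)
        expect_equal(startPositionCount(sig, segR, L),
                     bfStartPositionCount(sig, segR, L),
                     info = paste("sig", paste(sig, collapse = "-"), "L", L))
    }
})

test_that("start positions partition the effective length of a path", {
    segR <- randomSegmentation(2, 2, lengthRange = c(5, 40), seed = 13)
    L <- 15
    for (i in 1:20) {
        Z <- rbinom(nSegments(segR), 1, 0.6)
        tl <- sum(segmentLengths(segR)[Z == 1])
        if (tl < L) next
        sigs <- Filter(Negate(is.null),
                       lapply(0:(tl - L), bfWindowSignature, Z = Z, L = L,
                              seg = segR))
        uniq <- unique(sigs)
        total <- sum(vapply(uniq, startPositionCount, numeric(1),
                            seg = segR, L = L))
        expect_equal(total, tl - L + 1)
    }
})

test_that("counting aggregates, tallies discards, and is order invariant", {
    seg <- exampleSeg()
    r <- function(s, e) cbind(s, e)
    reads <- c(rep(list(rbind(c(1461, 1500), c(1661, 1700))), 3), # (2,4)
               rep(list(r(1211, 1290)), 2),                       # (2)
               list(r(950, 1029)),                                # overhang
               list(rbind(c(1451, 1490), c(1661, 1700))))         # novel
    sc <- countSignatures(reads, seg, L = 80)
    expect_equal(nSignatures(sc), 2)
    expect_equal(totalReads(sc), 5)
    expect_equal(unname(readCounts(sc)), c(2, 3))
    expect_equal(names(readCounts(sc)), c("2", "2-4"))
    expect_equal(discardedReads(sc), 2L)
    perm <- reads[c(4, 7, 2, 6, 1, 3, 5)]
    expect_equal(readCounts(countSignatures(perm, seg, L = 80)),
                 readCounts(sc))
    # reads of deviant length are skipped with a tally
    expect_message(sc2 <- countSignatures(c(reads[1:5], list(r(1211, 1220))),
                                          seg, L = 80), "skipped")
    expect_equal(discardedReads(sc2), 1L)
    expect_error(countSignatures(list(r(1111, 1120)), seg, L = 80,
                                 onLengthMismatch = "error"))
})

test_that("simulated signature frequencies match analytic expectations", {
    seg <- exampleSeg()
    theta <- exampleTheta()
    L <- 100
    sim <- simulateReads(seg, theta, N = 20000, L = L, seed = 31)
    sigs <- signatures(sim$counts)
    pg <- bfSignatureProb(sigs, theta, seg, L)
    obs <- readCounts(sim$counts)
    N <- totalReads(sim$counts)
    se <- sqrt(pg * (1 - pg) / N)
    expect_true(all(abs(obs / N - pg) <= 3.5 * se + 1e-12))
})

test_that("signature counts survive a TSV round trip", {
    seg <- exampleSeg()
    sim <- simulateReads(seg, exampleTheta(), N = 500, L = 100, seed = 5)
    f <- tempfile(fileext = ".tsv")
    writeSignatureCounts(sim$counts, f)
    back <- readSignatureCounts(f)[["geneA"]]
    expect_equal(signatures(back), signatures(sim$counts))
    expect_equal(readCounts(back), readCounts(sim$counts))
    expect_equal(readLength(back), 100L)
    unlink(f)
})

test_that("the BAM path reproduces in-memory signature counts exactly", {
    seg <- exampleSeg()
    sim <- simulateReads(seg, exampleTheta(), N = 400, L = 100, seed = 17,
                         keepReads = TRUE)
    sam <- tempfile(fileext = ".sam")
    writeSimulatedSam(sim, seg, sam)
    bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE,
                            indexDestination = TRUE)
    sc <- countSignatures(bam, seg, L = 100)
    expect_equal(readCounts(sc), readCounts(sim$counts))
    expect_equal(discardedReads(sc), 0L)
    unlink(c(sam, bam, paste0(bam, ".bai")))
})
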