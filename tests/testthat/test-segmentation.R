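test_that("the three-transcript worked example segments as expected", {
    seg <- exampleSeg()
    expect_equal(nSegments(seg), 8)
    expect_equal(nStartSites(seg), 4)
    expect_equal(nEndSites(seg), 3)
    expect_equal(boundaryKinds(seg),
                 c("start", "end", "start", "end", "start", "start", "end"))
    expect_equal(boundaryParams(seg), c(1L, 1L, 2L, 2L, 3L, 4L, 3L))
    # the three isoforms map onto the expected inclusion vectors
    ex <- exampleTranscripts()
    expect_equal(pathFromExons(ex[ex$transcript_id == "t1", ], seg),
                 c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L))
    expect_equal(pathFromExons(ex[ex$transcript_id == "t2", ], seg),
                 c(0L, 1L, 0L, 0L, 0L, 1L, 1L, 1L))
    expect_equal(pathFromExons(ex[ex$transcript_id == "t3", ], seg),
                 c(1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L))
})

test_that("degenerate and simple genes segment correctly", {
    one <- data.frame(gene_id = "g", transcript_id = "t", chrom = "c",
                      strand = "+", start = 101, end = 400)
    seg1 <- buildSegmentation(one)
    expect_equal(nSegments(seg1), 1)
    expect_equal(nStartSites(seg1), 0)
    expect_equal(nEndSites(seg1), 0)
    expect_length(boundaryKinds(seg1), 0)

    # cassette exon between shared flanks: exon,intron,cassette,intron,exon
    seg5 <- buildSegmentation(cassetteExons())
    expect_equal(nSegments(seg5), 5)
    expect_equal(nStartSites(seg5), 2)
    expect_equal(nEndSites(seg5), 2)
    expect_equal(boundaryKinds(seg5), c("end", "start", "end", "start"))
})

test_that("segments tile the gene span and boundaries match exon edges", {
    seg <- exampleSeg()
    expect_equal(sum(segmentLengths(seg)), 1600)
    tab <- segmentationTable(seg)
    expect_equal(tab$start[-1], tab$end[-nrow(tab)] + 1)
    # every exon edge except gene TSS/TES coincides with a typed boundary
    ex <- exampleTranscripts()
    edges <- sort(unique(c(ex$start, ex$end + 1L)))
    edges <- setdiff(edges, c(min(ex$start), max(ex$end) + 1L))
    cuts <- sort(unique(tab$start[-1]))
    expect_equal(edges, cuts)
})

test_that("segmentation is invariant to transcript and exon order", {
    ex <- exampleTranscripts()
    seg <- buildSegmentation(ex)
    for (s in 1:3) {
        perm <- ex[sample(nrow(ex)), ]
        expect_equal(buildSegmentation(perm), seg)
    }
})

test_that("minus-strand genes are flipped into transcription direction", {
    ex <- exampleTranscripts()
    # mirror coordinates around 3000 so the exon structure is reversed
    flip <- ex
    flip$start <- 3000 - ex$end
    flip$end <- 3000 - ex$start
    flip$strand <- "-"
    segM <- buildSegmentation(flip)
    segP <- exampleSeg()
    expect_equal(segmentLengths(segM), segmentLengths(segP))
    expect_equal(boundaryKinds(segM), boundaryKinds(segP))
    expect_equal(pathFromExons(flip[flip$transcript_id == "t1", ], segM),
                 c(1L, 1L, 0L, 1L, 0L, 0L, 1L, 1L))
    # genomic segment ranges run in descending genomic order
    gr <- segmentRanges(segM)
    expect_true(all(diff(GenomicRanges::start(gr)) < 0))
})

test_that("invalid inputs are rejected", {
    ex <- exampleTranscripts()
    mixed <- ex
    mixed$strand[1] <- "-"
    expect_error(buildSegmentation(mixed), "mixed strands")
    expect_error(buildSegmentation(ex[0, ]), "empty")
    overl <- data.frame(gene_id = "g", transcript_id = "t", chrom = "c",
                        strand = "+", start = c(1, 50), end = c(100, 150))
    expect_error(buildSegmentation(overl), "overlapping exons")
    disj <- data.frame(gene_id = "g", transcript_id = c("a", "b"),
                       chrom = "c", strand = "+",
                       start = c(1, 1000), end = c(100, 1100))
    expect_error(buildSegmentation(disj), "disjoint loci")
    loci <- splitGeneLoci(disj)
    expect_length(loci, 2)
    expect_equal(nSegments(buildSegmentation(loci[[1]])), 1)
})

test_that("boundaryOrderCheck reports violations precisely", {
    seg <- exampleSeg()
    expect_length(boundaryOrderCheck(seg), 0)
    tab <- segmentationTable(seg)
    gap <- tab
    gap$start[3] <- gap$start[3] + 5   # hole between segments 2 and 3
    v <- boundaryOrderCheck(gap)
    expect_length(v, 1)
    expect_match(v, "segment 3")
    wrongM <- tab
    wrongM$left_boundary_kind[3] <- "start"  # was end: Ms+Me+1 != M
    expect_true(any(grepl("!=", boundaryOrderCheck(wrongM)) |
                    grepl("consecutive from 1", boundaryOrderCheck(wrongM))))
    shuffled <- tab[c(2, 1, 3:8), ]
    shuffled$segment_index <- c(5L, 1:7)
    expect_true(length(boundaryOrderCheck(shuffled)) >= 1)
})

test_that("GTF round trip preserves the segmentation", {
    gtf <- tempfile(fileext = ".gtf")
    writeTranscriptsGTF(exampleTranscripts(), gtf)
    back <- readTranscriptsGTF(gtf)
    expect_equal(buildSegmentation(back), exampleSeg())
    unlink(gtf)
})

test_that("boundary coordinates point at the downstream segment start", {
    seg <- exampleSeg()
    # first modeled start site: gene offset 200 -> genomic base 1201
    expect_equal(boundaryCoords(seg)[1], 1201)
    tab <- segmentationTable(seg)
    expect_equal(boundaryCoords(seg), tab$start[-1])
})
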