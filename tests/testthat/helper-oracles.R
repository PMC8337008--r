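# Shared fixtures and independent brute-force oracles. The oracles work
# at base level / by full enumeration and deliberately avoid the DP and
# EM code paths they are used to check.

# study conditions for recovery/bootstrap checks on the worked example
exampleTheta <- function() {
    ChainParameters(0.55, p = c(0.30, 0.65, 0.40, 0.70),
                    q = c(0.45, 0.60, 0.35))
}

exampleSeg <- function() buildSegmentation(exampleTranscripts())

# two-isoform cassette-exon gene: exon - intron - cassette - intron - exon
cassetteExons <- function() {
    ex <- function(tx, s, e)
        data.frame(gene_id = "cass", transcript_id = tx, chrom = "chr2",
                   strand = "+", start = s, end = e,
                   stringsAsFactors = FALSE)
    rbind(ex("inc", c(101, 301, 501), c(200, 400, 650)),
          ex("skp", c(101, 501), c(200, 650)))
}

# base-level overlap: which segments do the blocks touch?
bfOverlapSegments <- function(blocks, seg) {
    gr <- segmentRanges(seg)
    segFor <- rep(NA_integer_, max(GenomicRanges::end(gr)))
    for (i in seq_along(gr))
        segFor[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <-
            gr$segment_index[i]
    bases <- unlist(apply(as.matrix(blocks), 1, function(b) b[1]:b[2],
                          simplify = FALSE))
    hits <- segFor[bases[bases >= 1 & bases <= length(segFor)]]
    sort(unique(hits[!is.na(hits)]))
}

# signature of a length-L window at 0-based transcript offset in path Z
bfWindowSignature <- function(Z, offset, L, seg) {
    ts <- which(Z == 1)
    lens <- segmentLengths(seg)[ts]
    segOfBase <- rep(ts, lens)           # transcript base -> segment
    if (offset + L > length(segOfBase)) return(NULL)
    sort(unique(segOfBase[(offset + 1):(offset + L)]))
}

# start positions of sig by sliding a window over the minimal transcript
bfStartPositionCount <- function(sig, seg, L, extraSegments = integer(0)) {
    M <- nSegments(seg)
    Z <- integer(M)
    Z[seq(sig[1], sig[length(sig)])] <- 0L
    Z[sig] <- 1L
    Z[extraSegments] <- 1L
    tl <- sum(segmentLengths(seg)[Z == 1])
    n <- 0L
    for (off in seq_len(max(tl - L + 1, 0)) - 1L) {
        w <- bfWindowSignature(Z, off, L, seg)
        if (!is.null(w) && identical(as.integer(w), as.integer(sig)))
            n <- n + 1L
    }
    n
}

# per-path window-signature count table over all observed signatures;
# rows follow en$paths
bfSignatureCountMatrix <- function(en, sigs, seg, L) {
    keys <- vapply(sigs, paste, character(1), collapse = "-")
    C <- matrix(0, nrow = nrow(en$paths), ncol = length(sigs))
    for (z in seq_len(nrow(en$paths))) {
        Z <- en$paths[z, ]
        tl <- en$tl[z]
        if (tl < L) next
        for (off in 0:(tl - L)) {
            w <- paste(bfWindowSignature(Z, off, L, seg), collapse = "-")
            hit <- match(w, keys)
            if (!is.na(hit)) C[z, hit] <- C[z, hit] + 1
        }
    }
    C
}

# enumeration-based signature probabilities P(g | theta)
bfSignatureProb <- function(sigs, theta, seg, L) {
    en <- enumeratePaths(theta, seg, L = L)
    C <- bfSignatureCountMatrix(en, sigs, seg, L)
    as.vector(t(C) %*% en$prob) / sum(en$prob * en$effLen)
}

# enumeration-based observed-data log-likelihood, as a function of the
# flat parameter vector (for direct numerical maximization)
bfLoglikFactory <- function(counts, seg, L) {
    Ms <- nStartSites(seg); Me <- nEndSites(seg)
    thetaOf <- function(v)
        ChainParameters(v[1], v[1 + seq_len(Ms)], v[1 + Ms + seq_len(Me)])
    probeTheta <- thetaOf(rep(0.5, 1 + Ms + Me))
    en0 <- enumeratePaths(probeTheta, seg, L = L)
    C <- bfSignatureCountMatrix(en0, signatures(counts), seg, L)
    effLen <- en0$effLen
    function(v) {
        en <- enumeratePaths(thetaOf(v), seg, L = L)
        pg <- as.vector(t(C) %*% en$prob) / sum(en$prob * effLen)
        if (any(pg <= 0)) return(-Inf)
        sum(readCounts(counts) * log(pg))
    }
}

# random valid segmentation + parameters for property checks; the
# default length range keeps every segment longer than the L = 12 reads
# used with these instances, so each segment supports interior reads and
# the likelihood surface has no short-segment flat directions
randomInstance <- function(seed, maxM = 10, lengthRange = c(15, 40)) {
    set.seed(seed)
    Ms <- sample(1:3, 1)
    Me <- sample(1:3, 1)
    while (Ms + Me + 1 > maxM) Ms <- max(Ms - 1, 1)
    seg <- randomSegmentation(Ms, Me, lengthRange = lengthRange,
                              seed = seed + 1000L)
    theta <- randomChainParameters(seg, range = c(0.15, 0.85),
                                   seed = seed + 2000L)
    list(seg = seg, theta = theta)
}
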