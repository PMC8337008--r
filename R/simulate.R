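#' Random gene segmentation
#'
#' Builds a segmentation with a random interleaving of `Ms` start-site
#' and `Me` end-site boundaries and uniformly drawn segment lengths.
#' Useful for property checks and simulations; the boundary typing is
#' arbitrary, as the chain is defined for any typing.
#'
#' @param Ms,Me number of modeled start/end sites.
#' @param lengthRange segment length bounds in bp.
#' @param seed optional RNG seed.
#' @param geneID,chrom,strand identifiers for the synthetic gene.
#' @return a \linkS4class{GeneSegmentation}.
#' @export
randomSegmentation <- function(Ms, Me, lengthRange = c(50, 300),
                               seed = NULL, geneID = "simgene",
                               chrom = "chrS", strand = "+") {
    withLocalSeed(seed, {
        M <- Ms + Me + 1L
        kind <- sample(c(rep("start", Ms), rep("end", Me)))
        param <- integer(length(kind))
        param[kind == "start"] <- seq_len(Ms)
        param[kind == "end"] <- seq_len(Me)
        new("GeneSegmentation", geneID = geneID, chrom = chrom,
            strand = strand, geneStart = 1000L,
            segLengths = as.integer(sample(
                seq(lengthRange[1], lengthRange[2]), M, replace = TRUE)),
            boundaryKind = kind, boundaryParam = param)
    })
}

#' Simulate reads from the generative model
#'
#' Samples transcripts with probability proportional to effective length
#' times chain probability, l(Z) w(Z), then places each read uniformly
#' over the transcript's start positions and records its mapping
#' signature. Transcript sampling is exact (path enumeration), so the
#' gene must have at most 20 segments.
#'
#' @param seg a \linkS4class{GeneSegmentation} (M <= 20).
#' @param theta true \linkS4class{ChainParameters}.
#' @param N number of reads (>= 1).
#' @param L read length in bp.
#' @param seed optional RNG seed.
#' @param keepReads also return the individual reads (needed by
#'   [writeSimulatedSam()]).
#' @return a list with elements `counts` (\linkS4class{SignatureCounts}),
#'   `truth` (list: `abundance`, a data.frame of non-null transcript
#'   paths with their renormalized chain probabilities; `usage`, the
#'   per-boundary true usages via [trueUsageFromAbundances()]), `theta`,
#'   and optionally `reads` (data.frame with the path and 0-based
#'   transcript start offset per read).
#' @export
simulateReads <- function(seg, theta, N, L, seed = NULL, keepReads = FALSE) {
    .checkThetaDims(theta, seg)
    if (N < 1) stop("N must be >= 1")
    stopifnot(L >= 1)
    en <- enumeratePaths(theta, seg, L = L)
    wts <- en$prob * en$effLen
    if (!any(wts > 0))
        stop("no transcript path with positive probability can emit a read")
    probT <- wts / sum(wts)
    cuts <- c(0L, cumsum(seg@segLengths))
    withLocalSeed(seed, {
        nPer <- as.vector(rmultinom(1, N, probT))
        sigs <- list()
        sigN <- numeric(0)
        reads <- if (keepReads)
            data.frame(path = integer(0), offset = integer(0)) else NULL
        for (k in which(nPer > 0)) {
            ts <- which(en$paths[k, ] == 1)
            segl <- seg@segLengths[ts]
            cum <- cumsum(segl)
            offs <- sample.int(en$effLen[k], nPer[k], replace = TRUE) - 1L
            firstIdx <- findInterval(offs, cum) + 1L        # offs < cum[i]
            lastIdx <- findInterval(offs + L - 1L, cum) + 1L
            tab <- table(paste(firstIdx, lastIdx))
            fl <- do.call(rbind, strsplit(names(tab), " "))
            for (r in seq_along(tab)) {
                sigs[[length(sigs) + 1L]] <-
                    ts[as.integer(fl[r, 1]):as.integer(fl[r, 2])]
                sigN <- c(sigN, as.numeric(tab[r]))
            }
            if (keepReads)
                reads <- rbind(reads,
                               data.frame(path = k, offset = offs))
        }
        keys <- vapply(sigs, paste, character(1), collapse = "-")
        agg <- rowsum(sigN, keys)
        uniq <- sigs[match(rownames(agg), keys)]
        ord <- order(vapply(uniq, `[`, integer(1), 1L), rownames(agg))
        counts <- new("SignatureCounts", geneID = seg@geneID,
                      signatures = uniq[ord], counts = as.numeric(agg)[ord],
                      readLength = as.integer(L), nDiscarded = 0L)
        nonNull <- which(en$prob > 0 & en$tl > 0)
        ab <- en$prob[nonNull] / sum(en$prob[nonNull])
        truth <- list(
            abundance = data.frame(
                path = apply(en$paths[nonNull, , drop = FALSE], 1, paste,
                             collapse = ""),
                tl = en$tl[nonNull], abundance = ab,
                stringsAsFactors = FALSE),
            usage = trueUsageFromAbundances(
                en$paths[nonNull, , drop = FALSE], ab, seg))
        out <- list(counts = counts, truth = truth, theta = theta)
        if (keepReads) {
            out$reads <- reads
            out$pathMatrix <- en$paths
        }
        out
    })
}

#' True site usages from transcript abundances
#'
#' The ground-truth usage of a boundary is the relative contribution of
#' transcripts in which an exon starts (for start sites) or ends (for
#' end sites) exactly at that boundary to the total transcript output of
#' the gene.
#'
#' @param paths transcripts: a 0/1 matrix with one row per transcript
#'   and `nSegments(seg)` columns, or an exon data.frame (converted per
#'   transcript via [pathFromExons()]).
#' @param abundances non-negative transcript abundances (not all zero);
#'   normalized internally.
#' @param seg a \linkS4class{GeneSegmentation}.
#' @return a data.frame with one row per internal boundary: `boundary`,
#'   `kind`, `param`, `usage`.
#' @export
trueUsageFromAbundances <- function(paths, abundances, seg) {
    if (is.data.frame(paths)) {
        tx <- unique(paths$transcript_id)
        paths <- t(vapply(tx, function(t)
            pathFromExons(paths[paths$transcript_id == t, , drop = FALSE],
                          seg), integer(nSegments(seg))))
    }
    paths <- as.matrix(paths)
    if (ncol(paths) != nSegments(seg))
        stop("paths must have nSegments(seg) columns")
    if (length(abundances) != nrow(paths))
        stop("one abundance per transcript required")
    if (any(abundances < 0) || all(abundances == 0))
        stop("abundances must be non-negative and not all zero")
    if (any(rowSums(paths) == 0))
        stop("a transcript with no transcribed segment is inconsistent ",
             "with the segmentation")
    ab <- abundances / sum(abundances)
    M <- nSegments(seg)
    b <- seq_len(M - 1)
    usage <- vapply(b, function(i) {
        if (seg@boundaryKind[i] == "start")
            sum(ab[paths[, i] == 0 & paths[, i + 1] == 1])
        else
            sum(ab[paths[, i] == 1 & paths[, i + 1] == 0])
    }, numeric(1))
    data.frame(boundary = b, kind = seg@boundaryKind,
               param = seg@boundaryParam, usage = usage)
}

#' Bernoulli Kullback-Leibler divergence between usages
#'
#' KL(u || uhat) = u log(u/uhat) + (1-u) log((1-u)/(1-uhat)) with
#' natural logarithm and the convention 0 log 0 = 0; the estimate is
#' clamped to `[eps, 1-eps]`. Non-negative, zero iff u equals the
#' clamped estimate. Vectorized.
#'
#' @param u true usage in [0, 1].
#' @param uhat estimated usage in [0, 1].
#' @param eps clamp width for the estimate.
#' @export
klScore <- function(u, uhat, eps = 1e-6) {
    stopifnot(all(u >= 0 & u <= 1, na.rm = TRUE),
              all(uhat >= 0 & uhat <= 1, na.rm = TRUE))
    uhat <- pmin(pmax(uhat, eps), 1 - eps)
    t1 <- ifelse(u > 0, u * log(u / uhat), 0)
    t2 <- ifelse(u < 1, (1 - u) * log((1 - u) / (1 - uhat)), 0)
    t1 + t2
}

#' Score estimated against true usages
#'
#' Joins an estimate table ([usageTable()]) with a truth table
#' ([trueUsageFromAbundances()]) by boundary and computes the per-site
#' Bernoulli KL divergence of the conditional-usage estimate from the
#' true usage. Constitutive sites (true usage 1) and unused sites (true
#' usage 0) are excluded from the summary by default, so that only
#' alternatively used sites are scored.
#'
#' @param estimates data.frame from [usageTable()].
#' @param truth data.frame from [trueUsageFromAbundances()].
#' @param variableOnly exclude sites with true usage exactly 0 or 1.
#' @return a data.frame of scored sites with columns of both inputs plus
#'   `kl`; mean KL in attribute `"meanKL"`.
#' @export
evaluateUsage <- function(estimates, truth, variableOnly = TRUE) {
    est <- estimates[estimates$boundary_kind %in% c("start", "end"), ,
                     drop = FALSE]
    est$boundary <- seq_len(nrow(est))
    m <- merge(est, truth, by = "boundary")
    if (variableOnly) m <- m[m$usage > 0 & m$usage < 1, , drop = FALSE]
    m <- m[!is.na(m$estimate), , drop = FALSE]
    m$kl <- klScore(m$usage, m$estimate)
    attr(m, "meanKL") <- mean(m$kl)
    m
}

# genomic alignment blocks of a simulated read (gene-coordinate math)
.readBlocks <- function(Z, offset, L, seg) {
    ts <- which(Z == 1)
    segl <- seg@segLengths[ts]
    cuts <- c(0L, cumsum(seg@segLengths))
    cum <- c(0L, cumsum(segl))
    lo <- offset; hi <- offset + L  # half-open in transcript coords
    blocks <- NULL
    for (i in seq_along(ts)) {
        a <- max(lo, cum[i]); b <- min(hi, cum[i + 1])
        if (a >= b) next
        gs <- cuts[ts[i]] + (a - cum[i])
        blocks <- rbind(blocks, c(gs, gs + (b - a)))
    }
    # merge gene-coordinate-adjacent blocks (consecutive segments)
    merged <- blocks[1, , drop = FALSE]
    for (i in seq_len(nrow(blocks) - 1) + 1) {
        if (blocks[i, 1] == merged[nrow(merged), 2])
            merged[nrow(merged), 2] <- blocks[i, 2]
        else merged <- rbind(merged, blocks[i, , drop = FALSE])
    }
    merged
}

#' Write simulated reads as a SAM file
#'
#' Emits single-end alignments for the reads of a [simulateReads()] run
#' (`keepReads = TRUE`) against the gene's reference, with `N` CIGAR
#' operations across spliced-out segments, so the BAM-based signature
#' counting path can be exercised end to end.
#'
#' @param sim result of `simulateReads(..., keepReads = TRUE)`.
#' @param seg the simulated \linkS4class{GeneSegmentation}.
#' @param file output SAM path.
#' @param refLength reference sequence length for the header (defaults
#'   to the gene end plus 100 bp).
#' @return the file path, invisibly.
#' @export
writeSimulatedSam <- function(sim, seg, file, refLength = NULL) {
    if (is.null(sim$reads))
        stop("simulateReads must be run with keepReads = TRUE")
    L <- readLength(sim$counts)
    geneEnd <- seg@geneStart + sum(seg@segLengths)
    if (is.null(refLength)) refLength <- geneEnd + 100L
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:coordinate",
                 sprintf("@SQ\tSN:%s\tLN:%d", seg@chrom, refLength)), con)
    flag <- if (seg@strand == "+") 0L else 16L
    recs <- character(nrow(sim$reads))
    pos <- integer(nrow(sim$reads))
    for (r in seq_len(nrow(sim$reads))) {
        Z <- sim$pathMatrix[sim$reads$path[r], ]
        gb <- .readBlocks(Z, sim$reads$offset[r], L, seg)
        # gene coords -> genomic half-open
        if (seg@strand == "+") {
            gstart <- seg@geneStart + gb[, 1]
            gend <- seg@geneStart + gb[, 2]
        } else {
            gstart <- geneEnd - gb[, 2]
            gend <- geneEnd - gb[, 1]
            o <- order(gstart); gstart <- gstart[o]; gend <- gend[o]
        }
        cig <- sprintf("%dM", gend[1] - gstart[1])
        if (length(gstart) > 1) for (i in seq_len(length(gstart) - 1) + 1) {
            cig <- paste0(cig, sprintf("%dN%dM", gstart[i] - gend[i - 1],
                                       gend[i] - gstart[i]))
        }
        pos[r] <- gstart[1] + 1L
        recs[r] <- paste(sprintf("read%06d", r), flag, seg@chrom, pos[r],
                         60L, cig, "*", 0L, 0L,
                         paste(rep("A", L), collapse = ""),
                         "*", sep = "\t")
    }
    writeLines(recs[order(pos)], con)
    invisible(file)
}
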