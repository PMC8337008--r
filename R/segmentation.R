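#' Read transcript exon structures from a GTF/GFF2 file
#'
#' Extracts exon features with their `gene_id` and `transcript_id`
#' attributes; all other feature types are ignored.
#'
#' @param file path to a GTF/GFF2 annotation.
#' @return a data.frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (1-based inclusive).
#' @export
readTranscriptsGTF <- function(file) {
    gr <- rtracklayer::import(file, format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    if (length(gr) == 0) stop("no exon features found in ", file)
    if (is.null(gr$gene_id) || is.null(gr$transcript_id))
        stop("exon features must carry gene_id and transcript_id attributes")
    df <- data.frame(
        gene_id = as.character(gr$gene_id),
        transcript_id = as.character(gr$transcript_id),
        chrom = as.character(GenomicRanges::seqnames(gr)),
        strand = as.character(GenomicRanges::strand(gr)),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        stringsAsFactors = FALSE
    )
    df[order(df$gene_id, df$transcript_id, df$start), , drop = FALSE]
}

#' Write a transcript exon table as GTF
#'
#' Inverse of [readTranscriptsGTF()] for the fields this package uses;
#' emits transcript and exon features.
#'
#' @param exons exon data.frame (see [readTranscriptsGTF()]).
#' @param file output path.
#' @export
writeTranscriptsGTF <- function(exons, file) {
    .validateExonTable(exons)
    lines <- character(0)
    for (tx in unique(exons$transcript_id)) {
        e <- exons[exons$transcript_id == tx, , drop = FALSE]
        e <- e[order(e$start), , drop = FALSE]
        attr9 <- sprintf('gene_id "%s"; transcript_id "%s";',
                         e$gene_id[1], tx)
        lines <- c(lines,
            paste(e$chrom[1], "SpliceChain", "transcript",
                  min(e$start), max(e$end), ".", e$strand[1], ".",
                  attr9, sep = "\t"),
            paste(e$chrom, "SpliceChain", "exon", e$start, e$end,
                  ".", e$strand, ".", attr9, sep = "\t"))
    }
    writeLines(lines, file)
    invisible(file)
}

.validateExonTable <- function(exons) {
    need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
    miss <- setdiff(need, names(exons))
    if (length(miss))
        stop("exon table lacks column(s): ", paste(miss, collapse = ", "))
    if (nrow(exons) == 0) stop("exon table is empty")
    if (any(exons$end < exons$start)) stop("exon with end < start")
    invisible(TRUE)
}

#' Split a gene into contiguous loci
#'
#' Transcripts that share a `gene_id` but occupy disjoint genomic loci
#' cannot be described by a single TSS-to-TES chain. This splits the exon
#' table into connected components of overlapping transcript spans; the
#' gene id is suffixed `_locus<k>` when more than one component exists.
#'
#' @param exons exon data.frame for one gene.
#' @return a named list of exon data.frames, one per contiguous locus.
#' @export
splitGeneLoci <- function(exons) {
    .validateExonTable(exons)
    gid <- unique(exons$gene_id)
    if (length(gid) != 1) stop("splitGeneLoci expects a single gene_id")
    tx <- unique(exons$transcript_id)
    spans <- t(vapply(tx, function(t) {
        e <- exons[exons$transcript_id == t, ]
        c(min(e$start), max(e$end))
    }, numeric(2)))
    ir <- IRanges::IRanges(start = spans[, 1], end = spans[, 2])
    comp <- IRanges::reduce(ir)
    hit <- IRanges::findOverlaps(ir, comp, select = "first")
    if (length(comp) == 1) {
        out <- list(exons)
        names(out) <- gid
        return(out)
    }
    out <- lapply(seq_along(comp), function(k) {
        e <- exons[exons$transcript_id %in% tx[hit == k], , drop = FALSE]
        e$gene_id <- sprintf("%s_locus%d", gid, k)
        e
    })
    names(out) <- sprintf("%s_locus%d", gid, seq_along(comp))
    out
}

# map genomic 1-based inclusive exon intervals of one gene to 0-based
# half-open gene coordinates (transcription direction)
.geneCoords <- function(exons, geneStart, geneEnd, strand) {
    s0 <- exons$start - 1L   # 0-based half-open
    e0 <- exons$end
    if (strand == "+") {
        data.frame(gs = s0 - geneStart, ge = e0 - geneStart)
    } else {
        data.frame(gs = geneEnd - e0, ge = geneEnd - s0)
    }
}

#' Build a gene segmentation from transcript exon structures
#'
#' Partitions a gene into segments bounded by the distinct exon start and
#' end sites of its transcripts. The 5'-most exon start (gene TSS) and
#' the 3'-most exon end (gene TES) bound the first and last segment but
#' receive no usage parameter; every other distinct exon start becomes a
#' modeled start site and every other distinct exon end a modeled end
#' site, including alternative transcription starts/ends. Segments tile
#' the span TSS to TES without gaps.
#'
#' @param exons exon data.frame for one gene (columns as in
#'   [readTranscriptsGTF()]); all transcripts must share gene id, strand
#'   and chromosome, and occupy one contiguous locus (see
#'   [splitGeneLoci()]).
#' @return a \linkS4class{GeneSegmentation}.
#' @examples
#' seg <- buildSegmentation(exampleTranscripts())
#' nSegments(seg)    # 8
#' nStartSites(seg)  # 4
#' nEndSites(seg)    # 3
#' @export
buildSegmentation <- function(exons) {
    .validateExonTable(exons)
    gid <- unique(exons$gene_id)
    if (length(gid) != 1) stop("all transcripts must share one gene_id")
    strand <- unique(exons$strand)
    if (length(strand) != 1)
        stop("transcripts on mixed strands cannot be segmented together")
    if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
    chrom <- unique(exons$chrom)
    if (length(chrom) != 1) stop("all exons must lie on one chromosome")

    # per-transcript checks; merge bookended exons, reject overlapping ones
    cleaned <- do.call(rbind, lapply(split(exons, exons$transcript_id),
        function(e) {
            e <- e[order(e$start), , drop = FALSE]
            if (nrow(e) > 1 && any(e$start[-1] <= e$end[-nrow(e)]))
                stop("overlapping exons within transcript ",
                     e$transcript_id[1])
            ir <- IRanges::reduce(IRanges::IRanges(e$start, e$end),
                                  min.gapwidth = 1L)
            data.frame(gene_id = e$gene_id[1],
                       transcript_id = e$transcript_id[1],
                       chrom = e$chrom[1], strand = e$strand[1],
                       start = IRanges::start(ir), end = IRanges::end(ir),
                       stringsAsFactors = FALSE)
        }))
    rownames(cleaned) <- NULL

    if (length(splitGeneLoci(cleaned)) > 1)
        stop("transcripts of '", gid, "' occupy disjoint loci; ",
             "split them with splitGeneLoci() first")

    geneStart <- min(cleaned$start) - 1L  # 0-based
    geneEnd <- max(cleaned$end)           # half-open end
    geneLen <- geneEnd - geneStart
    gc <- .geneCoords(cleaned, geneStart, geneEnd, strand)

    startCoords <- sort(unique(gc$gs))
    endCoords <- sort(unique(gc$ge))
    internalStarts <- setdiff(startCoords, 0L)
    internalEnds <- setdiff(endCoords, geneLen)
    clash <- intersect(internalStarts, internalEnds)
    if (length(clash))
        stop("an exon start and an exon end coincide at gene offset ",
             paste(clash, collapse = ","),
             " (zero-length segment); annotation not representable")

    bpos <- sort(c(internalStarts, internalEnds))
    kind <- if (length(bpos)) {
        ifelse(bpos %in% internalStarts, "start", "end")
    } else character(0)
    param <- integer(length(kind))
    param[kind == "start"] <- seq_len(sum(kind == "start"))
    param[kind == "end"] <- seq_len(sum(kind == "end"))

    new("GeneSegmentation",
        geneID = gid, chrom = chrom, strand = strand,
        geneStart = as.integer(geneStart),
        segLengths = as.integer(diff(c(0L, bpos, geneLen))),
        boundaryKind = kind, boundaryParam = param)
}

# cumulative gene-coordinate positions of internal boundaries
.boundaryOffsets <- function(seg) {
    cs <- cumsum(seg@segLengths)
    cs[-length(cs)]
}

#' @details `boundaryCoords()` reports, for each internal boundary, the
#'   1-based genomic coordinate of the first base of the segment
#'   downstream of the boundary in transcription direction (for a start
#'   site on the plus strand, the first exonic base of the acceptor).
#' @rdname GeneSegmentation-class
setMethod("boundaryCoords", "GeneSegmentation", function(x) {
    off <- .boundaryOffsets(x)
    geneEnd <- x@geneStart + sum(x@segLengths)
    if (x@strand == "+") x@geneStart + off + 1L else geneEnd - off
})

#' @rdname GeneSegmentation-class
setMethod("segmentRanges", "GeneSegmentation", function(x) {
    cs <- c(0L, cumsum(x@segLengths))
    geneEnd <- x@geneStart + sum(x@segLengths)
    if (x@strand == "+") {
        gstart <- x@geneStart + cs[-length(cs)] + 1L
        gend <- x@geneStart + cs[-1]
    } else {
        gstart <- geneEnd - cs[-1] + 1L
        gend <- geneEnd - cs[-length(cs)]
    }
    gr <- GenomicRanges::GRanges(x@chrom,
        IRanges::IRanges(start = gstart, end = gend), strand = x@strand)
    gr$segment_index <- seq_along(x@segLengths)
    gr
})

#' Tabulate a segmentation
#'
#' One row per segment in transcription order, with the genomic interval
#' (1-based inclusive) and the type and parameter index of the boundary
#' on the segment's upstream (5', transcription direction) side. The
#' first segment's upstream boundary is the gene TSS, which carries no
#' parameter.
#'
#' @param seg a \linkS4class{GeneSegmentation}.
#' @return a data.frame with columns `gene_id`, `segment_index`, `chrom`,
#'   `start`, `end`, `strand`, `left_boundary_kind`,
#'   `left_boundary_param_index`.
#' @export
segmentationTable <- function(seg) {
    stopifnot(is(seg, "GeneSegmentation"))
    gr <- segmentRanges(seg)
    M <- nSegments(seg)
    data.frame(
        gene_id = seg@geneID,
        segment_index = seq_len(M),
        chrom = seg@chrom,
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        strand = seg@strand,
        left_boundary_kind = c("TSS", seg@boundaryKind),
        left_boundary_param_index = c(NA_integer_, seg@boundaryParam),
        stringsAsFactors = FALSE
    )
}

#' @rdname boundaryOrderCheck
setMethod("boundaryOrderCheck", "GeneSegmentation", function(x) {
    v <- .checkSegmentationSlots(x)
    if (length(v)) return(v)
    boundaryOrderCheck(segmentationTable(x))
})

#' @rdname boundaryOrderCheck
setMethod("boundaryOrderCheck", "data.frame", function(x) {
    v <- character(0)
    need <- c("gene_id", "segment_index", "start", "end", "strand",
              "left_boundary_kind", "left_boundary_param_index")
    miss <- setdiff(need, names(x))
    if (length(miss))
        return(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
    if (nrow(x) == 0) return("segmentation table is empty")
    x <- x[order(x$segment_index), , drop = FALSE]
    M <- nrow(x)
    if (!identical(as.integer(x$segment_index), seq_len(M)))
        v <- c(v, "segment indices are not consecutive from 1")
    if (any(x$end < x$start))
        v <- c(v, sprintf("segment %s has length < 1",
            paste(x$segment_index[x$end < x$start], collapse = ",")))
    strand <- x$strand[1]
    if (M > 1) {
        if (strand == "+") {
            gap <- which(x$start[-1] != x$end[-M] + 1L)
        } else {
            gap <- which(x$end[-1] != x$start[-M] - 1L)
        }
        for (g in gap)
            v <- c(v, sprintf(
                "segment %d is not contiguous with segment %d (gap or overlap)",
                x$segment_index[g + 1], x$segment_index[g]))
    }
    kinds <- x$left_boundary_kind
    if (!kinds[1] %in% c("TSS", NA))
        v <- c(v, "first segment's upstream boundary should be the gene TSS")
    internal <- kinds[-1]
    bad <- which(!internal %in% c("start", "end"))
    for (b in bad)
        v <- c(v, sprintf("boundary upstream of segment %d has unknown kind '%s'",
                          x$segment_index[b + 1], internal[b]))
    Ms <- sum(internal == "start")
    Me <- sum(internal == "end")
    if (!length(bad) && M != Ms + Me + 1)
        v <- c(v, sprintf("M (%d) != Ms (%d) + Me (%d) + 1", M, Ms, Me))
    for (k in c("start", "end")) {
        idx <- x$left_boundary_param_index[-1][internal == k]
        if (length(idx) && !identical(as.integer(idx), seq_along(idx)))
            v <- c(v, sprintf(
                "%s-site parameter indices are not consecutive from 1", k))
    }
    v
})

#' Segment inclusion vector of a transcript
#'
#' Maps one transcript's exon structure onto the segmentation, returning
#' the binary vector Z of length M with Z[i] = 1 when segment i is part
#' of the transcript. Every exon boundary must coincide with a segment
#' boundary (or the gene TSS/TES).
#'
#' @param exons exon data.frame for one transcript.
#' @param seg a \linkS4class{GeneSegmentation}.
#' @return integer vector of length `nSegments(seg)`.
#' @export
pathFromExons <- function(exons, seg) {
    .validateExonTable(exons)
    if (length(unique(exons$transcript_id)) != 1)
        stop("pathFromExons expects a single transcript")
    geneEnd <- seg@geneStart + sum(seg@segLengths)
    gc <- .geneCoords(exons, seg@geneStart, geneEnd, seg@strand)
    cuts <- c(0L, cumsum(seg@segLengths))
    Z <- integer(nSegments(seg))
    for (i in seq_len(nrow(gc))) {
        a <- gc$gs[i]; b <- gc$ge[i]
        if (!(a %in% cuts) || !(b %in% cuts))
            stop("transcript '", exons$transcript_id[1],
                 "' is inconsistent with the segmentation")
        Z[cuts[-length(cuts)] >= a & cuts[-1] <= b] <- 1L
    }
    Z
}
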