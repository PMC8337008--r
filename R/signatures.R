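#' Mapping signature of one alignment
#'
#' Computes the ordered set of segments a read's aligned blocks overlap.
#' Junction reads (more than one block) are accepted only if each
#' junction coincides exactly with modeled segment boundaries; a read
#' whose junction uses an unmodeled donor or acceptor, or that reaches
#' outside the gene span, is discarded (returns `NULL`).
#'
#' @param blocks two-column matrix or data.frame of the read's match
#'   blocks, 1-based inclusive genomic start/end, sorted genomically.
#' @param seg a \linkS4class{GeneSegmentation}.
#' @return strictly increasing integer vector of segment indices in
#'   transcription order, or `NULL` if the read is incompatible with the
#'   segmentation.
#' @export
signatureOfAlignment <- function(blocks, seg) {
    blocks <- as.matrix(blocks)
    if (ncol(blocks) != 2) stop("blocks must have two columns (start, end)")
    if (any(blocks[, 2] < blocks[, 1])) stop("block with end < start")
    ord <- order(blocks[, 1])
    blocks <- blocks[ord, , drop = FALSE]
    nb <- nrow(blocks)
    if (nb > 1 && any(blocks[-1, 1] <= blocks[-nb, 2]))
        stop("alignment blocks overlap each other")

    geneEnd <- seg@geneStart + sum(seg@segLengths)
    # gene coordinates, 0-based half-open, transcription direction
    if (seg@strand == "+") {
        gs <- blocks[, 1] - 1L - seg@geneStart
        ge <- blocks[, 2] - seg@geneStart
    } else {
        gs <- geneEnd - blocks[, 2]
        ge <- geneEnd - (blocks[, 1] - 1L)
        o <- order(gs)
        gs <- gs[o]; ge <- ge[o]
    }
    geneLen <- sum(seg@segLengths)
    if (gs[1] < 0 || ge[length(ge)] > geneLen) return(NULL)

    cuts <- c(0L, cumsum(seg@segLengths))  # M+1 cut points
    sig <- integer(0)
    for (i in seq_along(gs)) {
        # junction endpoints must sit exactly on segment boundaries
        if (i > 1 && !(gs[i] %in% cuts)) return(NULL)
        if (i < length(gs) && !(ge[i] %in% cuts)) return(NULL)
        hit <- which(cuts[-length(cuts)] < ge[i] & cuts[-1] > gs[i])
        sig <- c(sig, hit)
    }
    if (length(sig) == 0 || any(diff(sig) <= 0)) return(NULL)
    sig
}

# aggregate a list of signatures into a SignatureCounts object
.aggregateSignatures <- function(sigs, geneID, L, nDiscarded) {
    keys <- vapply(sigs, paste, character(1), collapse = "-")
    tab <- table(keys)
    uniq <- sigs[match(names(tab), keys)]
    ord <- order(vapply(uniq, `[`, integer(1), 1L), names(tab))
    new("SignatureCounts", geneID = geneID,
        signatures = uniq[ord],
        counts = as.numeric(tab)[ord],
        readLength = as.integer(L),
        nDiscarded = as.integer(nDiscarded))
}

#' @importClassesFrom GenomicAlignments GAlignments
#' @param onLengthMismatch what to do with reads whose aligned length
#'   differs from `L`: `"skip"` them (tallied, with a message) or raise an
#'   `"error"`. The model assumes a fixed read length.
#' @rdname countSignatures
setMethod("countSignatures", "list",
    function(x, seg, L = NULL, onLengthMismatch = c("skip", "error")) {
        onLengthMismatch <- match.arg(onLengthMismatch)
        lens <- vapply(x, function(b) {
            b <- as.matrix(b)
            sum(b[, 2] - b[, 1] + 1)
        }, numeric(1))
        if (is.null(L)) {
            L <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
        }
        wrong <- lens != L
        if (any(wrong)) {
            if (onLengthMismatch == "error")
                stop(sum(wrong), " reads have aligned length != ", L)
            message(sum(wrong), " reads with aligned length != ", L,
                    " skipped")
        }
        nDiscarded <- sum(wrong)
        sigs <- list()
        for (b in which(!wrong)) {
            s <- signatureOfAlignment(x[[b]], seg)
            if (is.null(s)) nDiscarded <- nDiscarded + 1L
            else sigs[[length(sigs) + 1L]] <- s
        }
        if (length(sigs) == 0)
            stop("no alignment is compatible with the segmentation of '",
                 seg@geneID, "'")
        .aggregateSignatures(sigs, seg@geneID, L, nDiscarded)
    })

#' @rdname countSignatures
setMethod("countSignatures", "GAlignments",
    function(x, seg, L = NULL, onLengthMismatch = c("skip", "error")) {
        blk <- GenomicAlignments::grglist(x, drop.D.ranges = TRUE)
        blocks <- lapply(seq_along(blk), function(i) {
            r <- IRanges::ranges(blk[[i]])
            cbind(start = IRanges::start(r), end = IRanges::end(r))
        })
        countSignatures(blocks, seg, L = L,
                        onLengthMismatch = match.arg(onLengthMismatch))
    })

#' @rdname countSignatures
setMethod("countSignatures", "character",
    function(x, seg, L = NULL, onLengthMismatch = c("skip", "error")) {
        gr <- range(segmentRanges(seg))
        GenomicRanges::strand(gr) <- "*"
        param <- Rsamtools::ScanBamParam(
            which = gr,
            flag = Rsamtools::scanBamFlag(
                isUnmappedQuery = FALSE,
                isSecondaryAlignment = FALSE,
                isSupplementaryAlignment = FALSE))
        aln <- GenomicAlignments::readGAlignments(x, param = param)
        if (length(aln) == 0)
            stop("no alignments overlap gene '", seg@geneID, "' in ", x)
        countSignatures(aln, seg, L = L,
                        onLengthMismatch = match.arg(onLengthMismatch))
    })

#' Number of read start positions generating a signature
#'
#' Within any transcript whose inclusion states match the signature over
#' its span, counts the start positions of a length-L read that produce
#' exactly this signature: the read starts in the signature's first
#' segment, ends inside its last segment, and covers all intermediate
#' (non-skipped) segments completely. The count is 0 when this is
#' geometrically impossible, e.g. when the span beyond the first segment
#' holds L or more bases before the last segment is reached.
#'
#' @param sig strictly increasing integer vector of segment indices.
#' @param seg a \linkS4class{GeneSegmentation}.
#' @param L read length in bp.
#' @return a non-negative integer.
#' @export
startPositionCount <- function(sig, seg, L) {
    stopifnot(L >= 1)
    if (length(sig) == 0 || any(sig < 1 | sig > nSegments(seg)) ||
        any(diff(sig) <= 0))
        stop("sig must be a strictly increasing vector of segment indices")
    len <- seg@segLengths[sig]
    k <- length(len)
    Sk <- sum(len)
    Skm1 <- Sk - len[k]
    lo <- max(0L, Skm1 - L + 1L)      # read must reach the last segment
    hi <- min(len[1] - 1L, Sk - L)    # ... start in the first, end in the last
    max(0L, as.integer(hi - lo + 1L))
}

#' All geometrically possible signatures of a gene
#'
#' Enumerates every signature with a positive start-position count under
#' some transcript: all strictly increasing index vectors whose segments
#' can be covered by a read of length L. Guarded to small genes.
#'
#' @inheritParams startPositionCount
#' @return list of integer vectors.
#' @export
allSignatures <- function(seg, L) {
    M <- nSegments(seg)
    if (M > 14) stop("allSignatures is limited to M <= 14")
    out <- list()
    for (first in seq_len(M)) for (last in first:M) {
        mid <- if (last > first + 1) seq(first + 1, last - 1) else integer(0)
        subsets <- if (length(mid)) {
            m <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), length(mid))))
            lapply(seq_len(nrow(m)), function(i) mid[m[i, ]])
        } else list(integer(0))
        for (s in subsets) {
            sig <- sort(c(first, s, last))
            sig <- unique(sig)
            if (startPositionCount(sig, seg, L) > 0)
                out[[length(out) + 1L]] <- sig
        }
    }
    unique(out)
}

#' Write signature counts as TSV
#'
#' Columns `gene_id`, `signature` (dash-joined segment indices) and
#' `count`; comment header lines carry the read length `L`, the total `N`
#' and the discarded-read tally. The file can replace BAM input.
#'
#' @param x a \linkS4class{SignatureCounts} or a list of them.
#' @param file output path.
#' @export
writeSignatureCounts <- function(x, file) {
    if (is(x, "SignatureCounts")) x <- list(x)
    con <- file(file, "w")
    on.exit(close(con))
    for (sc in x) {
        writeLines(sprintf("# gene=%s L=%d N=%d discarded=%d",
                           sc@geneID, sc@readLength,
                           as.integer(totalReads(sc)), sc@nDiscarded), con)
    }
    writeLines("gene_id\tsignature\tcount", con)
    for (sc in x) {
        keys <- vapply(sc@signatures, paste, character(1), collapse = "-")
        writeLines(sprintf("%s\t%s\t%d", sc@geneID, keys,
                           as.integer(sc@counts)), con)
    }
    invisible(file)
}

#' Read signature counts from TSV
#'
#' @param file a file written by [writeSignatureCounts()].
#' @return a named list of \linkS4class{SignatureCounts}, one per gene.
#' @export
readSignatureCounts <- function(file) {
    lines <- readLines(file)
    hdr <- grep("^# gene=", lines, value = TRUE)
    meta <- do.call(rbind, lapply(hdr, function(h) {
        kv <- regmatches(h, gregexpr("[A-Za-z]+=[^ ]+", h))[[1]]
        vals <- sub("^[A-Za-z]+=", "", kv)
        names(vals) <- sub("=.*$", "", kv)
        as.data.frame(as.list(vals), stringsAsFactors = FALSE)
    }))
    tab <- read.table(file, sep = "\t", header = TRUE, comment.char = "#",
                      stringsAsFactors = FALSE)
    out <- lapply(seq_len(nrow(meta)), function(i) {
        g <- meta$gene[i]
        rows <- tab[tab$gene_id == g, , drop = FALSE]
        if (nrow(rows) == 0) stop("no counts for gene '", g, "' in ", file)
        sigs <- lapply(strsplit(rows$signature, "-", fixed = TRUE),
                       as.integer)
        new("SignatureCounts", geneID = g, signatures = sigs,
            counts = as.numeric(rows$count),
            readLength = as.integer(meta$L[i]),
            nDiscarded = as.integer(meta$discarded[i]))
    })
    names(out) <- meta$gene
    out
}
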