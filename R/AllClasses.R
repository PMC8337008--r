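#' @include AllGenerics.R
NULL

#' GeneSegmentation: a gene partitioned into segments
#'
#' Ordered, non-overlapping segments that tile a gene from its 5'-most
#' transcription start site (TSS) to its 3'-most transcription end site
#' (TES) in transcription direction. Each of the M-1 internal boundaries
#' is typed as an exon start site (3' acceptor splice site or an
#' alternative TSS) or an exon end site (5' donor splice site or an
#' alternative TES) and indexes one usage parameter. The outermost gene
#' TSS and TES carry no parameter, so M = Ms + Me + 1.
#'
#' Coordinates are stored 0-based half-open internally (`geneStart` is the
#' 0-based genomic start of the gene span); all user-facing coordinates
#' are 1-based inclusive. For minus-strand genes, segment index 1 is the
#' 5' end in transcription direction, i.e. the highest genomic coordinate.
#'
#' @slot geneID gene identifier.
#' @slot chrom reference sequence name.
#' @slot strand `"+"` or `"-"`.
#' @slot geneStart 0-based genomic start of the gene span.
#' @slot segLengths integer segment lengths (bp), transcription order.
#' @slot boundaryKind `"start"` or `"end"` for each internal boundary.
#' @slot boundaryParam 1-based parameter index within its kind.
#'
#' @param x a `GeneSegmentation`.
#' @aliases geneID nSegments nStartSites nEndSites segmentLengths
#'   boundaryKinds boundaryParams boundaryCoords segmentRanges
#' @export
setClass("GeneSegmentation",
    representation(
        geneID = "character",
        chrom = "character",
        strand = "character",
        geneStart = "integer",
        segLengths = "integer",
        boundaryKind = "character",
        boundaryParam = "integer"
    )
)

.checkSegmentationSlots <- function(object) {
    v <- character(0)
    M <- length(object@segLengths)
    if (M < 1) v <- c(v, "segmentation must contain at least one segment")
    if (any(object@segLengths < 1L))
        v <- c(v, sprintf("segment %s has length < 1",
                          paste(which(object@segLengths < 1L), collapse = ",")))
    if (!object@strand %in% c("+", "-"))
        v <- c(v, "strand must be '+' or '-'")
    if (length(object@boundaryKind) != M - 1L)
        v <- c(v, sprintf("expected %d internal boundaries, found %d",
                          M - 1L, length(object@boundaryKind)))
    if (length(object@boundaryParam) != length(object@boundaryKind))
        v <- c(v, "boundaryParam and boundaryKind lengths differ")
    bad <- !object@boundaryKind %in% c("start", "end")
    if (any(bad))
        v <- c(v, sprintf("boundary %s has unknown kind",
                          paste(which(bad), collapse = ",")))
    if (length(v)) return(v)
    Ms <- sum(object@boundaryKind == "start")
    Me <- sum(object@boundaryKind == "end")
    if (M != Ms + Me + 1L)
        v <- c(v, sprintf("M (%d) != Ms (%d) + Me (%d) + 1", M, Ms, Me))
    for (k in c("start", "end")) {
        idx <- object@boundaryParam[object@boundaryKind == k]
        if (length(idx) && !identical(idx, seq_along(idx)))
            v <- c(v, sprintf("%s-site parameter indices are not 1..%d in order",
                              k, length(idx)))
    }
    v
}

setValidity("GeneSegmentation", function(object) {
    v <- .checkSegmentationSlots(object)
    if (length(v)) v else TRUE
})

#' SignatureCounts: sufficient statistics for one gene
#'
#' The J distinct mapping signatures observed in a gene together with
#' their read counts c_j (summing to N) and the read length L. A
#' signature is the strictly increasing vector of transcription-order
#' segment indices a read overlaps; non-consecutive indices mean the read
#' splices over the omitted segments.
#'
#' @slot geneID gene identifier.
#' @slot signatures list of strictly increasing integer vectors.
#' @slot counts numeric counts, one per signature, each >= 1.
#' @slot readLength read length L in bp.
#' @slot nDiscarded number of reads discarded during counting.
#'
#' @param x a `SignatureCounts`.
#' @aliases signatures readCounts totalReads nSignatures readLength
#'   discardedReads
#' @export
setClass("SignatureCounts",
    representation(
        geneID = "character",
        signatures = "list",
        counts = "numeric",
        readLength = "integer",
        nDiscarded = "integer"
    )
)

setValidity("SignatureCounts", function(object) {
    v <- character(0)
    if (length(object@signatures) != length(object@counts))
        v <- c(v, "signatures and counts lengths differ")
    if (length(object@counts) && any(object@counts < 1))
        v <- c(v, "all signature counts must be >= 1")
    if (object@readLength < 1L) v <- c(v, "read length must be >= 1")
    ok <- vapply(object@signatures, function(s)
        length(s) > 0 && all(s >= 1) && all(diff(s) > 0), logical(1))
    if (length(ok) && !all(ok))
        v <- c(v, "signatures must be non-empty strictly increasing index vectors")
    if (length(v)) v else TRUE
})

#' ChainParameters: usage parameters of the splicing chain
#'
#' Theta = (pi, p, q): `pi` is the proportion of transcripts containing
#' the first segment; `p[m]` is the conditional usage of the m-th exon
#' start site (probability an intronic state enters an exon there);
#' `q[m]` is the conditional usage of the m-th exon end site
#' (probability an exonic state ends the exon there).
#'
#' @slot pi initial probability in [0, 1].
#' @slot p start-site usages, one per modeled start site.
#' @slot q end-site usages, one per modeled end site.
#'
#' @param x a `ChainParameters`.
#' @aliases initialProb startUsages endUsages thetaVector
#' @export
setClass("ChainParameters",
    representation(pi = "numeric", p = "numeric", q = "numeric")
)

setValidity("ChainParameters", function(object) {
    v <- character(0)
    if (length(object@pi) != 1 || is.na(object@pi) ||
        object@pi < 0 || object@pi > 1)
        v <- c(v, "pi must be a single probability in [0, 1]")
    if (length(object@p) && (anyNA(object@p) || any(object@p < 0 | object@p > 1)))
        v <- c(v, "all p must be probabilities in [0, 1]")
    if (length(object@q) && (anyNA(object@q) || any(object@q < 0 | object@q > 1)))
        v <- c(v, "all q must be probabilities in [0, 1]")
    if (length(v)) v else TRUE
})

#' @param pi,p,q see slots.
#' @rdname ChainParameters-class
#' @export
ChainParameters <- function(pi, p = numeric(0), q = numeric(0)) {
    new("ChainParameters", pi = as.numeric(pi), p = as.numeric(p),
        q = as.numeric(q))
}

#' SpliceFit: maximum-likelihood fit of the chain parameters
#'
#' Result of [emFit()]. The log-likelihood trace is non-decreasing across
#' EM iterations; `identifiable` flags parameters with no read support
#' (reported as NA in output tables), `atBoundary` flags estimates at the
#' boundary of parameter space.
#'
#' @slot geneID gene identifier.
#' @slot theta fitted \linkS4class{ChainParameters}.
#' @slot logLik final observed-data log-likelihood.
#' @slot logLikTrace per-iteration log-likelihood.
#' @slot converged logical.
#' @slot iterations number of EM iterations run.
#' @slot identifiable list with elements `pi`, `p`, `q` of logicals.
#' @slot atBoundary same shape as `identifiable`.
#'
#' @param x a `SpliceFit`.
#' @aliases fittedTheta logLikTrace identifiableFlags
#' @export
setClass("SpliceFit",
    representation(
        geneID = "character",
        theta = "ChainParameters",
        logLik = "numeric",
        logLikTrace = "numeric",
        converged = "logical",
        iterations = "integer",
        identifiable = "list",
        atBoundary = "list"
    )
)

#' BootstrapCI: bootstrap uncertainty of a fit
#'
#' B parameter estimates obtained by refitting multinomially resampled
#' signature counts, and percentile confidence intervals at the given
#' level. Intervals are reported only for identifiable parameters.
#'
#' @slot geneID gene identifier.
#' @slot B number of bootstrap replicates.
#' @slot level confidence level, e.g. 0.95.
#' @slot seed RNG seed used (NA if none supplied).
#' @slot estimates B x nparam matrix of replicate estimates.
#' @slot lower,upper named interval endpoints.
#'
#' @param x a `BootstrapCI`.
#' @param ... unused.
#' @aliases confInt bootstrapEstimates
#' @export
setClass("BootstrapCI",
    representation(
        geneID = "character",
        B = "integer",
        level = "numeric",
        seed = "integer",
        estimates = "matrix",
        lower = "numeric",
        upper = "numeric"
    )
)

## ---- accessors ----

#' @rdname GeneSegmentation-class
setMethod("geneID", "GeneSegmentation", function(x) x@geneID)
#' @rdname SignatureCounts-class
setMethod("geneID", "SignatureCounts", function(x) x@geneID)
#' @rdname SpliceFit-class
setMethod("geneID", "SpliceFit", function(x) x@geneID)

#' @rdname GeneSegmentation-class
setMethod("nSegments", "GeneSegmentation", function(x) length(x@segLengths))
#' @rdname GeneSegmentation-class
setMethod("nStartSites", "GeneSegmentation",
    function(x) sum(x@boundaryKind == "start"))
#' @rdname GeneSegmentation-class
setMethod("nEndSites", "GeneSegmentation",
    function(x) sum(x@boundaryKind == "end"))
#' @rdname GeneSegmentation-class
setMethod("segmentLengths", "GeneSegmentation", function(x) x@segLengths)
#' @rdname GeneSegmentation-class
setMethod("boundaryKinds", "GeneSegmentation", function(x) x@boundaryKind)
#' @rdname GeneSegmentation-class
setMethod("boundaryParams", "GeneSegmentation", function(x) x@boundaryParam)

#' @rdname SignatureCounts-class
setMethod("signatures", "SignatureCounts", function(x) x@signatures)
#' @rdname SignatureCounts-class
setMethod("readCounts", "SignatureCounts", function(x) {
    stats::setNames(x@counts,
        vapply(x@signatures, paste, character(1), collapse = "-"))
})
#' @rdname SignatureCounts-class
setMethod("totalReads", "SignatureCounts", function(x) sum(x@counts))
#' @rdname SignatureCounts-class
setMethod("nSignatures", "SignatureCounts", function(x) length(x@signatures))
#' @rdname SignatureCounts-class
setMethod("readLength", "SignatureCounts", function(x) x@readLength)
#' @rdname SignatureCounts-class
setMethod("discardedReads", "SignatureCounts", function(x) x@nDiscarded)

#' @rdname ChainParameters-class
setMethod("initialProb", "ChainParameters", function(x) x@pi)
#' @rdname ChainParameters-class
setMethod("startUsages", "ChainParameters", function(x) x@p)
#' @rdname ChainParameters-class
setMethod("endUsages", "ChainParameters", function(x) x@q)
#' @rdname ChainParameters-class
setMethod("thetaVector", "ChainParameters", function(x) {
    v <- c(x@pi, x@p, x@q)
    names(v) <- c("pi",
        if (length(x@p)) paste0("p", seq_along(x@p)),
        if (length(x@q)) paste0("q", seq_along(x@q)))
    v
})

#' @rdname SpliceFit-class
setMethod("fittedTheta", "SpliceFit", function(x) x@theta)
#' @rdname SpliceFit-class
setMethod("logLikTrace", "SpliceFit", function(x) x@logLikTrace)
#' @rdname SpliceFit-class
setMethod("identifiableFlags", "SpliceFit", function(x) x@identifiable)
#' @importFrom stats logLik
#' @rdname SpliceFit-class
#' @export
setMethod("logLik", "SpliceFit", function(object, ...) object@logLik)

#' @rdname BootstrapCI-class
setMethod("confInt", "BootstrapCI", function(x, ...)
    data.frame(parameter = names(x@lower), lower = unname(x@lower),
               upper = unname(x@upper), row.names = NULL))
#' @rdname BootstrapCI-class
setMethod("bootstrapEstimates", "BootstrapCI", function(x) x@estimates)

## ---- show methods ----

setMethod("show", "GeneSegmentation", function(object) {
    cat(sprintf("GeneSegmentation '%s' (%s:%s, %s strand)\n",
        object@geneID, object@chrom,
        paste0(object@geneStart + 1L, "-",
               object@geneStart + sum(object@segLengths)),
        object@strand))
    cat(sprintf("  M = %d segments, Ms = %d start sites, Me = %d end sites\n",
        nSegments(object), nStartSites(object), nEndSites(object)))
    cat("  segment lengths:", paste(object@segLengths, collapse = " "), "\n")
    if (length(object@boundaryKind))
        cat("  boundaries:", paste0(
            ifelse(object@boundaryKind == "start", "s", "e"),
            object@boundaryParam, collapse = " "), "\n")
})

setMethod("show", "SignatureCounts", function(object) {
    cat(sprintf("SignatureCounts '%s': J = %d signatures, N = %d reads, L = %d bp\n",
        object@geneID, nSignatures(object), as.integer(totalReads(object)),
        object@readLength))
    if (object@nDiscarded > 0L)
        cat(sprintf("  %d reads discarded during counting\n", object@nDiscarded))
    if (nSignatures(object) > 0) {
        tab <- readCounts(object)
        tab <- tab[order(-tab)]
        show <- utils::head(tab, 5)
        cat("  top signatures:",
            paste(sprintf("%s:%d", names(show), as.integer(show)),
                  collapse = ", "), "\n")
    }
})

setMethod("show", "ChainParameters", function(object) {
    cat("ChainParameters\n")
    cat(sprintf("  pi = %.4g\n", object@pi))
    if (length(object@p))
        cat("  p  =", paste(sprintf("%.4g", object@p), collapse = " "), "\n")
    if (length(object@q))
        cat("  q  =", paste(sprintf("%.4g", object@q), collapse = " "), "\n")
})

setMethod("show", "SpliceFit", function(object) {
    cat(sprintf("SpliceFit '%s': logLik = %.6g after %d iterations (%s)\n",
        object@geneID, object@logLik, object@iterations,
        if (object@converged) "converged" else "not converged"))
    show(object@theta)
    unid <- sum(!unlist(object@identifiable))
    if (unid > 0) cat(sprintf("  %d unidentifiable parameter(s)\n", unid))
})

setMethod("show", "BootstrapCI", function(object) {
    cat(sprintf("BootstrapCI '%s': B = %d replicates, %.0f%% percentile intervals\n",
        object@geneID, object@B, 100 * object@level))
    print(confInt(object))
})
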