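#' @rdname GeneSegmentation-class
#' @export
setGeneric("geneID", function(x) standardGeneric("geneID"))

#' @rdname GeneSegmentation-class
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' @rdname GeneSegmentation-class
#' @export
setGeneric("nStartSites", function(x) standardGeneric("nStartSites"))

#' @rdname GeneSegmentation-class
#' @export
setGeneric("nEndSites", function(x) standardGeneric("nEndSites"))

#' @rdname GeneSegmentation-class
#' @export
setGeneric("segmentLengths", function(x) standardGeneric("segmentLengths"))

#' @rdname GeneSegmentation-class
#' @export
setGeneric("boundaryKinds", function(x) standardGeneric("boundaryKinds"))

#' @rdname GeneSegmentation-class
#' @export
setGeneric("boundaryParams", function(x) standardGeneric("boundaryParams"))

#' @rdname GeneSegmentation-class
#' @export
setGeneric("boundaryCoords", function(x) standardGeneric("boundaryCoords"))

#' @rdname GeneSegmentation-class
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))

#' Structural sanity check of a segmentation
#'
#' Verifies the invariants a gene segmentation must satisfy: segments are
#' contiguous and tile the gene span in transcription direction, indices
#' run 1..M, every internal boundary is typed, parameter indices of each
#' boundary kind are consecutive from 1, and M equals the number of
#' modeled start sites plus end sites plus one.
#'
#' @param x a \linkS4class{GeneSegmentation} or a segmentation table as
#'   produced by [segmentationTable()].
#' @return a character vector of violations; empty when the object is valid.
#' @export
setGeneric("boundaryOrderCheck", function(x) standardGeneric("boundaryOrderCheck"))

#' @rdname SignatureCounts-class
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname SignatureCounts-class
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' @rdname SignatureCounts-class
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' @rdname SignatureCounts-class
#' @export
setGeneric("nSignatures", function(x) standardGeneric("nSignatures"))

#' @rdname SignatureCounts-class
#' @export
setGeneric("readLength", function(x) standardGeneric("readLength"))

#' @rdname SignatureCounts-class
#' @export
setGeneric("discardedReads", function(x) standardGeneric("discardedReads"))

#' Count mapping signatures of aligned reads
#'
#' Reduces alignments to segment mapping signatures and aggregates the
#' signature counts for one gene, the sufficient statistics of the model.
#'
#' @param x alignments: a list of per-read block matrices (two columns,
#'   1-based inclusive genomic start/end), a
#'   \link[GenomicAlignments]{GAlignments} object, or the path to a
#'   coordinate-sorted, indexed BAM file (queried over the gene span).
#' @param seg a \linkS4class{GeneSegmentation}.
#' @param L read length in bp. When `NULL`, the modal aligned read length
#'   is used and reads of other lengths are skipped with a tally.
#' @param ... passed between methods.
#' @return a \linkS4class{SignatureCounts} object. Reads that are
#'   incompatible with the segmentation (e.g. junctions at unmodeled
#'   boundaries) or fall outside the gene span are discarded and counted
#'   in `discardedReads()`.
#' @export
setGeneric("countSignatures", function(x, seg, L = NULL, ...)
    standardGeneric("countSignatures"))

#' @rdname ChainParameters-class
#' @export
setGeneric("initialProb", function(x) standardGeneric("initialProb"))

#' @rdname ChainParameters-class
#' @export
setGeneric("startUsages", function(x) standardGeneric("startUsages"))

#' @rdname ChainParameters-class
#' @export
setGeneric("endUsages", function(x) standardGeneric("endUsages"))

#' @rdname ChainParameters-class
#' @export
setGeneric("thetaVector", function(x) standardGeneric("thetaVector"))

#' @rdname SpliceFit-class
#' @export
setGeneric("fittedTheta", function(x) standardGeneric("fittedTheta"))

#' @rdname SpliceFit-class
#' @export
setGeneric("logLikTrace", function(x) standardGeneric("logLikTrace"))

#' @rdname SpliceFit-class
#' @export
setGeneric("identifiableFlags", function(x) standardGeneric("identifiableFlags"))

#' @rdname BootstrapCI-class
#' @export
setGeneric("confInt", function(x, ...) standardGeneric("confInt"))

#' @rdname BootstrapCI-class
#' @export
setGeneric("bootstrapEstimates", function(x) standardGeneric("bootstrapEstimates"))
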