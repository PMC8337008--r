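#' Worked example: a three-transcript gene with complex splicing
#'
#' A small plus-strand gene whose three isoforms induce eight segments:
#' four modeled exon start sites (one of them an alternative TSS) and
#' three modeled exon end sites (one of them an alternative TES), the
#' gene TSS and TES being unmodeled. The three transcripts correspond to
#' the inclusion vectors (1,1,0,1,0,0,1,1), (0,1,0,0,0,1,1,1) and
#' (1,1,0,0,0,0,1,0) over the segments.
#'
#' @return an exon data.frame suitable for [buildSegmentation()].
#' @examples
#' seg <- buildSegmentation(exampleTranscripts())
#' seg
#' @export
exampleTranscripts <- function() {
    # segment lengths 200,300,160,240,180,150,220,150 starting at offset
    # 1000; every segment is longer than a typical short read, so each
    # boundary is resolvable from read placements
    ex <- function(tx, s, e)
        data.frame(gene_id = "geneA", transcript_id = tx, chrom = "chr1",
                   strand = "+", start = s, end = e,
                   stringsAsFactors = FALSE)
    rbind(
        ex("t1", c(1001, 1661, 2231), c(1500, 1900, 2600)),
        ex("t2", c(1201, 2081), c(1500, 2600)),
        ex("t3", c(1001, 2231), c(1500, 2450))
    )
}
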