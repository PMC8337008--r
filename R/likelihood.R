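# encode signatures for the compiled likelihood/EM routines: first
# segment, 0/1 pattern over the span, and log start-position counts
.sigEncode <- function(counts, seg) {
    M <- nSegments(seg)
    L <- counts@readLength
    first <- vapply(counts@signatures, `[`, integer(1), 1L)
    if (any(vapply(counts@signatures, max, integer(1)) > M))
        stop("signature refers to a segment beyond M = ", M)
    pattern <- lapply(counts@signatures, function(s) {
        span <- seq(s[1], s[length(s)])
        as.integer(span %in% s)
    })
    spc <- vapply(counts@signatures, startPositionCount, numeric(1),
                  seg = seg, L = L)
    list(first = as.integer(first), pattern = pattern,
         spc = spc, logspc = ifelse(spc > 0, log(spc), -Inf),
         counts = counts@counts, L = as.integer(L))
}

#' Signature probabilities under the model
#'
#' P(signature g | theta) = spc(g) * P(Z matches g's span pattern) / D,
#' where spc(g) is the start-position count of the signature, the span
#' pattern fixes Z to 1 on the signature's segments and 0 on the skipped
#' ones (other segments marginalized), and D is the expected effective
#' length. Probabilities over all geometrically possible signatures sum
#' to 1 whenever D > 0.
#'
#' @param x a \linkS4class{SignatureCounts}, or a list of signature index
#'   vectors (then `L` is required).
#' @param theta a \linkS4class{ChainParameters}.
#' @param seg a \linkS4class{GeneSegmentation}.
#' @param L read length, only needed when `x` is a plain list.
#' @return numeric vector of probabilities, one per signature.
#' @export
signatureProbability <- function(x, theta, seg, L = NULL) {
    if (is.list(x) && !is(x, "SignatureCounts")) {
        x <- new("SignatureCounts", geneID = seg@geneID, signatures = x,
                 counts = rep(1, length(x)), readLength = as.integer(L),
                 nDiscarded = 0L)
    }
    .checkThetaDims(theta, seg)
    enc <- .segEncode(seg)
    se <- .sigEncode(x, seg)
    D <- cpp_expected_eff_len(theta@pi, theta@p, theta@q,
                              enc$segLen, enc$btype, enc$bpar, se$L)
    if (!(D > 0)) return(rep(NaN, length(se$first)))
    lp <- cpp_pattern_logprob(theta@pi, theta@p, theta@q,
                              enc$btype, enc$bpar, se$first, se$pattern)
    exp(se$logspc + lp - log(D))
}

#' Observed-data log-likelihood of signature counts
#'
#' sum_j c_j log P(g_j | theta). A signature whose start-position count
#' is zero is geometrically impossible under every transcript and
#' contributes `-Inf`; such input is flagged with a warning.
#'
#' @param counts a \linkS4class{SignatureCounts}.
#' @inheritParams signatureProbability
#' @return the log-likelihood (scalar; `-Inf` for inconsistent input or
#'   when no transcript path can emit a read).
#' @export
signatureLogLik <- function(counts, theta, seg) {
    .checkThetaDims(theta, seg)
    enc <- .segEncode(seg)
    se <- .sigEncode(counts, seg)
    if (any(se$spc == 0))
        warning("signature(s) ",
                paste(vapply(counts@signatures[se$spc == 0], paste,
                             character(1), collapse = "-"), collapse = ", "),
                " are geometrically impossible at L = ", se$L,
                "; inconsistent input")
    cpp_loglik(theta@pi, theta@p, theta@q,
               enc$segLen, enc$btype, enc$bpar, se$L,
               se$first, se$pattern, se$logspc, se$counts)
}

#' Structural identifiability of the parameters
#'
#' A usage parameter carries no read information when no observed
#' signature overlaps either segment adjacent to its boundary; such
#' parameters are reported as NA downstream. The initial proportion pi is
#' flagged unidentifiable for single-segment genes (the likelihood is
#' constant in pi there) and when no signature overlaps the first
#' segment.
#'
#' @param counts a \linkS4class{SignatureCounts}.
#' @param seg a \linkS4class{GeneSegmentation}.
#' @return list with logical elements `pi`, `p` (length Ms), `q`
#'   (length Me).
#' @export
checkIdentifiability <- function(counts, seg) {
    M <- nSegments(seg)
    covered <- logical(M)
    for (s in counts@signatures) covered[s] <- TRUE
    piOK <- M > 1 && covered[1]
    p <- logical(nStartSites(seg))
    q <- logical(nEndSites(seg))
    for (b in seq_len(M - 1)) {
        ok <- covered[b] || covered[b + 1]
        if (seg@boundaryKind[b] == "start") p[seg@boundaryParam[b]] <- ok
        else q[seg@boundaryParam[b]] <- ok
    }
    list(pi = piOK, p = p, q = q)
}
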