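#' Probability of one transcript path under the chain
#'
#' The chain starts in state Z1 = 1 with probability pi. At an exon start
#' site the intronic state (0) enters an exon (1) with the site's usage
#' p_m, while an exonic state passes through unchanged; at an exon end
#' site the exonic state (1) ends the exon (0) with usage q_m, while an
#' intronic state passes through. Transitions 1 -> 0 at start sites and
#' 0 -> 1 at end sites are impossible and give probability 0.
#'
#' @param Z binary inclusion vector of length `nSegments(seg)`.
#' @param theta a \linkS4class{ChainParameters}.
#' @param seg a \linkS4class{GeneSegmentation}.
#' @param log return the log probability (exact zeros give `-Inf`).
#' @return the path probability w_theta(Z).
#' @export
pathProbability <- function(Z, theta, seg, log = FALSE) {
    .checkThetaDims(theta, seg)
    M <- nSegments(seg)
    if (length(Z) != M) stop("Z must have length ", M)
    if (!all(Z %in% c(0, 1))) stop("Z must be binary")
    lp <- if (Z[1] == 1) log(theta@pi) else log1p(-theta@pi)
    for (b in seq_len(M - 1)) {
        par <- .boundaryParamValue(theta, seg, b)
        f <- if (seg@boundaryKind[b] == "start") {
            if (Z[b] == 0) (if (Z[b + 1] == 1) par else 1 - par)
            else (if (Z[b + 1] == 1) 1 else 0)
        } else {
            if (Z[b] == 1) (if (Z[b + 1] == 0) par else 1 - par)
            else (if (Z[b + 1] == 0) 1 else 0)
        }
        lp <- lp + if (f > 0) log(f) else -Inf
    }
    if (log) lp else exp(lp)
}

.boundaryParamValue <- function(theta, seg, b) {
    if (seg@boundaryKind[b] == "start") theta@p[seg@boundaryParam[b]]
    else theta@q[seg@boundaryParam[b]]
}

.checkThetaDims <- function(theta, seg) {
    if (length(theta@p) != nStartSites(seg) ||
        length(theta@q) != nEndSites(seg))
        stop(sprintf(
            "theta dimensions (|p|=%d, |q|=%d) do not match segmentation (Ms=%d, Me=%d)",
            length(theta@p), length(theta@q),
            nStartSites(seg), nEndSites(seg)))
    invisible(TRUE)
}

# encode boundary typing for the compiled routines
.segEncode <- function(seg) {
    list(segLen = seg@segLengths,
         btype = as.integer(seg@boundaryKind == "end"),
         bpar = seg@boundaryParam)
}

#' Enumerate all transcript paths (brute-force oracle)
#'
#' Lists every binary inclusion vector over the M segments with its chain
#' probability and transcribed length. Intended as an exact reference for
#' small genes; refuses M > 20.
#'
#' @inheritParams pathProbability
#' @param L optional read length; when given, the effective length
#'   `max(tl - L + 1, 0)` of each path is included.
#' @return a list with elements `paths` (2^M x M 0/1 matrix), `prob`,
#'   `tl` (transcribed length, bp) and, if `L` was supplied, `effLen`.
#' @export
enumeratePaths <- function(theta, seg, L = NULL) {
    .checkThetaDims(theta, seg)
    M <- nSegments(seg)
    if (M > 20) stop("enumeratePaths is limited to M <= 20 (got M = ", M, ")")
    paths <- as.matrix(expand.grid(rep(list(0:1), M), KEEP.OUT.ATTRS = FALSE))
    dimnames(paths) <- NULL
    storage.mode(paths) <- "integer"
    prob <- ifelse(paths[, 1] == 1, theta@pi, 1 - theta@pi)
    for (b in seq_len(M - 1)) {
        par <- .boundaryParamValue(theta, seg, b)
        z0 <- paths[, b]; z1 <- paths[, b + 1]
        f <- if (seg@boundaryKind[b] == "start") {
            ifelse(z0 == 0, ifelse(z1 == 1, par, 1 - par),
                   ifelse(z1 == 1, 1, 0))
        } else {
            ifelse(z0 == 1, ifelse(z1 == 0, par, 1 - par),
                   ifelse(z1 == 0, 1, 0))
        }
        prob <- prob * f
    }
    tl <- as.vector(paths %*% seg@segLengths)
    out <- list(paths = paths, prob = prob, tl = tl)
    if (!is.null(L)) out$effLen <- pmax(tl - L + 1, 0)
    out
}

#' Marginal transcription probabilities P(Z_i = 1)
#'
#' Forward-pass marginals of the chain, one per segment.
#'
#' @inheritParams pathProbability
#' @return numeric vector of length `nSegments(seg)`.
#' @export
transcribedMarginals <- function(theta, seg) {
    .checkThetaDims(theta, seg)
    enc <- .segEncode(seg)
    as.numeric(cpp_forward_marginals(theta@pi, theta@p, theta@q,
                                     enc$btype, enc$bpar))
}

#' Expected effective length of a random transcript
#'
#' The normalizer sum_Z l(Z) w(Z) of the read-generation model, where
#' l(Z) = max(tl(Z) - L + 1, 0) is the number of read start positions a
#' path offers. Computed exactly by dynamic programming over segments and
#' transcribed-length buckets capped at L.
#'
#' @inheritParams pathProbability
#' @param L read length in bp.
#' @return expected effective length in bp (possibly 0).
#' @export
expectedEffectiveLength <- function(theta, seg, L) {
    .checkThetaDims(theta, seg)
    stopifnot(L >= 1)
    enc <- .segEncode(seg)
    cpp_expected_eff_len(theta@pi, theta@p, theta@q,
                         enc$segLen, enc$btype, enc$bpar, as.integer(L))
}

#' Conditional and marginal site usages
#'
#' For each internal boundary, reports the conditional usage (the chain
#' parameter itself: the probability the site is used given the splicing
#' process considers it) and the marginal usage, i.e. the probability an
#' exon actually starts (P(Z_i = 0) * p_m) or ends (P(Z_i = 1) * q_m)
#' there under the chain. The usage of the terminal gene TES, conditional
#' on transcription reaching the last segment, is 1 by construction and
#' is not listed.
#'
#' @inheritParams pathProbability
#' @return a data.frame with one row per internal boundary: `boundary`
#'   (index of the upstream segment), `kind`, `param`, `conditional`,
#'   `marginal`.
#' @export
marginalSiteUsage <- function(theta, seg) {
    .checkThetaDims(theta, seg)
    M <- nSegments(seg)
    if (M == 1)
        return(data.frame(boundary = integer(0), kind = character(0),
                          param = integer(0), conditional = numeric(0),
                          marginal = numeric(0)))
    marg <- transcribedMarginals(theta, seg)
    b <- seq_len(M - 1)
    cond <- vapply(b, function(i) .boundaryParamValue(theta, seg, i), numeric(1))
    marginal <- ifelse(seg@boundaryKind == "start",
                       (1 - marg[b]) * cond, marg[b] * cond)
    data.frame(boundary = b, kind = seg@boundaryKind,
               param = seg@boundaryParam, conditional = cond,
               marginal = marginal)
}

#' Random chain parameters
#'
#' Draws each usage uniformly from `range`; convenient for property
#' checks and simulations.
#'
#' @param seg a \linkS4class{GeneSegmentation}.
#' @param range lower and upper bound of the uniform draw.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @export
randomChainParameters <- function(seg, range = c(0.05, 0.95), seed = NULL) {
    withLocalSeed(seed, {
        n <- 1L + nStartSites(seg) + nEndSites(seg)
        u <- runif(n, range[1], range[2])
        ChainParameters(pi = u[1],
                        p = u[seq_len(nStartSites(seg)) + 1L],
                        q = u[seq_len(nEndSites(seg)) + 1L + nStartSites(seg)])
    })
}
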