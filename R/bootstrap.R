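#' Multinomial resampling of signature counts
#'
#' Draws a bootstrap replicate c* ~ multinomial(c_1/N, ..., c_J/N; N):
#' the resampled counts always sum to the original total N. Signatures
#' drawn zero times are dropped from the replicate.
#'
#' @param counts a \linkS4class{SignatureCounts}.
#' @param seed optional RNG seed (restores the caller's RNG state).
#' @return a \linkS4class{SignatureCounts} with resampled counts.
#' @export
resampleCounts <- function(counts, seed = NULL) {
    stopifnot(is(counts, "SignatureCounts"))
    N <- totalReads(counts)
    if (N < 1) stop("cannot resample empty counts")
    withLocalSeed(seed, {
        cb <- as.numeric(rmultinom(1, size = N, prob = counts@counts / N))
        keep <- cb > 0
        new("SignatureCounts", geneID = counts@geneID,
            signatures = counts@signatures[keep], counts = cb[keep],
            readLength = counts@readLength,
            nDiscarded = counts@nDiscarded)
    })
}

#' Bootstrap confidence intervals for the usage estimates
#'
#' Refits the model on B multinomially resampled replicates of the
#' signature counts and returns percentile intervals (empirical
#' quantiles of the replicate estimates, inverted-ECDF type) at the
#' given level. Intervals are reported per identifiable parameter; runs
#' are deterministic given `seed`. A replicate whose fit fails is
#' redrawn (bounded retries).
#'
#' Interval non-overlap between two individuals can be tested with
#' [ciOverlap()]; note that no multiple-testing correction is applied
#' when many sites are compared this way.
#'
#' @param counts a \linkS4class{SignatureCounts}.
#' @param seg a \linkS4class{GeneSegmentation}.
#' @param B number of bootstrap replicates (>= 2).
#' @param level confidence level.
#' @param seed RNG seed.
#' @param tol,maxIter passed to [emFit()].
#' @return a \linkS4class{BootstrapCI}.
#' @export
bootstrapFit <- function(counts, seg, B = 100, level = 0.95, seed = NULL,
                         tol = 1e-6, maxIter = 1000) {
    stopifnot(B >= 2, level > 0, level < 1)
    pnames <- names(thetaVector(
        ChainParameters(0.5, rep(0.5, nStartSites(seg)),
                        rep(0.5, nEndSites(seg)))))
    est <- matrix(NA_real_, nrow = B, ncol = length(pnames),
                  dimnames = list(NULL, pnames))
    withLocalSeed(seed, {
        for (b in seq_len(B)) {
            fit <- NULL
            for (try in 1:5) {
                cb <- resampleCounts(counts)
                fit <- tryCatch(
                    emFit(cb, seg, tol = tol, maxIter = maxIter),
                    error = function(e) NULL)
                if (!is.null(fit)) break
                message("bootstrap replicate ", b, " redrawn (fit failed)")
            }
            if (is.null(fit))
                stop("bootstrap replicate ", b, " failed repeatedly")
            est[b, ] <- thetaVector(fit@theta)
        }
    })
    idf <- checkIdentifiability(counts, seg)
    idfv <- c(idf$pi, idf$p, idf$q)
    a <- (1 - level) / 2
    lower <- apply(est, 2, quantile, probs = a, type = 1, names = FALSE)
    upper <- apply(est, 2, quantile, probs = 1 - a, type = 1, names = FALSE)
    lower[!idfv] <- NA_real_
    upper[!idfv] <- NA_real_
    new("BootstrapCI", geneID = counts@geneID, B = as.integer(B),
        level = level,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
        estimates = est,
        lower = setNames(lower, pnames), upper = setNames(upper, pnames))
}

#' Do two sets of confidence intervals overlap?
#'
#' Parameter-wise overlap predicate for two \linkS4class{BootstrapCI}
#' objects over the same gene, as used when contrasting an individual
#' carrying a splicing variant with a control: non-overlapping intervals
#' flag a significantly different usage. No multiple-testing correction
#' is applied.
#'
#' @param a,b \linkS4class{BootstrapCI} objects with matching parameters.
#' @return named logical vector (NA where either interval is NA).
#' @export
ciOverlap <- function(a, b) {
    stopifnot(is(a, "BootstrapCI"), is(b, "BootstrapCI"))
    if (!identical(names(a@lower), names(b@lower)))
        stop("interval parameter sets differ")
    a@lower <= b@upper & b@lower <= a@upper
}
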