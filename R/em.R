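#' Maximum-likelihood estimation of splice site usages by EM
#'
#' Fits the chain parameters to signature counts. The E-step computes,
#' by a forward-backward pass over segments conditioned on each
#' signature's span pattern, the expected number of each boundary
#' transition and of the initial state under the posterior over
#' transcript paths. The M-step maximizes the expected complete-data
#' log-likelihood, whose normalizer (the expected effective length) is
#' itself a function of the parameters: it is linear in each individual
#' parameter, so each conditional maximization reduces to the root of a
#' quadratic and is solved exactly (an ECM scheme). The observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' Signatures that are geometrically impossible at the stored read
#' length are dropped with a warning. Parameters are kept in
#' `[1e-9, 1 - 1e-9]` during iteration; estimates within `1e-6` of 0 or
#' 1 are flagged as boundary estimates.
#'
#' @param counts a \linkS4class{SignatureCounts}.
#' @param seg a \linkS4class{GeneSegmentation}.
#' @param init `"default"` (all parameters 0.5), `"random"`, or a
#'   \linkS4class{ChainParameters} to start from.
#' @param tol convergence threshold on the relative change in
#'   log-likelihood.
#' @param maxIter maximum number of EM iterations.
#' @param restarts number of seeded random re-initializations attempted
#'   when the likelihood is non-finite at the start.
#' @param seed seed for random initializations.
#' @param polish refine the converged EM solution with a box-constrained
#'   quasi-Newton ascent of the observed log-likelihood; the refinement
#'   is kept only if it improves the likelihood. Speeds up the final
#'   approach along low-curvature directions where EM converges slowly.
#' @return a \linkS4class{SpliceFit}.
#' @examples
#' seg <- buildSegmentation(exampleTranscripts())
#' theta <- ChainParameters(0.5, p = c(.3, .7, .4, .6), q = c(.5, .4, .6))
#' sim <- simulateReads(seg, theta, N = 5000, L = 100, seed = 1)
#' fit <- emFit(sim$counts, seg)
#' fittedTheta(fit)
#' @export
emFit <- function(counts, seg, init = "default", tol = 1e-6,
                  maxIter = 1000, restarts = 3, seed = NULL,
                  polish = TRUE) {
    stopifnot(is(counts, "SignatureCounts"), is(seg, "GeneSegmentation"))
    if (nSignatures(counts) == 0 || totalReads(counts) < 1)
        stop("signature counts are empty")
    if (sum(seg@segLengths) < counts@readLength)
        stop("gene span (", sum(seg@segLengths),
             " bp) is shorter than the read length; no path can emit a read")

    se <- .sigEncode(counts, seg)
    if (any(se$spc == 0)) {
        warning(sum(se$spc == 0), " geometrically impossible signature(s) ",
                "dropped from the fit")
        keep <- se$spc > 0
        counts <- new("SignatureCounts", geneID = counts@geneID,
                      signatures = counts@signatures[keep],
                      counts = counts@counts[keep],
                      readLength = counts@readLength,
                      nDiscarded = counts@nDiscarded +
                          as.integer(sum(counts@counts[!keep])))
        if (nSignatures(counts) == 0)
            stop("no geometrically possible signature remains")
        se <- .sigEncode(counts, seg)
    }
    enc <- .segEncode(seg)
    Ms <- nStartSites(seg)
    Me <- nEndSites(seg)

    theta0 <- if (is(init, "ChainParameters")) {
        .checkThetaDims(init, seg)
        init
    } else if (identical(init, "default")) {
        ChainParameters(0.5, rep(0.5, Ms), rep(0.5, Me))
    } else if (identical(init, "random")) {
        randomChainParameters(seg, seed = seed)
    } else stop("unknown init")

    run <- function(th) {
        cpp_em_fit(th@pi, th@p, th@q, enc$segLen, enc$btype, enc$bpar,
                   se$L, se$first, se$pattern, se$logspc, se$counts,
                   tol, as.integer(maxIter))
    }
    res <- run(theta0)
    tries <- 0
    while (!is.finite(res$logLik) && tries < restarts) {
        tries <- tries + 1
        res <- run(randomChainParameters(seg,
            seed = if (is.null(seed)) NULL else seed + tries))
    }
    if (!is.finite(res$logLik))
        stop("likelihood non-finite after ", restarts, " restarts")

    if (polish && Ms + Me >= 1) {
        eps <- 1e-9
        obj <- function(v) -cpp_loglik(v[1], v[1 + seq_len(Ms)],
                                       v[1 + Ms + seq_len(Me)],
                                       enc$segLen, enc$btype, enc$bpar,
                                       se$L, se$first, se$pattern,
                                       se$logspc, se$counts)
        v0 <- pmin(pmax(c(res$pi, res$p, res$q), eps), 1 - eps)
        opt <- tryCatch(
            optim(v0, obj, method = "L-BFGS-B", lower = eps,
                  upper = 1 - eps,
                  control = list(factr = 100, maxit = 2000)),
            error = function(e) NULL)
        if (!is.null(opt) && is.finite(opt$value) &&
            -opt$value > res$logLik) {
            res$pi <- opt$par[1]
            res$p <- opt$par[1 + seq_len(Ms)]
            res$q <- opt$par[1 + Ms + seq_len(Me)]
            res$logLik <- -opt$value
            res$trace <- c(res$trace, res$logLik)
        }
    }

    theta <- ChainParameters(res$pi, res$p, res$q)
    idf <- checkIdentifiability(counts, seg)
    bnd <- function(v) v < 1e-6 | v > 1 - 1e-6
    new("SpliceFit",
        geneID = seg@geneID, theta = theta,
        logLik = res$logLik, logLikTrace = res$trace,
        converged = res$converged, iterations = as.integer(res$iterations),
        identifiable = idf,
        atBoundary = list(pi = bnd(res$pi), p = bnd(res$p), q = bnd(res$q)))
}

#' Per-boundary usage estimates as a table
#'
#' One row per modeled boundary with the conditional usage estimate (NA
#' when the parameter is unidentifiable), the marginal usage implied by
#' the fitted chain, and the number of reads whose signature overlaps a
#' segment adjacent to the boundary. A first row reports the initial
#' proportion pi (boundary kind `"TSS"`).
#'
#' @param fit a \linkS4class{SpliceFit}.
#' @param seg the \linkS4class{GeneSegmentation} that was fitted.
#' @param counts the \linkS4class{SignatureCounts} that were fitted
#'   (for supporting-read tallies); optional.
#' @return a data.frame with columns `gene_id`, `boundary_coordinate`,
#'   `boundary_kind`, `parameter_index`, `estimate`, `marginal_usage`,
#'   `identifiable_flag`, `n_supporting_reads`.
#' @export
usageTable <- function(fit, seg, counts = NULL) {
    theta <- fit@theta
    M <- nSegments(seg)
    supp <- function(segs) {
        if (is.null(counts)) return(NA_real_)
        sum(counts@counts[vapply(counts@signatures,
            function(s) any(s %in% segs), logical(1))])
    }
    usage <- marginalSiteUsage(theta, seg)
    coords <- boundaryCoords(seg)
    est <- vapply(seq_len(max(M - 1, 0)), function(b) {
        ok <- if (seg@boundaryKind[b] == "start")
            fit@identifiable$p[seg@boundaryParam[b]]
        else fit@identifiable$q[seg@boundaryParam[b]]
        if (ok) usage$conditional[b] else NA_real_
    }, numeric(1))
    rows <- if (M == 1) NULL else data.frame(
        gene_id = seg@geneID,
        boundary_coordinate = if (M > 1) coords else integer(0),
        boundary_kind = seg@boundaryKind,
        parameter_index = seg@boundaryParam,
        estimate = est,
        marginal_usage = usage$marginal,
        identifiable_flag = !is.na(est),
        n_supporting_reads = vapply(seq_len(M - 1),
            function(b) supp(c(b, b + 1)), numeric(1)),
        stringsAsFactors = FALSE)
    piRow <- data.frame(
        gene_id = seg@geneID,
        boundary_coordinate = if (seg@strand == "+") seg@geneStart + 1L
                              else seg@geneStart + sum(seg@segLengths),
        boundary_kind = "TSS", parameter_index = NA_integer_,
        estimate = if (fit@identifiable$pi) theta@pi else NA_real_,
        marginal_usage = theta@pi,
        identifiable_flag = fit@identifiable$pi,
        n_supporting_reads = supp(1),
        stringsAsFactors = FALSE)
    rbind(piRow, rows)
}
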