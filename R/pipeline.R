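#' End-to-end usage estimation for the genes of an annotation
#'
#' Runs the full pipeline for each selected gene: segmentation from the
#' GTF, signature counting from a BAM file or a precomputed signature
#' TSV (exactly one of the two), EM fit and, optionally, bootstrap
#' confidence intervals. Per-gene result tables are written next to
#' `outPrefix` and also returned. Genes whose transcripts occupy
#' disjoint loci are split into one chain per locus; genes without
#' usable reads are skipped with a logged reason.
#'
#' @param gtf path to the gene annotation (GTF).
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param signatureFile path to a signature-count TSV
#'   ([writeSignatureCounts()]); alternative to `bam`.
#' @param genes optional character vector of gene ids to process.
#' @param readLength read length override for BAM counting.
#' @param tol,maxIter EM settings.
#' @param bootstrapB number of bootstrap replicates (0 disables).
#' @param level bootstrap confidence level.
#' @param seed RNG seed, recorded in all outputs.
#' @param outPrefix path prefix for output files; `NULL` writes nothing.
#' @param verbose log progress.
#' @return invisibly, a list per gene with elements `seg`, `counts`,
#'   `fit`, `estimates`, and `ci` (when bootstrapped), plus a `log`
#'   data.frame of per-gene status.
#' @export
runFit <- function(gtf, bam = NULL, signatureFile = NULL, genes = NULL,
                   readLength = NULL, tol = 1e-6, maxIter = 1000,
                   bootstrapB = 0, level = 0.95, seed = NULL,
                   outPrefix = NULL, verbose = TRUE) {
    if (is.null(bam) == is.null(signatureFile))
        stop("supply exactly one of 'bam' and 'signatureFile'")
    say <- function(...) if (verbose) message(...)
    exons <- readTranscriptsGTF(gtf)
    if (!is.null(genes)) exons <- exons[exons$gene_id %in% genes, ]
    if (nrow(exons) == 0) stop("no exon features for the selected genes")
    sigTab <- if (!is.null(signatureFile)) readSignatureCounts(signatureFile)

    results <- list()
    logRows <- list()
    for (gid in unique(exons$gene_id)) {
        loci <- splitGeneLoci(exons[exons$gene_id == gid, , drop = FALSE])
        for (lname in names(loci)) {
            status <- tryCatch({
                seg <- buildSegmentation(loci[[lname]])
                counts <- if (!is.null(bam)) {
                    countSignatures(bam, seg, L = readLength)
                } else {
                    sc <- sigTab[[lname]]
                    if (is.null(sc)) sc <- sigTab[[gid]]
                    if (is.null(sc)) stop("no signature counts for gene")
                    sc
                }
                fit <- emFit(counts, seg, tol = tol, maxIter = maxIter,
                             seed = seed)
                est <- usageTable(fit, seg, counts)
                res <- list(seg = seg, counts = counts, fit = fit,
                            estimates = est)
                if (bootstrapB > 0) {
                    res$ci <- bootstrapFit(counts, seg, B = bootstrapB,
                                           level = level, seed = seed,
                                           tol = tol, maxIter = maxIter)
                }
                results[[lname]] <- res
                say(sprintf(
                    "%s: M=%d, N=%d reads (%d discarded), logLik=%.6g, %s",
                    lname, nSegments(seg), as.integer(totalReads(counts)),
                    discardedReads(counts), logLik(fit),
                    if (fit@converged) "converged" else "NOT converged"))
                sprintf("ok: N=%d discarded=%d converged=%s",
                        as.integer(totalReads(counts)),
                        discardedReads(counts), fit@converged)
            }, error = function(e) {
                say(sprintf("%s: skipped (%s)", lname, conditionMessage(e)))
                paste("skipped:", conditionMessage(e))
            })
            logRows[[lname]] <- data.frame(gene = lname, status = status,
                                           stringsAsFactors = FALSE)
        }
    }
    if (length(results) == 0) stop("no gene could be processed")
    logTab <- do.call(rbind, logRows)

    if (!is.null(outPrefix)) {
        .writeRunOutputs(results, logTab, outPrefix, seed, level)
    }
    invisible(c(results, list(log = logTab)))
}

# stable numeric formatting for file outputs: 6 significant digits, NA kept
.fmt6 <- function(x) ifelse(is.na(x), "NA", formatC(signif(x, 6),
                                                    format = "g", digits = 6))

.writeRunOutputs <- function(results, logTab, outPrefix, seed, level) {
    seedLine <- sprintf("# seed=%s", if (is.null(seed)) "NA" else seed)
    segTab <- do.call(rbind, lapply(results, function(r)
        segmentationTable(r$seg)))
    estTab <- do.call(rbind, lapply(results, function(r) {
        e <- r$estimates
        e$estimate <- .fmt6(e$estimate)
        e$marginal_usage <- .fmt6(e$marginal_usage)
        e
    }))
    writeTsv <- function(tab, path) {
        con <- file(path, "w")
        writeLines(seedLine, con)
        suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                                     row.names = FALSE))
        close(con)
    }
    writeTsv(segTab, paste0(outPrefix, "_segments.tsv"))
    writeTsv(estTab, paste0(outPrefix, "_estimates.tsv"))
    ciRows <- lapply(results, function(r) {
        if (is.null(r$ci)) return(NULL)
        ci <- confInt(r$ci)
        data.frame(gene_id = geneID(r$seg), parameter = ci$parameter,
                   estimate = .fmt6(thetaVector(fittedTheta(r$fit))),
                   ci_lower = .fmt6(ci$lower), ci_upper = .fmt6(ci$upper),
                   B = r$ci@B, level = level, stringsAsFactors = FALSE)
    })
    ciRows <- ciRows[!vapply(ciRows, is.null, logical(1))]
    if (length(ciRows))
        writeTsv(do.call(rbind, ciRows), paste0(outPrefix, "_bootstrap.tsv"))
    writeTsv(logTab, paste0(outPrefix, "_log.tsv"))
    invisible(NULL)
}

#' Read a key-value simulation config
#'
#' One `key = value` pair per line; `#` starts a comment; vector values
#' are comma-separated. Recognized keys: `Ms`, `Me`, `lengthRange`, `N`,
#' `L`, `seed`, `pi`, `p`, `q`, `emitSam`.
#'
#' @param file config path.
#' @return a named list.
#' @export
readSimulationConfig <- function(file) {
    lines <- readLines(file)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines[nzchar(trimws(lines))])
    cfg <- list()
    for (ln in lines) {
        kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
        if (length(kv) != 2) stop("malformed config line: ", ln)
        key <- trimws(kv[1])
        val <- trimws(strsplit(kv[2], ",", fixed = TRUE)[[1]])
        num <- suppressWarnings(as.numeric(val))
        cfg[[key]] <- if (!anyNA(num)) num else val
    }
    cfg
}

#' Simulate a fixture bundle
#'
#' Generates a synthetic gene, simulates reads from given or random true
#' parameters, and writes the bundle: signature counts TSV, ground-truth
#' usage TSV, the gene's GTF and segmentation, an optional SAM file, and
#' a manifest recording the true parameters and seed.
#'
#' @param config a list (or [readSimulationConfig()] result) with
#'   entries `Ms`, `Me`, `N`, `L`, `seed` and optionally `lengthRange`,
#'   `pi`, `p`, `q`, `emitSam`.
#' @param outPrefix path prefix for outputs.
#' @return invisibly, the simulation result list plus the segmentation.
#' @export
runSimulate <- function(config, outPrefix) {
    need <- c("Ms", "Me", "N", "L", "seed")
    miss <- setdiff(need, names(config))
    if (length(miss))
        stop("config lacks entries: ", paste(miss, collapse = ", "))
    cfg <- modifyList(list(lengthRange = c(50, 300), emitSam = 0), config)
    seed <- as.integer(cfg$seed)
    seg <- randomSegmentation(cfg$Ms, cfg$Me, lengthRange = cfg$lengthRange,
                              seed = seed)
    theta <- if (!is.null(cfg$pi)) {
        ChainParameters(cfg$pi, cfg$p, cfg$q)
    } else randomChainParameters(seg, seed = seed + 1L)
    .checkThetaDims(theta, seg)
    emitSam <- isTRUE(cfg$emitSam == 1) || isTRUE(cfg$emitSam)
    sim <- simulateReads(seg, theta, N = cfg$N, L = cfg$L, seed = seed + 2L,
                         keepReads = emitSam)
    writeSignatureCounts(sim$counts, paste0(outPrefix, "_signatures.tsv"))
    write.table(sim$truth$usage, paste0(outPrefix, "_truth.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(segmentationTable(seg), paste0(outPrefix, "_segments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .writeSegmentsAsGTF(seg, paste0(outPrefix, ".gtf"))
    if (emitSam)
        writeSimulatedSam(sim, seg, paste0(outPrefix, ".sam"))
    manifest <- c(
        sprintf("seed = %d", seed),
        sprintf("N = %d", as.integer(cfg$N)),
        sprintf("L = %d", as.integer(cfg$L)),
        sprintf("pi = %s", .fmt6(initialProb(theta))),
        sprintf("p = %s", paste(.fmt6(startUsages(theta)), collapse = ",")),
        sprintf("q = %s", paste(.fmt6(endUsages(theta)), collapse = ",")))
    writeLines(manifest, paste0(outPrefix, "_manifest.txt"))
    invisible(list(sim = sim, seg = seg, theta = theta))
}

# express a synthetic segmentation as a GTF: one transcript per distinct
# emittable path is overkill, so emit the two extreme isoforms that
# realize every boundary (all-exon and per-boundary alternating), enough
# for buildSegmentation to reproduce the segmentation exactly
.writeSegmentsAsGTF <- function(seg, file) {
    tab <- segmentationTable(seg)
    cuts <- c(0L, cumsum(seg@segLengths))
    geneLen <- sum(seg@segLengths)
    # one transcript per segment pair spanning the whole gene, with exactly
    # one "intron" per internal boundary is not generally valid; instead
    # emit single-exon-per-segment transcripts anchored at TSS/TES
    txs <- list()
    M <- nSegments(seg)
    bnd <- .boundaryOffsets(seg)
    starts <- c(0L, bnd[seg@boundaryKind == "start"])
    ends <- c(bnd[seg@boundaryKind == "end"], geneLen)
    k <- 0
    for (s in starts) {
        e <- ends[ends > s][1]    # nearest end site downstream
        if (is.na(e)) e <- geneLen
        k <- k + 1
        txs[[k]] <- c(s, e)
    }
    for (e in ends) {
        s <- rev(starts[starts < e])[1]
        if (is.na(s)) s <- 0L
        k <- k + 1
        txs[[k]] <- c(s, e)
    }
    # anchor the gene span
    txs[[k + 1]] <- c(0L, geneLen)
    geneEnd <- seg@geneStart + geneLen
    rows <- do.call(rbind, lapply(seq_along(txs), function(i) {
        a <- txs[[i]][1]; b <- txs[[i]][2]
        if (seg@strand == "+") {
            data.frame(start = seg@geneStart + a + 1L,
                       end = seg@geneStart + b)
        } else {
            data.frame(start = geneEnd - b + 1L, end = geneEnd - a)
        }
    }))
    exons <- data.frame(gene_id = seg@geneID,
                        transcript_id = sprintf("sim_tx%02d", seq_len(nrow(rows))),
                        chrom = seg@chrom, strand = seg@strand,
                        start = rows$start, end = rows$end,
                        stringsAsFactors = FALSE)
    writeTranscriptsGTF(exons, file)
    invisible(file)
}
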