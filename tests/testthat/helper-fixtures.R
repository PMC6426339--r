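# shared fixtures: all built in code, nothing on disk

# a RatioProfile over 1 kb bins; values may be a list (one element per chromosome)
makeProfile <- function(values, smoothingN = 0L) {
    if (!is.list(values)) values <- list(chr1 = values)
    if (is.null(names(values)))
        names(values) <- paste0("chr", seq_along(values))
    lens <- vapply(values, function(v) 1000L * length(v), integer(1))
    fmap <- buildBinMap(lens, 1000)
    new("RatioProfile", fmap = fmap, values = unlist(values, use.names = FALSE),
        smoothingN = as.integer(smoothingN), quantileNormalized = FALSE)
}

# alignments GRanges from 0-based coordinates
makeAln <- function(chrom, start0, end0, mapq = 60L, flag = 0L) {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1L, end = end0))
    gr$mapq <- rep_len(as.integer(mapq), length(gr))
    gr$flag <- rep_len(as.integer(flag), length(gr))
    gr
}

# independent brute-force oracle for the max circular-arc t statistic:
# plain double loop over all (i, j], pooled variance, same tie-break
bruteMaxArc <- function(x, minWidth = 1L) {
    n <- length(x)
    best <- -Inf; bi <- NA_integer_; bj <- NA_integer_
    for (i in 0:(n - 1)) {
        if (i + minWidth > n) break
        for (j in seq.int(i + minWidth, n)) {
            k <- j - i
            if (k > n - minWidth) next
            arc <- x[(i + 1):j]
            rest <- x[-((i + 1):j)]
            ma <- mean(arc); mb <- mean(rest)
            ss <- sum((arc - ma)^2) + sum((rest - mb)^2)
            s2 <- max(ss / max(n - 2, 1), 1e-12)
            tt <- abs((ma - mb) / sqrt(s2 * (1 / k + 1 / (n - k))))
            if (tt > best) { best <- tt; bi <- i; bj <- j }
        }
    }
    list(i = bi, j = bj, stat = best)
}

# small simulated experiment for tests that need reads quickly
smallSim <- function(seed, genomeLength = 4e6, nChromosomes = 1,
                     readsPerSample = 2e5, ...) {
    simulateDamIDExperiment(simParams(
        genomeLength = genomeLength, nChromosomes = nChromosomes,
        readsPerSample = readsPerSample, seed = seed, ...))
}

# plain GRanges from 0-based half-open coordinates
gr0 <- function(chrom, start0, end0, ...) {
    gr <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(start = start0 + 1, end = end0))
    mc <- list(...)
    for (nm in names(mc)) S4Vectors::mcols(gr)[[nm]] <- mc[[nm]]
    gr
}

# 0-based view of a fragment/interval GRanges, for readable assertions
bed3 <- function(gr) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr) - 1L,
               end = BiocGenerics::end(gr))
}
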