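test_that("simulated genomes are reproducible with the expected GATC density", {
    p <- simParams(genomeLength = 1e6, nChromosomes = 1, seed = 3)
    g1 <- simulateGenome(p)
    g2 <- simulateGenome(p)
    expect_identical(as.character(g1), as.character(g2))
    expect_true("chrM" %in% names(g1))
    expect_equal(BiocGenerics::width(g1)[match("chrM", names(g1))], 16000)

    nGatc <- length(findGATCSites(g1[["chr1"]]))
    expectGatc <- 1e6 / 256
    expect_lt(abs(nGatc - expectGatc), 3 * sqrt(expectGatc))

    expect_error(simulateGenome(simParams(genomeLength = -1)),
                 "positive|ladCoverage")
})

test_that("LAD placement hits the target coverage with in-range lengths", {
    p <- simParams(genomeLength = 10e6, nChromosomes = 2,
                   ladCoverage = 0.5, seed = 21)
    g <- simulateGenome(p)
    truth <- simulateLADs(p, g)
    lads <- ladRanges(truth)
    cov <- sum(BiocGenerics::width(lads)) / 10e6
    expect_gte(cov, 0.45); expect_lte(cov, 0.55)
    expect_true(all(BiocGenerics::width(lads) >= 30e3))
    expect_true(all(BiocGenerics::width(lads) <= 2e6))
    expect_equal(length(GenomicRanges::reduce(lads, min.gapwidth = 0L)),
                 length(lads))

    # zero coverage: empty truth, all contact probabilities low
    p0 <- simParams(genomeLength = 2e6, nChromosomes = 1,
                    ladCoverage = 0, seed = 21)
    g0 <- simulateGenome(p0)
    t0 <- simulateLADs(p0, g0)
    expect_equal(length(ladRanges(t0)), 0)
    expect_true(all(t0@contactProb <= p0@contactOut))
})

test_that("amplicon selection requires both flanking sites methylated", {
    p <- simParams(genomeLength = 2e6, nChromosomes = 1, seed = 17)
    g <- simulateGenome(p)
    fmap <- buildFragmentMap(g)
    truth <- simulateLADs(p, g, fmap)
    ampD <- simulateMethylation(truth, fmap, p, "dam")

    # terminal fragments of each chromosome are never amplifiable
    chrom <- as.character(GenomicRanges::seqnames(fragments(fmap)))
    for (ch in unique(chrom)) {
        sel <- which(chrom == ch)
        expect_false(ampD[sel[1]])
        expect_false(ampD[sel[length(sel)]])
    }
    # Dam-only: each internal site methylated with prob 0.5 and adjacent
    # fragments share sites, so the overall amplifiable rate is near 0.25
    inner <- ampD[chrom == "chr1"][-c(1, sum(chrom == "chr1"))]
    expect_lt(abs(mean(inner) - 0.25), 0.02)
    # deterministic given the seed
    expect_identical(ampD, simulateMethylation(truth, fmap, p, "dam"))

    # LaminB1 sample at full in-LAD contact: enrichment inside LADs
    ampL <- simulateMethylation(truth, fmap, p, "lmnb1")
    inLad <- truth@contactProb > 0.5
    expect_gt(mean(ampL[inLad]), mean(ampL[!inLad & chrom != "chrM"]))
})

test_that("simulated reads carry the requested contamination and enrichment", {
    sim <- smallSim(seed = 29, genomeLength = 3e6, readsPerSample = 1e5,
                    chrMFraction = 0.2)
    reads <- sim$reads$lmnb1
    nM <- sum(as.character(GenomicRanges::seqnames(reads)) == "chrM")
    expect_lt(abs(nM - 0.2 * 1e5), 3 * sqrt(1e5 * 0.2 * 0.8) + 1)

    # LaminB1/Dam count ratio inside LADs exceeds the outside ratio
    cl <- readCounts(countReads(sim$fmap, sim$reads$lmnb1))
    cd <- readCounts(countReads(sim$fmap, sim$reads$dam))
    inLad <- sim$truth@contactProb > 0.5
    chrom <- as.character(GenomicRanges::seqnames(fragments(sim$fmap)))
    out <- !inLad & chrom != "chrM"
    ratioIn <- sum(cl[inLad]) / max(sum(cd[inLad]), 1)
    ratioOut <- sum(cl[out]) / max(sum(cd[out]), 1)
    expect_gt(ratioIn, ratioOut)

    # zero reads: empty but valid stream
    p0 <- simParams(genomeLength = 2e6, nChromosomes = 1,
                    readsPerSample = 0, seed = 29)
    g0 <- simulateGenome(p0); f0 <- buildFragmentMap(g0)
    t0 <- simulateLADs(p0, g0, f0)
    r0 <- simulateReads(f0, simulateMethylation(t0, f0, p0, "dam"), p0, "dam")
    expect_equal(length(r0), 0)
    expect_true(all(c("mapq", "flag") %in% names(S4Vectors::mcols(r0))))
})

test_that("the whole simulated experiment is reproducible bit for bit", {
    p <- simParams(genomeLength = 2e6, nChromosomes = 1,
                   readsPerSample = 5e4, seed = 101)
    a <- simulateDamIDExperiment(p)
    b <- simulateDamIDExperiment(p)
    expect_identical(as.character(a$genome), as.character(b$genome))
    expect_identical(bed3(ladRanges(a$truth)), bed3(ladRanges(b$truth)))
    expect_identical(bed3(a$reads$lmnb1), bed3(b$reads$lmnb1))
    expect_identical(a$truthReport, b$truthReport)
})

test_that("reduced sequencing depth degrades LAD recovery gracefully", {
    # depth is the main determinant of data quality: at a tenth of the
    # reference depth the same genome/truth yields worse boundary recovery
    quality <- function(seed, reads) {
        sim <- smallSim(seed = seed, genomeLength = 4e6,
                        readsPerSample = reads)
        res <- runPipeline(sim$fmap, sim$reads$lmnb1, sim$reads$dam,
                           config = pipelineConfig(minCleanReads = 1e3,
                                                   seed = 1))
        cmp <- compareLADs(res$lads, sim$truth)
        c(jaccard = cmp$jaccard, offset = median(cmp$boundaryOffsets))
    }
    seeds <- 1:5
    full <- vapply(seeds, quality, numeric(2), reads = 8e4)
    tenth <- vapply(seeds, quality, numeric(2), reads = 8e3)
    expect_lt(mean(tenth["jaccard", ]), mean(full["jaccard", ]))
    expect_gte(sum(tenth["jaccard", ] < full["jaccard", ]), 4)
    expect_gt(mean(tenth["offset", ]), mean(full["offset", ]))
})
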