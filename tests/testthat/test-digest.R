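test_that("GATC motif finding handles plain, overlappingly spaced and masked input", {
    expect_equal(findGATCSites("GATC"), 0L)
    expect_equal(findGATCSites("AAGATCTTGATCAA"), c(2L, 8L))
    expect_equal(findGATCSites("GATCGATC"), c(0L, 4L))
    expect_equal(findGATCSites("AAAA"), integer(0))
    expect_equal(findGATCSites(""), integer(0))
    # case-insensitive, soft-mask treated as sequence
    expect_equal(findGATCSites("aagatcTT"), 2L)
    # N never matches
    expect_equal(findGATCSites("GANCGATN"), integer(0))
    expect_equal(findGATCSites(Biostrings::DNAString("TTGATCTT")), 2L)
})

test_that("DpnI fragment map cuts at GA^TC and tiles each chromosome", {
    g <- Biostrings::DNAStringSet(c(chr1 = "AAGATCTTGATCAA"))
    fm <- buildFragmentMap(g)
    expect_s4_class(fm, "FragmentMap")
    expect_equal(fragmentMode(fm), "dpnI")
    expect_equal(bed3(fragments(fm)),
                 data.frame(chrom = "chr1", start = c(0L, 4L, 10L),
                            end = c(4L, 10L, 14L)))
    expect_equal(fragments(fm)$fragment_id, 1:3)

    # no GATC: one fragment spanning the chromosome
    g2 <- Biostrings::DNAStringSet(c(chrA = "AAAATTTTCCCC"))
    fm2 <- buildFragmentMap(g2)
    expect_equal(bed3(fragments(fm2)),
                 data.frame(chrom = "chrA", start = 0L, end = 12L))
})

test_that("fragment maps partition random genomes exactly", {
    set.seed(404)
    for (rep in 1:5) {
        lens <- sample(500:3000, 3)
        seqs <- vapply(lens, function(L)
            paste(sample(c("A", "C", "G", "T", "N"), L, replace = TRUE,
                         prob = c(.24, .24, .24, .24, .04)), collapse = ""),
            character(1))
        g <- Biostrings::DNAStringSet(setNames(seqs, paste0("c", 1:3)))
        fm <- buildFragmentMap(g)
        fr <- fragments(fm)
        for (ch in names(g)) {
            w <- BiocGenerics::width(fr[GenomicRanges::seqnames(fr) == ch])
            expect_equal(sum(w), lens[match(ch, names(g))])
        }
        expect_false(any(GenomicRanges::countOverlaps(fr, fr) > 1))
        expect_true(all(diff(fr$fragment_id) == 1))
    }
})

test_that("cut sets of a sequence and its reverse complement mirror each other", {
    set.seed(77)
    s <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
               collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    cuts <- findGATCSites(s) + 2L
    cutsRc <- findGATCSites(rc) + 2L
    expect_gt(length(cuts), 0)
    expect_equal(sort(nchar(s) - cuts), cutsRc)
})

test_that("fixed-size bin maps truncate the final bin at the chromosome end", {
    expect_equal(nrow(bed3(fragments(buildBinMap(c(chr1 = 10000), 2000)))), 5)
    b <- bed3(fragments(buildBinMap(c(chr1 = 10500), 2000)))
    expect_equal(nrow(b), 6)
    expect_equal(b[6, c("start", "end")],
                 data.frame(start = 10000L, end = 10500L, row.names = 6L))
    whole <- bed3(fragments(buildBinMap(c(chr1 = 1500), 2000)))
    expect_equal(whole, data.frame(chrom = "chr1", start = 0L, end = 1500L))
    expect_error(buildBinMap(c(chr1 = 1000), 0), "positive")
    expect_error(buildBinMap(c(chr1 = 1000), -5), "positive")
})

test_that("fragment-size statistics summarize lengths genome-wide", {
    g <- Biostrings::DNAStringSet(c(chr1 = "AAGATCTTGATCAA"))  # lengths 4,6,4
    s <- fragmentSizeStats(buildFragmentMap(g))
    expect_equal(s$median, 4)
    expect_equal(s$nFragments, 3)
    expect_equal(s$fractionUnderThreshold, 1)
    emptyGr <- GenomicRanges::GRanges()
    emptyGr$fragment_id <- integer(0)
    expect_error(fragmentSizeStats(
        new("FragmentMap", ranges = emptyGr,
            mode = "dpnI", binSize = NA_integer_)), "empty")
})

test_that("i.i.d. genome digestion matches the geometric inter-motif model", {
    # GATC density 1/256 per position -> median fragment length
    # ln(0.5)/ln(1 - 1/256) ~ 177 bp
    p <- simParams(genomeLength = 10e6, nChromosomes = 1, seed = 19)
    fm <- buildFragmentMap(simulateGenome(p))
    s <- fragmentSizeStats(fm)
    expect_gte(s$median, 170)
    expect_lte(s$median, 185)
    # geometric tail: essentially everything under 3 kb
    expect_gte(s$fractionUnderThreshold, 0.999)
})

test_that("FragmentMap round-trips through BED exactly", {
    g <- Biostrings::DNAStringSet(c(
        chr1 = "AAGATCTTGATCAAGATCAAAC", chr2 = "TTTTGATCTTTT"))
    fm <- buildFragmentMap(g)
    path <- tempfile(fileext = ".bed")
    writeBed(fm, path)
    fm2 <- readFragmentMap(path, g)
    expect_equal(bed3(fragments(fm2)), bed3(fragments(fm)))
    expect_equal(fragments(fm2)$fragment_id, fragments(fm)$fragment_id)
    unlink(path)
})
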