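# fragment map [0,4), [4,10), [10,14) used by the counting examples
threeFragMap <- function() {
    buildFragmentMap(Biostrings::DNAStringSet(c(chr1 = "AAGATCTTGATCAA")))
}

test_that("read counting in overlap and midpoint modes", {
    fm <- threeFragMap()
    r1 <- makeAln("chr1", 5, 9)  # inside second fragment
    expect_equal(readCounts(countReads(fm, r1, "overlap")), c(0L, 1L, 0L))
    expect_equal(readCounts(countReads(fm, r1, "midpoint")), c(0L, 1L, 0L))

    r2 <- makeAln("chr1", 2, 6)  # spans the first cut
    expect_equal(readCounts(countReads(fm, r2, "overlap")), c(1L, 1L, 0L))
    # midpoint 4 lies in the second fragment
    expect_equal(readCounts(countReads(fm, r2, "midpoint")), c(0L, 1L, 0L))

    # read on an unknown chromosome is tallied, not fatal
    r3 <- suppressWarnings(c(r1, makeAln("chrUn", 0, 50)))
    ct <- countReads(fm, r3)
    expect_equal(ct@nSkipped, 1)
    expect_equal(totalReads(ct), 2)
})

test_that("normalized counts are proportions of the sample read total", {
    fm <- threeFragMap()
    ct <- new("CountTrack", fmap = fm, counts = c(2L, 1L, 1L),
              label = "s", totalReads = 4, nSkipped = 0)
    expect_equal(normalizeCounts(ct), c(0.5, 0.25, 0.25))

    zero <- new("CountTrack", fmap = fm, counts = c(0L, 0L, 0L),
                label = "s", totalReads = 10, nSkipped = 0)
    expect_equal(normalizeCounts(zero), c(0, 0, 0))

    bad <- new("CountTrack", fmap = fm, counts = c(0L, 0L, 0L),
               label = "s", totalReads = 0, nSkipped = 0)
    expect_error(normalizeCounts(bad), "zero total")

    # overlap mode: one read spanning two fragments, total 1 -> sums exceed 1
    spanning <- countReads(fm, makeAln("chr1", 2, 6), "overlap")
    expect_equal(normalizeCounts(spanning), c(1, 1, 0))
})

test_that("log2 ratio with pseudocount is finite and symmetric", {
    fm <- threeFragMap()
    mk <- function(counts, total) new("CountTrack", fmap = fm,
        counts = as.integer(counts), label = "s", totalReads = total,
        nSkipped = 0)
    expect_equal(profileValues(log2Ratio(mk(c(3, 5, 7), 100),
                                         mk(c(3, 5, 7), 100))),
                 c(0, 0, 0))
    # (15+1)/(3+1) with equal totals -> log2(4) = 2
    expect_equal(profileValues(log2Ratio(mk(c(15, 0, 0), 50),
                                         mk(c(3, 0, 0), 50)))[1], 2)
    v <- profileValues(log2Ratio(mk(c(10, 0, 0), 50), mk(c(0, 0, 0), 50)))
    expect_true(all(is.finite(v)))
    other <- buildBinMap(c(chr1 = 14), 7)
    expect_error(log2Ratio(mk(c(1, 1, 1), 3),
                           new("CountTrack", fmap = other, counts = c(1L, 1L),
                               label = "s", totalReads = 2, nSkipped = 0)),
                 "different fragment maps")
})

test_that("quantile normalization maps ranks to across-profile means", {
    p1 <- makeProfile(c(1, 3, 5))
    p2 <- makeProfile(c(2, 4, 8))
    qn <- quantileNormalizeProfiles(list(p1, p2))
    expect_equal(profileValues(qn[[1]]), c(1.5, 3.5, 6.5))
    expect_equal(profileValues(qn[[2]]), c(1.5, 3.5, 6.5))
    expect_true(qn[[1]]@quantileNormalized)

    # identical profiles unchanged
    qn2 <- quantileNormalizeProfiles(list(p1, makeProfile(c(1, 3, 5))))
    expect_equal(profileValues(qn2[[1]]), c(1, 3, 5))

    # single profile: no-op with a notice
    expect_message(qn1 <- quantileNormalizeProfiles(list(p1)), "no-op")
    expect_equal(profileValues(qn1[[1]]), c(1, 3, 5))
})

test_that("quantile normalization preserves rank order and equalizes multisets", {
    set.seed(31)
    vals <- replicate(3, rnorm(200), simplify = FALSE)
    qn <- quantileNormalizeProfiles(lapply(vals, makeProfile))
    out <- lapply(qn, profileValues)
    for (k in 1:3)
        expect_equal(order(out[[k]]), order(vals[[k]]))
    expect_equal(sort(out[[1]]), sort(out[[2]]))
    expect_equal(sort(out[[2]]), sort(out[[3]]))
})

test_that("window smoothing follows the centered, truncated-window rule", {
    p <- makeProfile(c(0, 0, 10, 0, 0))
    expect_equal(profileValues(smoothProfile(p, 2)),
                 c(0, 10/3, 10/3, 10/3, 0))
    # constant profile unchanged at any n
    pc <- makeProfile(rep(2.5, 30))
    expect_equal(profileValues(smoothProfile(pc, 20)), rep(2.5, 30))
    # n = 0 is the identity
    expect_equal(profileValues(smoothProfile(p, 0)), c(0, 0, 10, 0, 0))
    # first element: truncated window mean of elements 1..2
    p2 <- makeProfile(c(4, 8, 0, 0, 0))
    expect_equal(profileValues(smoothProfile(p2, 2))[1], 6)
    # odd n rounds down with a warning
    expect_warning(s <- smoothProfile(p, 3), "rounded down")
    expect_equal(s@smoothingN, 2L)
    expect_error(smoothProfile(p, -2), "non-negative")
})

test_that("smoothing is linear and never crosses chromosome boundaries", {
    set.seed(8)
    x <- rnorm(40); y <- rnorm(40)
    sm <- function(v) profileValues(smoothProfile(makeProfile(v), 6))
    expect_equal(sm(2 * x + 3 * y), 2 * sm(x) + 3 * sm(y))

    # two chromosomes: a spike on chr2 never leaks into chr1
    p <- makeProfile(list(chr1 = rep(0, 10), chr2 = c(100, rep(0, 9))))
    s <- profileValues(smoothProfile(p, 4))
    expect_equal(s[1:10], rep(0, 10))
    expect_gt(s[11], 0)
})

test_that("a smoothed step's zero crossing moves at most n/2 fragments", {
    step <- makeProfile(c(rep(-1, 50), rep(1, 50)))
    for (n in c(10, 20)) {
        s <- profileValues(smoothProfile(step, n))
        crossing <- which(s > 0)[1]
        expect_lte(abs(crossing - 51), n / 2)
    }
})
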