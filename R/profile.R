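#' @include AllClasses.R AllGenerics.R
NULL

#' Count filtered reads per fragment
#'
#' In \code{"overlap"} mode (the default) a read increments every fragment it
#' overlaps by at least 1 bp; in \code{"midpoint"} mode it increments exactly
#' the fragment containing its midpoint.  Reads on chromosomes absent from
#' the fragment map are tallied as skipped, not fatal.  Strand is ignored
#' (Dam methylation of GATC is strand-symmetric).
#'
#' @param fmap a \linkS4class{FragmentMap}.
#' @param aln filtered alignments (\code{GRanges}); see
#'   \code{\link{filterAlignments}}.
#' @param mode \code{"overlap"} or \code{"midpoint"}.
#' @param label sample label stored on the track.
#' @return a \linkS4class{CountTrack}; \code{totalReads} is the number of
#'   alignments supplied (the normalization denominator).
#' @export
countReads <- function(fmap, aln, mode = c("overlap", "midpoint"),
                       label = "sample") {
    mode <- match.arg(mode)
    stopifnot(is(fmap, "FragmentMap"))
    frag <- fmap@ranges
    known <- as.character(GenomicRanges::seqnames(aln)) %in%
        GenomeInfoDb::seqlevels(frag)
    nSkipped <- sum(!known)
    use <- aln[known]
    GenomeInfoDb::seqlevels(use) <- GenomeInfoDb::seqlevels(frag)
    if (mode == "midpoint" && length(use)) {
        # 0-based midpoint floor((start0 + end0) / 2), as a 1 bp point
        mid0 <- (BiocGenerics::start(use) - 1L + BiocGenerics::end(use)) %/% 2L
        use <- GRanges(GenomicRanges::seqnames(use),
                       IRanges::IRanges(start = mid0 + 1L, width = 1L))
    }
    counts <- GenomicRanges::countOverlaps(frag, use, ignore.strand = TRUE)
    new("CountTrack", fmap = fmap, counts = as.integer(counts), label = label,
        totalReads = length(aln), nSkipped = nSkipped)
}

#' Normalized counts: proportion of the sample's reads per fragment
#'
#' \code{normalized[f] = count[f] / totalReads}.  In overlap mode the
#' proportions can sum to more than 1 because a read spanning a cut site is
#' counted in both flanking fragments; the denominator is deliberately the
#' read total of the sample, not the column sum.
#'
#' @param track a \linkS4class{CountTrack} with \code{totalReads > 0}.
#' @return numeric vector of per-fragment proportions.
#' @export
normalizeCounts <- function(track) {
    stopifnot(is(track, "CountTrack"))
    if (track@totalReads <= 0)
        stop("cannot normalize a track with zero total reads")
    track@counts / track@totalReads
}

#' Per-fragment log2(LaminB1-Dam / Dam-only) ratio
#'
#' The DamID signal: \code{log2(((cL + pc)/TL) / ((cD + pc)/TD))} per
#' fragment, where \code{cL, cD} are raw counts, \code{TL, TD} the sample
#' read totals and \code{pc} a pseudocount (default 1 read) guaranteeing
#' finite values on zero-count fragments.
#'
#' @param lmnb1 \linkS4class{CountTrack} of the LaminB1-Dam sample.
#' @param dam \linkS4class{CountTrack} of the Dam-only control.
#' @param pseudocount reads added to both samples (default 1).
#' @return a \linkS4class{RatioProfile} (raw: \code{smoothingN = 0}).
#' @export
log2Ratio <- function(lmnb1, dam, pseudocount = 1) {
    stopifnot(is(lmnb1, "CountTrack"), is(dam, "CountTrack"))
    if (!identical(lmnb1@fmap@ranges, dam@fmap@ranges))
        stop("count tracks are on different fragment maps")
    if (lmnb1@totalReads <= 0 || dam@totalReads <= 0)
        stop("both samples need a positive read total")
    v <- log2(((lmnb1@counts + pseudocount) / lmnb1@totalReads) /
              ((dam@counts + pseudocount) / dam@totalReads))
    new("RatioProfile", fmap = lmnb1@fmap, values = v,
        smoothingN = 0L, quantileNormalized = FALSE)
}

#' Quantile-normalize a set of ratio profiles
#'
#' Forces all profiles to share an identical value distribution: each rank
#' is mapped to the across-profile mean of that rank (ties share the mean of
#' the reference values they span).  Delegated to
#' \code{limma::normalizeQuantiles}.  A single profile is returned unchanged
#' with a notice.
#'
#' @param profiles list of \linkS4class{RatioProfile} objects on the same
#'   fragment map.
#' @return list of quantile-normalized profiles.
#' @export
quantileNormalizeProfiles <- function(profiles) {
    if (is(profiles, "RatioProfile")) profiles <- list(profiles)
    stopifnot(length(profiles) >= 1,
              all(vapply(profiles, is, logical(1), "RatioProfile")))
    if (length(profiles) == 1) {
        message("single profile: quantile normalization is a no-op")
        return(profiles)
    }
    fr <- profiles[[1]]@fmap@ranges
    for (p in profiles[-1])
        if (!identical(p@fmap@ranges, fr))
            stop("profiles are on different fragment maps")
    m <- vapply(profiles, profileValues, numeric(length(fr)))
    qn <- limma::normalizeQuantiles(m, ties = TRUE)
    lapply(seq_along(profiles), function(k) {
        p <- profiles[[k]]
        p@values <- qn[, k]
        p@quantileNormalized <- TRUE
        p
    })
}

.runningMean <- function(x, half) {
    # centered window [i - half, i + half] truncated at the vector ends
    n <- length(x)
    if (n == 0 || half == 0) return(x)
    cs <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - half, 1L)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a ratio profile over a fragment window
#'
#' Substitutes each fragment's value by the average of the n fragments
#' surrounding it, implemented as a centered window of n/2 fragments each
#' side plus the fragment itself (so n = 20 averages 21 values).  Windows
#' are truncated at chromosome boundaries and never cross them; n = 0 is
#' the identity.  Odd n is rounded down to even with a warning.
#'
#' @param profile a \linkS4class{RatioProfile}.
#' @param n smoothing window in fragments (even, >= 0; default 20).
#' @return a smoothed \linkS4class{RatioProfile} with \code{smoothingN = n}.
#' @export
smoothProfile <- function(profile, n = 20) {
    stopifnot(is(profile, "RatioProfile"))
    if (n < 0) stop("smoothing window must be non-negative")
    n <- as.integer(n)
    if (n %% 2L == 1L) {
        warning("odd smoothing window ", n, " rounded down to ", n - 1L)
        n <- n - 1L
    }
    if (n == 0L) {
        profile@smoothingN <- 0L
        return(profile)
    }
    chrom <- as.character(GenomicRanges::seqnames(profile@fmap@ranges))
    v <- profile@values
    out <- unlist(lapply(split(v, factor(chrom, unique(chrom))),
                         .runningMean, half = n %/% 2L),
                  use.names = FALSE)
    profile@values <- out
    profile@smoothingN <- n
    profile
}
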