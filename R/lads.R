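#' @include AllClasses.R AllGenerics.R
NULL

.asGRanges <- function(x) {
    if (is(x, "LADSet")) x@lads
    else if (is(x, "SegmentSet")) x@segments
    else if (is(x, "SimTruth")) x@lads
    else x
}

#' Subtract assembly gaps from intervals
#'
#' Base-pair set difference: segmentation does not know about assembly gaps
#' (unknown reference sequence), so segments spanning them must be cut back,
#' otherwise artifactual LADs spanning regions with no information are
#' produced.  Intervals fully covered by gaps vanish.
#'
#' @param intervals \code{GRanges} (or \linkS4class{LADSet}).
#' @param gaps \code{GRanges} of assembly gaps (e.g. the UCSC gap table read
#'   with \code{\link{readBed}}).
#' @return \code{GRanges}, sorted.
#' @export
subtractGaps <- function(intervals, gaps) {
    intervals <- .asGRanges(intervals)
    if (length(gaps) == 0) return(BiocGenerics::sort(intervals))
    # gap tables routinely cover contigs absent from the intervals; the
    # seqlevel-merge warning setdiff raises in that case is expected
    suppressWarnings(
        GenomicRanges::setdiff(intervals, gaps, ignore.strand = TRUE))
}

#' Keep segments with mean signal above a threshold
#'
#' Strict inequality: a segment whose mean equals the threshold is dropped.
#' Zero is the common threshold; values up to 0.1 (or higher) can help on
#' noisy data.
#'
#' @param segments a \linkS4class{SegmentSet}, or a \code{GRanges} with a
#'   \code{mean_value} (or \code{score}) column.
#' @param tau log2-ratio threshold (default 0).
#' @return \code{GRanges} of the retained segments.
#' @export
thresholdSegments <- function(segments, tau = 0) {
    gr <- .asGRanges(segments)
    mv <- if (!is.null(gr$mean_value)) gr$mean_value else gr$score
    if (is.null(mv)) stop("segments carry no mean_value/score column")
    gr[mv > tau]
}

#' Merge nearby intervals
#'
#' Overlapping intervals, and same-chromosome intervals separated by at most
#' \code{maxGap} bp, are unioned.  Merge distances of 5--8 kb work well
#' without fusing distinct LADs.
#'
#' @param intervals \code{GRanges}.
#' @param maxGap maximum gap in bp to bridge (default 5000).
#' @return merged \code{GRanges}, sorted.
#' @export
mergeIntervals <- function(intervals, maxGap = 5000) {
    GenomicRanges::reduce(BiocGenerics::sort(.asGRanges(intervals)),
                          min.gapwidth = maxGap + 1L, ignore.strand = TRUE)
}

#' Drop intervals below a minimum size
#'
#' Inclusive rule: an interval of exactly \code{minSize} bp is kept.  Small
#' putative LADs have low confidence without replicates; cutting anything
#' below 5--30 kb (depending on noise) is the usual practice.
#'
#' @param intervals \code{GRanges}.
#' @param minSize minimum length in bp (default 10000).
#' @return filtered \code{GRanges}.
#' @export
filterMinSize <- function(intervals, minSize = 10000) {
    gr <- .asGRanges(intervals)
    gr[BiocGenerics::width(gr) >= minSize]
}

#' Call LADs from a segmentation
#'
#' The four post-processing steps, in order: remove assembly gaps, apply the
#' signal threshold, merge nearby regions, and remove small regions.  The
#' parameters used are recorded in the result's provenance.
#'
#' @param segments a \linkS4class{SegmentSet}.
#' @param gaps \code{GRanges} of assembly gaps (empty by default).
#' @param tau log2-ratio threshold (default 0, strict).
#' @param maxGap merge distance in bp (default 5000).
#' @param minSize minimum LAD size in bp (default 10000, inclusive).
#' @return a \linkS4class{LADSet}.
#' @export
callLADs <- function(segments, gaps = GRanges(), tau = 0, maxGap = 5000,
                     minSize = 10000) {
    kept <- thresholdSegments(subtractGapsKeepMeans(segments, gaps), tau)
    merged <- mergeIntervals(kept, maxGap)
    lads <- filterMinSize(merged, minSize)
    lads <- BiocGenerics::sort(lads)
    S4Vectors::mcols(lads) <- NULL
    new("LADSet", lads = lads,
        provenance = list(tau = tau, maxGap = maxGap, minSize = minSize,
                          nGaps = length(gaps)))
}

# gap subtraction that preserves each segment's mean_value on its surviving
# pieces (plain setdiff unions adjacent segments and collapses metadata, so
# union-level pieces are clipped back to the segment they came from)
subtractGapsKeepMeans <- function(segments, gaps) {
    gr <- .asGRanges(segments)
    if (length(gaps) == 0 || length(gr) == 0) return(gr)
    pieces <- GenomicRanges::setdiff(gr, gaps, ignore.strand = TRUE)
    hits <- GenomicRanges::findOverlaps(pieces, gr, ignore.strand = TRUE)
    out <- GenomicRanges::pintersect(
        pieces[S4Vectors::queryHits(hits)],
        gr[S4Vectors::subjectHits(hits)], ignore.strand = TRUE)
    out$hit <- NULL
    mv <- if (!is.null(gr$mean_value)) gr$mean_value else gr$score
    out$mean_value <- mv[S4Vectors::subjectHits(hits)]
    BiocGenerics::sort(out)
}

#' Compare two LAD sets
#'
#' Binary presence/absence comparison at base-pair resolution: Jaccard index
#' of the covered bases, exclusive coverage of each set, and for every
#' boundary of \code{a} the distance to the nearest boundary of \code{b}.
#'
#' @param a,b \linkS4class{LADSet}, \linkS4class{SimTruth} or \code{GRanges}.
#' @return list with \code{jaccard}, \code{aOnlyBp}, \code{bOnlyBp} and
#'   \code{boundaryOffsets} (bp; empty if either set is empty).
#' @export
compareLADs <- function(a, b) {
    ga <- GenomicRanges::reduce(BiocGenerics::sort(.asGRanges(a)))
    gb <- GenomicRanges::reduce(BiocGenerics::sort(.asGRanges(b)))
    wInt <- sum(as.numeric(BiocGenerics::width(
        GenomicRanges::intersect(ga, gb, ignore.strand = TRUE))))
    wa <- sum(as.numeric(BiocGenerics::width(ga)))
    wb <- sum(as.numeric(BiocGenerics::width(gb)))
    wUnion <- wa + wb - wInt
    jac <- if (wUnion == 0) 1 else wInt / wUnion
    offs <- numeric(0)
    if (length(ga) && length(gb)) {
        bnd <- function(g) {
            split(c(BiocGenerics::start(g) - 1, BiocGenerics::end(g)),
                  rep(as.character(GenomicRanges::seqnames(g)), 2))
        }
        ba <- bnd(ga); bb <- bnd(gb)
        offs <- unlist(lapply(names(ba), function(ch) {
            if (is.null(bb[[ch]])) return(rep(Inf, length(ba[[ch]])))
            vapply(ba[[ch]], function(p) min(abs(bb[[ch]] - p)), numeric(1))
        }), use.names = FALSE)
    }
    list(jaccard = jac, aOnlyBp = wa - wInt, bOnlyBp = wb - wInt,
         boundaryOffsets = offs)
}
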