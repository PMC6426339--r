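#' @include AllClasses.R
NULL

#' Extract the fragment intervals of an object
#'
#' @param x an object carrying a \linkS4class{FragmentMap}.
#' @return a \code{GRanges} of fragments with a \code{fragment_id} column.
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' Fragmentation mode of a FragmentMap
#' @param x a \linkS4class{FragmentMap}.
#' @return \code{"dpnI"} or \code{"fixed_bin"}.
#' @export
setGeneric("fragmentMode", function(x) standardGeneric("fragmentMode"))

#' Per-fragment raw read counts
#' @param x a \linkS4class{CountTrack}.
#' @return integer vector of counts.
#' @export
setGeneric("readCounts", function(x) standardGeneric("readCounts"))

#' Total filtered reads of a sample
#' @param x a \linkS4class{CountTrack}.
#' @return numeric scalar.
#' @export
setGeneric("totalReads", function(x) standardGeneric("totalReads"))

#' Per-fragment signal values of a profile
#' @param x a \linkS4class{RatioProfile}.
#' @return numeric vector of log2 ratios.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Segment intervals of a SegmentSet
#' @param x a \linkS4class{SegmentSet}.
#' @return \code{GRanges} with \code{mean_value} and fragment bookkeeping.
#' @export
setGeneric("segmentRanges", function(x) standardGeneric("segmentRanges"))

#' Called LAD intervals
#' @param x a \linkS4class{LADSet} or \linkS4class{SimTruth}.
#' @return \code{GRanges} of LADs.
#' @export
setGeneric("ladRanges", function(x) standardGeneric("ladRanges"))

#' @rdname fragments
#' @export
setMethod("fragments", "FragmentMap", function(x) x@ranges)

#' @rdname fragments
#' @export
setMethod("fragments", "CountTrack", function(x) x@fmap@ranges)

#' @rdname fragments
#' @export
setMethod("fragments", "RatioProfile", function(x) x@fmap@ranges)

#' @rdname fragmentMode
#' @export
setMethod("fragmentMode", "FragmentMap", function(x) x@mode)

#' @rdname readCounts
#' @export
setMethod("readCounts", "CountTrack", function(x) x@counts)

#' @rdname totalReads
#' @export
setMethod("totalReads", "CountTrack", function(x) x@totalReads)

#' @rdname profileValues
#' @export
setMethod("profileValues", "RatioProfile", function(x) x@values)

#' @rdname segmentRanges
#' @export
setMethod("segmentRanges", "SegmentSet", function(x) x@segments)

#' @rdname ladRanges
#' @export
setMethod("ladRanges", "LADSet", function(x) x@lads)

#' @rdname ladRanges
#' @export
setMethod("ladRanges", "SimTruth", function(x) x@lads)

#' @export
setMethod("length", "FragmentMap", function(x) length(x@ranges))

#' @export
setMethod("length", "LADSet", function(x) length(x@lads))

setMethod("show", "FragmentMap", function(object) {
    sl <- GenomeInfoDb::seqlengths(object@ranges)
    cat("FragmentMap (", object@mode,
        if (object@mode == "fixed_bin") paste0(", bin ", object@binSize, " bp"),
        "): ", length(object@ranges), " fragments on ",
        length(sl), " chromosome(s), ", sum(as.numeric(sl)), " bp\n", sep = "")
})

setMethod("show", "ContaminationReport", function(object) {
    m <- function(x) formatC(x / 1e6, format = "f", digits = 1)
    cat("ContaminationReport\n",
        "  n total:      ", object@nTotal, " (", m(object@nTotal), " M)\n",
        "  n chrs:       ", object@nMappedChrs, " (", m(object@nMappedChrs), " M)\n",
        "  n chrM:       ", object@nChrM, " (", m(object@nChrM), " M)\n",
        "  % chrM:       ", pctChrM(object), "\n",
        "  n post filter:", object@nFinal, " (", m(object@nFinal), " M)\n", sep = "")
    if (length(object@warnings))
        cat("  warnings:\n", paste0("    - ", object@warnings, "\n"), sep = "")
})

setMethod("show", "CountTrack", function(object) {
    cat("CountTrack '", object@label, "': ", length(object@counts),
        " fragments, ", object@totalReads, " filtered reads, ",
        object@nSkipped, " skipped\n", sep = "")
})

setMethod("show", "RatioProfile", function(object) {
    cat("RatioProfile: ", length(object@values), " fragments, smoothing n = ",
        object@smoothingN, ", quantile normalized: ",
        object@quantileNormalized, "\n", sep = "")
})

setMethod("show", "SegmentSet", function(object) {
    cat("SegmentSet: ", length(object@segments), " segments on ",
        length(unique(as.character(GenomicRanges::seqnames(object@segments)))),
        " chromosome(s)\n", sep = "")
})

setMethod("show", "LADSet", function(object) {
    cat("LADSet: ", length(object@lads), " LADs, ",
        sum(BiocGenerics::width(object@lads)), " bp total",
        " (tau=", object@provenance$tau,
        ", maxGap=", object@provenance$maxGap,
        ", minSize=", object@provenance$minSize, ")\n", sep = "")
})

setMethod("show", "SimTruth", function(object) {
    cat("SimTruth: ", length(object@lads), " LADs covering ",
        sum(BiocGenerics::width(object@lads)), " bp; ",
        length(object@contactProb), " fragments\n", sep = "")
})
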