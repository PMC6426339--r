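#' @include AllClasses.R AllGenerics.R
NULL

#' Find GATC motifs in a sequence
#'
#' Returns the 0-based start positions of every GATC motif.  Dam methylates
#' the adenine of GATC, so these motifs are the substrate of the whole DamID
#' readout; DpnI later cuts the methylated ones.  Matching is
#' case-insensitive (soft-masked genomes are treated as normal sequence) and
#' motifs containing N never match.
#'
#' @param sequence a character string, \code{DNAString}, or a
#'   \code{DNAStringSet} of length one.
#' @return integer vector of ascending 0-based motif start positions.
#' @examples
#' findGATCSites("AAGATCTTGATCAA")  # 2, 8
#' @export
findGATCSites <- function(sequence) {
    if (is(sequence, "DNAStringSet")) {
        stopifnot(length(sequence) == 1)
        sequence <- sequence[[1]]
    }
    if (is.character(sequence)) {
        if (!nzchar(sequence)) return(integer(0))
        sequence <- Biostrings::DNAString(toupper(sequence))
    }
    if (length(sequence) < 4L) return(integer(0))
    m <- Biostrings::matchPattern("GATC", sequence, fixed = TRUE)
    BiocGenerics::start(m) - 1L
}

.fragmentsFromCuts <- function(chrom, len, cuts0) {
    # cuts0: 0-based cut coordinates inside (0, len); fragments tile [0, len)
    bounds <- c(0L, cuts0, len)
    GRanges(chrom,
            IRanges::IRanges(start = bounds[-length(bounds)] + 1L,
                             end = bounds[-1L]))
}

.newFragmentMap <- function(grl, seqlens, mode, binSize = NA_integer_) {
    gr <- suppressWarnings(do.call(c, unname(grl)))
    GenomeInfoDb::seqlevels(gr) <- names(seqlens)
    GenomeInfoDb::seqlengths(gr) <- seqlens
    gr$fragment_id <- seq_along(gr)
    new("FragmentMap", ranges = gr, mode = mode,
        binSize = as.integer(binSize))
}

#' Build the genome-wide DpnI fragment map
#'
#' DpnI cleaves GA^TC bluntly, so each GATC motif at 0-based position p
#' contributes a cut at coordinate p + 2.  Fragments are the intervals
#' between consecutive cuts plus the two terminal intervals; a chromosome
#' without any GATC yields a single fragment spanning it.  These fragments
#' are the native resolution unit of DamID quantitation.
#'
#' @param genome a named \code{DNAStringSet} (one entry per chromosome).
#' @return a \linkS4class{FragmentMap} in \code{"dpnI"} mode.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AAGATCTTGATCAA"))
#' buildFragmentMap(g)  # fragments [0,4), [4,10), [10,14) in BED coordinates
#' @export
buildFragmentMap <- function(genome) {
    stopifnot(is(genome, "DNAStringSet"), !is.null(names(genome)),
              !anyDuplicated(names(genome)), all(BiocGenerics::width(genome) > 0))
    seqlens <- stats::setNames(BiocGenerics::width(genome), names(genome))
    grl <- lapply(names(genome), function(chrom) {
        len <- seqlens[[chrom]]
        cuts <- findGATCSites(genome[[chrom]]) + 2L
        cuts <- cuts[cuts > 0L & cuts < len]
        .fragmentsFromCuts(chrom, len, cuts)
    })
    .newFragmentMap(grl, seqlens, "dpnI")
}

#' Build a fixed-size bin map
#'
#' Quantifying reads in constant-size bins (2--5 kb is a reasonable starting
#' point) is the alternative to native DpnI fragments; it is less influenced
#' by the mix of high- and low-count fragments.
#'
#' @param genome a named \code{DNAStringSet}, or a named numeric vector of
#'   chromosome lengths.
#' @param binSize bin width in bp (> 0); the final bin of each chromosome is
#'   truncated at the chromosome end.
#' @return a \linkS4class{FragmentMap} in \code{"fixed_bin"} mode.
#' @export
buildBinMap <- function(genome, binSize) {
    if (!is.numeric(binSize) || length(binSize) != 1 || binSize <= 0)
        stop("binSize must be a single positive number")
    binSize <- as.integer(binSize)
    seqlens <- if (is(genome, "DNAStringSet")) {
        stats::setNames(BiocGenerics::width(genome), names(genome))
    } else {
        stopifnot(is.numeric(genome), !is.null(names(genome)))
        stats::setNames(as.integer(genome), names(genome))
    }
    grl <- lapply(names(seqlens), function(chrom) {
        len <- seqlens[[chrom]]
        starts <- seq.int(1L, len, by = binSize)
        GRanges(chrom, IRanges::IRanges(start = starts,
                                        end = pmin(starts + binSize - 1L, len)))
    })
    .newFragmentMap(grl, seqlens, "fixed_bin", binSize)
}

#' Restrict a FragmentMap to a set of chromosomes
#'
#' Used by the pipeline to drop excluded contigs (e.g. \code{chrM}) from the
#' analysis coordinate system: fragments on chromosomes with no retained
#' reads would otherwise produce constant pseudocount-only profile stretches
#' that segment into artifactual calls.
#'
#' @param fmap a \linkS4class{FragmentMap}.
#' @param chroms chromosomes to keep (or drop).
#' @param invert if \code{TRUE}, \code{chroms} are dropped instead of kept.
#' @return a \linkS4class{FragmentMap} (fragment ids are preserved, so they
#'   remain globally unique but need not start at 1).
#' @export
subsetFragmentMap <- function(fmap, chroms, invert = FALSE) {
    stopifnot(is(fmap, "FragmentMap"))
    keep <- if (invert) setdiff(GenomeInfoDb::seqlevels(fmap@ranges), chroms)
            else chroms
    gr <- fmap@ranges[as.character(GenomicRanges::seqnames(fmap@ranges))
                      %in% keep]
    gr <- GenomeInfoDb::keepSeqlevels(gr, keep, pruning.mode = "coarse")
    new("FragmentMap", ranges = gr, mode = fmap@mode, binSize = fmap@binSize)
}

#' Fragment-size statistics of a FragmentMap
#'
#' Summarizes the genome-wide fragment length distribution.  For the mouse
#' genome the DpnI map has a median of roughly 260 bp with the 95th
#' percentile near 1238 bp and 99.9\% of fragments under 3 kb; for an
#' i.i.d.-uniform synthetic genome the inter-motif model (geometric with
#' p = 1/256) puts the median near 177 bp.
#'
#' @param fmap a non-empty \linkS4class{FragmentMap}.
#' @param sizeThreshold report the fraction of fragments shorter than this
#'   many bp (default 3000).
#' @return list with \code{median}, \code{p95}, \code{fractionUnderThreshold}
#'   and \code{nFragments}.
#' @export
fragmentSizeStats <- function(fmap, sizeThreshold = 3000) {
    stopifnot(is(fmap, "FragmentMap"))
    w <- BiocGenerics::width(fmap@ranges)
    if (!length(w)) stop("empty FragmentMap")
    list(median = stats::median(w),
         p95 = unname(stats::quantile(w, 0.95, type = 1)),
         fractionUnderThreshold = mean(w < sizeThreshold),
         nFragments = length(w))
}
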