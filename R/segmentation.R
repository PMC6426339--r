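#' @include AllClasses.R AllGenerics.R
#' @useDynLib LADid, .registration=TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Construct CBS parameters
#'
#' @param alpha permutation significance level for accepting a split
#'   (default 0.01).
#' @param nPerm permutation count (default 1000).
#' @param minWidth minimum segment width in fragments (default 2).
#' @param seed RNG seed (default 1); identical inputs and seed give identical
#'   segmentations.
#' @param permCap segments longer than this many fragments are thinned to
#'   \code{permCap} evenly spaced values for the permutation test only
#'   (default 1000); the boundary search always runs at full resolution.
#' @return a \linkS4class{CBSParams}.
#' @export
cbsParams <- function(alpha = 0.01, nPerm = 1000, minWidth = 2, seed = 1,
                      permCap = 1000) {
    new("CBSParams", alpha = alpha, nPerm = as.integer(nPerm),
        minWidth = as.integer(minWidth), seed = as.integer(seed),
        permCap = as.integer(permCap))
}

#' Maximal circular-arc t statistic
#'
#' Scans every arc (i, j] of the vector (arcs may wrap; a wrapping arc is the
#' complement of a plain one and has the same statistic) and returns the arc
#' maximizing the absolute pooled-variance two-sample t statistic comparing
#' the mean inside the arc against the mean outside.  Ties are broken by
#' smallest i, then smallest j.  A constant vector has statistic 0 and no
#' arc.
#'
#' @param values numeric vector (length >= 4 for a meaningful statistic).
#' @param minWidth minimum number of elements inside and outside the arc
#'   (default 1).
#' @return list with 0-based boundaries \code{i}, \code{j} (the arc is
#'   elements \code{i+1 .. j} in 1-based indexing, \code{NA} if no arc) and
#'   \code{stat}, the maximal |T|.
#' @export
maxArcStatistic <- function(values, minWidth = 1) {
    stopifnot(is.numeric(values))
    if (length(values) < 2 || stats::var(values) == 0)
        return(list(i = NA_integer_, j = NA_integer_, stat = 0))
    r <- cpp_max_arc(as.numeric(values), as.integer(minWidth))
    if (r$i < 0) return(list(i = NA_integer_, j = NA_integer_, stat = 0))
    list(i = as.integer(r$i), j = as.integer(r$j), stat = r$stat)
}

# significance of the best split of v, assessed by permutation on a vector
# thinned to at most permCap evenly spaced values (statistics are compared at
# the thinned resolution so observed and permuted values are commensurable)
.splitSignificant <- function(v, params) {
    if (length(v) > params@permCap) {
        idx <- unique(round(seq(1, length(v), length.out = params@permCap)))
        v <- v[idx]
    }
    if (stats::var(v) == 0) return(FALSE)
    obs <- cpp_max_arc(v, params@minWidth)
    if (obs$i < 0 || obs$stat <= 0) return(FALSE)
    res <- cpp_perm_test(v, obs$stat, params@nPerm, params@alpha,
                         params@minWidth)
    isTRUE(res$significant)
}

# recursive CBS on one chromosome's values; returns sorted 0-based cut
# positions strictly inside (0, n)
.cbsCuts <- function(v, params) {
    n <- length(v)
    if (n < max(4L, 2L * params@minWidth)) return(integer(0))
    if (stats::var(v) == 0) return(integer(0))
    arc <- cpp_max_arc(v, params@minWidth)
    if (arc$i < 0 || arc$stat <= 0) return(integer(0))
    if (!.splitSignificant(v, params)) return(integer(0))
    cuts <- setdiff(c(arc$i, arc$j), c(0L, n))
    bounds <- c(0L, sort(cuts), n)
    out <- cuts
    for (k in seq_len(length(bounds) - 1L)) {
        lo <- bounds[k]; hi <- bounds[k + 1L]
        sub <- .cbsCuts(v[(lo + 1L):hi], params)
        out <- c(out, lo + sub)
    }
    sort(unique(out))
}

#' Segment a ratio profile by circular binary segmentation
#'
#' Per chromosome, recursively finds the arc with the maximal two-sample t
#' statistic, accepts the split when a permutation test on the segment's
#' values gives p < alpha, and recurses into the resulting pieces until no
#' significant split remains or a piece is shorter than twice the minimum
#' width.  Deterministic given \code{params@seed}.
#'
#' @param profile a \linkS4class{RatioProfile} (raw or smoothed; segmentation
#'   runs on whatever smoothing level the profile carries).
#' @param params a \linkS4class{CBSParams}.
#' @return a \linkS4class{SegmentSet} whose segments tile the fragments of
#'   each chromosome exactly.
#' @export
cbsSegment <- function(profile, params = cbsParams()) {
    stopifnot(is(profile, "RatioProfile"), is(params, "CBSParams"))
    set.seed(params@seed)
    fr <- profile@fmap@ranges
    chrom <- as.character(GenomicRanges::seqnames(fr))
    uchr <- unique(chrom)
    segs <- lapply(uchr, function(ch) {
        sel <- which(chrom == ch)
        v <- profile@values[sel]
        n <- length(v)
        cuts <- if (n >= 2 && stats::var(v) > 0) .cbsCuts(v, params)
                else integer(0)
        bounds <- c(0L, cuts, n)
        first <- sel[bounds[-length(bounds)] + 1L]
        last <- sel[bounds[-1L]]
        gr <- GRanges(ch, IRanges::IRanges(
            start = BiocGenerics::start(fr)[first],
            end = BiocGenerics::end(fr)[last]))
        gr$mean_value <- vapply(seq_along(first), function(k)
            mean(v[(bounds[k] + 1L):bounds[k + 1L]]), numeric(1))
        gr$n_fragments <- bounds[-1L] - bounds[-length(bounds)]
        gr$first_fragment <- fr$fragment_id[first]
        gr$last_fragment <- fr$fragment_id[last]
        gr
    })
    out <- suppressWarnings(do.call(c, unname(segs)))
    GenomeInfoDb::seqlevels(out) <- GenomeInfoDb::seqlevels(fr)
    GenomeInfoDb::seqlengths(out) <- GenomeInfoDb::seqlengths(fr)
    new("SegmentSet", segments = out, params = params)
}
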