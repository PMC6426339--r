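#' @import methods
#' @importFrom GenomicRanges GRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' FragmentMap: the genomic coordinate system of a DamID experiment
#'
#' An ordered, disjoint set of intervals partitioning each chromosome, either
#' the DpnI fragments between consecutive GATC cut sites or fixed-size bins.
#' Intervals are stored 1-based closed (\code{GRanges} convention); all BED
#' input/output is 0-based half-open.
#'
#' @slot ranges \code{GRanges} with metadata column \code{fragment_id}
#'   (globally unique, strictly increasing in genome order) and seqlengths set.
#' @slot mode \code{"dpnI"} or \code{"fixed_bin"}.
#' @slot binSize bin width in bp (only meaningful for \code{"fixed_bin"}).
#' @export
setClass("FragmentMap",
    slots = c(ranges = "GRanges", mode = "character", binSize = "integer"))

setValidity("FragmentMap", function(object) {
    gr <- object@ranges
    if (!object@mode %in% c("dpnI", "fixed_bin"))
        return("mode must be 'dpnI' or 'fixed_bin'")
    if (is.null(gr$fragment_id))
        return("ranges must carry a fragment_id metadata column")
    if (length(gr) && any(diff(gr$fragment_id) <= 0))
        return("fragment_id must be strictly increasing")
    sl <- GenomeInfoDb::seqlengths(gr)
    if (any(is.na(sl)))
        return("seqlengths must be set for all chromosomes")
    covered <- vapply(split(BiocGenerics::width(gr),
                            as.character(GenomicRanges::seqnames(gr))),
                      sum, numeric(1))
    if (!isTRUE(all(covered[names(sl)[sl > 0]] == sl[sl > 0])))
        return("fragments must cover each chromosome exactly")
    if (length(gr) > 1) {
        bychr <- split(gr, GenomicRanges::seqnames(gr))
        ok <- all(vapply(bychr, function(g) {
            length(g) < 2 ||
                all(BiocGenerics::start(g)[-1] == BiocGenerics::end(g)[-length(g)] + 1L)
        }, logical(1)))
        if (!ok) return("fragments must be sorted, disjoint and contiguous")
    }
    TRUE
})

#' ContaminationReport: per-sample read accounting
#'
#' Mirrors the read-accounting table of a DamID-seq experiment: total reads,
#' reads mapping (unambiguously) to reference chromosomes, mitochondrial
#' reads, and reads surviving all filters.
#'
#' @slot nTotal total primary records seen.
#' @slot nMappedChrs mapped, primary, mapping-quality-passing records.
#' @slot nChrM subset of \code{nMappedChrs} on mitochondrial contigs.
#' @slot nFinal \code{nMappedChrs - nChrM} (and minus other excluded contigs).
#' @slot nUnmapped unmapped records.
#' @slot nLowMapq mapped records failing the mapping-quality cutoff.
#' @slot warnings character vector of QC messages.
#' @export
setClass("ContaminationReport",
    slots = c(nTotal = "numeric", nMappedChrs = "numeric", nChrM = "numeric",
              nFinal = "numeric", nUnmapped = "numeric", nLowMapq = "numeric",
              warnings = "character"))

setValidity("ContaminationReport", function(object) {
    if (object@nMappedChrs > object@nTotal)
        return("nMappedChrs cannot exceed nTotal")
    if (object@nFinal > object@nMappedChrs)
        return("nFinal cannot exceed nMappedChrs")
    if (object@nChrM > object@nMappedChrs)
        return("nChrM cannot exceed nMappedChrs")
    TRUE
})

#' CountTrack: raw per-fragment read counts for one sample
#'
#' @slot fmap the \linkS4class{FragmentMap} the counts live on.
#' @slot counts integer vector, one count per fragment.
#' @slot label sample label (e.g. \code{"LaminB1-Dam"}).
#' @slot totalReads total filtered reads in the sample (the denominator of
#'   the normalized counts; not \code{sum(counts)}, since in overlap mode a
#'   read can increment several fragments).
#' @slot nSkipped reads on chromosomes absent from the fragment map.
#' @export
setClass("CountTrack",
    slots = c(fmap = "FragmentMap", counts = "integer", label = "character",
              totalReads = "numeric", nSkipped = "numeric"))

setValidity("CountTrack", function(object) {
    if (length(object@counts) != length(object@fmap@ranges))
        return("counts length must equal the number of fragments")
    if (any(object@counts < 0)) return("counts must be non-negative")
    TRUE
})

#' RatioProfile: per-fragment log2(LaminB1-Dam / Dam-only) signal
#'
#' @slot fmap the \linkS4class{FragmentMap} the values live on.
#' @slot values finite numeric vector of log2 ratios.
#' @slot smoothingN smoothing window in fragments (0 = raw).
#' @slot quantileNormalized whether quantile normalization has been applied.
#' @export
setClass("RatioProfile",
    slots = c(fmap = "FragmentMap", values = "numeric",
              smoothingN = "integer", quantileNormalized = "logical"))

setValidity("RatioProfile", function(object) {
    if (length(object@values) != length(object@fmap@ranges))
        return("values length must equal the number of fragments")
    if (any(!is.finite(object@values)))
        return("values must be finite everywhere")
    TRUE
})

#' CBSParams: tuning parameters for circular binary segmentation
#'
#' @slot alpha permutation significance level for accepting a split.
#' @slot nPerm number of permutations.
#' @slot minWidth minimum segment width in fragments.
#' @slot seed RNG seed making the segmentation deterministic.
#' @slot permCap segments longer than this are thinned to \code{permCap}
#'   evenly spaced values for the permutation test only (boundary search is
#'   always at full resolution).
#' @export
setClass("CBSParams",
    slots = c(alpha = "numeric", nPerm = "integer", minWidth = "integer",
              seed = "integer", permCap = "integer"))

setValidity("CBSParams", function(object) {
    if (object@alpha <= 0 || object@alpha >= 1)
        return("alpha must be in (0, 1)")
    if (object@nPerm < 100L) return("nPerm must be >= 100")
    if (object@minWidth < 2L) return("minWidth must be >= 2")
    if (object@permCap < 100L) return("permCap must be >= 100")
    TRUE
})

#' SegmentSet: circular-binary-segmentation output
#'
#' Per-chromosome runs of quasi-uniform signal.  Segments tile the fragments
#' of each chromosome exactly.
#'
#' @slot segments \code{GRanges} with metadata columns \code{mean_value},
#'   \code{n_fragments}, \code{first_fragment}, \code{last_fragment}
#'   (global fragment ids).
#' @slot params the \linkS4class{CBSParams} used.
#' @export
setClass("SegmentSet",
    slots = c(segments = "GRanges", params = "CBSParams"))

#' LADSet: final called lamina-associated domains
#'
#' @slot lads sorted, non-overlapping \code{GRanges}.
#' @slot provenance named list of the post-processing parameters used
#'   (\code{tau}, \code{maxGap}, \code{minSize}).
#' @export
setClass("LADSet",
    slots = c(lads = "GRanges", provenance = "list"))

setValidity("LADSet", function(object) {
    if (length(object@lads) > 1 &&
        !S4Vectors::isSorted(object@lads))
        return("LADs must be sorted")
    if (length(GenomicRanges::reduce(object@lads, min.gapwidth = 0L)) !=
        length(object@lads))
        return("LADs must be non-overlapping")
    TRUE
})

#' SimParams: study conditions for the DamID experiment simulator
#'
#' Defaults are the simulated study conditions used throughout the package's
#' validation: a 40 Mb genome, LADs covering 40\% of it with log-uniform
#' lengths between 30 kb and 2 Mb, a mean in-LAD log2 enrichment of 2, 2
#' million reads per sample and 15\% mitochondrial contamination (inside the
#' 7--26\% range observed in primary hepatocytes).
#'
#' @slot genomeLength total nuclear genome length in bp.
#' @slot nChromosomes number of nuclear chromosomes.
#' @slot chrMLength length of the mitochondrial contig in bp.
#' @slot ladCoverage target fraction of the nuclear genome inside LADs.
#' @slot ladLengthRange log-uniform LAD length range in bp.
#' @slot enrichment target mean in-LAD log2(LaminB1-Dam/Dam-only) ratio.
#' @slot contactIn per-fragment lamina-contact probability inside LADs
#'   (\code{NA} = derived from \code{enrichment}).
#' @slot contactOut contact probability outside LADs.
#' @slot damAccessibility methylation probability per GATC site for the
#'   soluble Dam-only control.
#' @slot accessibilityDip if \code{TRUE}, Dam-only accessibility drops to 0.3
#'   inside LADs (peripheral chromatin is less accessible to free Dam).
#' @slot readsPerSample reads per sample (each of LaminB1-Dam and Dam-only).
#' @slot chrMFraction fraction of reads drawn from the mitochondrial contig.
#' @slot readLength read length in bp.
#' @slot seed master RNG seed; every stage derives its stream from it.
#' @export
setClass("SimParams",
    slots = c(genomeLength = "numeric", nChromosomes = "integer",
              chrMLength = "integer", ladCoverage = "numeric",
              ladLengthRange = "numeric", enrichment = "numeric",
              contactIn = "numeric", contactOut = "numeric",
              damAccessibility = "numeric", accessibilityDip = "logical",
              readsPerSample = "numeric", chrMFraction = "numeric",
              readLength = "integer", seed = "integer"))

setValidity("SimParams", function(object) {
    if (object@genomeLength <= 0) return("genomeLength must be positive")
    if (object@ladCoverage < 0 || object@ladCoverage > 0.6)
        return("ladCoverage must be in [0, 0.6]")
    if (object@chrMFraction < 0 || object@chrMFraction >= 1)
        return("chrMFraction must be in [0, 1)")
    if (!is.na(object@enrichment) && object@enrichment <= 0)
        return("enrichment must be positive")
    if (length(object@ladLengthRange) != 2 ||
        object@ladLengthRange[1] > object@ladLengthRange[2])
        return("ladLengthRange must be c(min, max)")
    TRUE
})

#' SimTruth: ground truth of a simulated DamID experiment
#'
#' @slot lads true LAD intervals (\code{GRanges}).
#' @slot contactProb per-fragment lamina-contact probability in [0, 1].
#' @slot fmap the \linkS4class{FragmentMap} of the simulated genome.
#' @export
setClass("SimTruth",
    slots = c(lads = "GRanges", contactProb = "numeric", fmap = "FragmentMap"))

setValidity("SimTruth", function(object) {
    if (any(object@contactProb < 0 | object@contactProb > 1))
        return("contactProb must be in [0, 1]")
    if (length(GenomicRanges::reduce(object@lads, min.gapwidth = 0L)) !=
        length(object@lads))
        return("truth LADs must be disjoint")
    TRUE
})
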