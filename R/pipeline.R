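#' @include AllClasses.R AllGenerics.R digest.R qc.R profile.R segmentation.R lads.R io.R
NULL

#' Default pipeline configuration
#'
#' All stage parameters with their defaults.  Override entries by passing
#' named values; unknown names raise an error.
#'
#' @param ... named overrides (e.g. \code{smoothN = 10}, \code{tau = 0.1}).
#' @return named list of parameters.
#' @export
pipelineConfig <- function(...) {
    cfg <- list(mapqMin = 10, excludeChroms = c("chrM", "MT", "chrMT"),
                minCleanReads = 30e6, countMode = "overlap", pseudocount = 1,
                quantileNormalize = TRUE, smoothN = 20,
                smoothBeforeNormalize = FALSE, alpha = 0.01, nPerm = 1000,
                minWidth = 2, tau = 0, maxGap = 5000, minSize = 10000,
                seed = 1)
    dots <- list(...)
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown))
        stop("unknown config parameter(s): ", paste(unknown, collapse = ", "))
    cfg[names(dots)] <- dots
    cfg
}

#' Run the DamID pipeline: alignments to LAD calls
#'
#' Executes the full analysis on one experiment (one LaminB1-Dam and one
#' Dam-only sample): filter alignments, count reads per fragment, form the
#' log2 ratio, optionally quantile-normalize (across the profiles supplied
#' via \code{extraProfiles}, if any; a lone profile is left unchanged),
#' smooth, segment by CBS, and call LADs.  By default smoothing follows
#' normalization; set \code{smoothBeforeNormalize = TRUE} in the config for
#' the alternative order.
#'
#' @param fmap a \linkS4class{FragmentMap}.
#' @param lmnb1,dam alignments (\code{GRanges} from
#'   \code{\link{readAlignments}} or \code{\link{simulateReads}}).
#' @param gaps assembly gaps (\code{GRanges}; empty by default).
#' @param config list from \code{\link{pipelineConfig}}.
#' @param extraProfiles optional list of additional
#'   \linkS4class{RatioProfile}s (e.g. a second condition) to include in
#'   quantile normalization; they are normalized alongside but only this
#'   experiment's profile continues through segmentation.
#' @return list with \code{reports} (per-sample
#'   \linkS4class{ContaminationReport} + depth warnings), \code{tracks},
#'   \code{profile} (final \linkS4class{RatioProfile}), \code{segments}
#'   (\linkS4class{SegmentSet}), \code{lads} (\linkS4class{LADSet}) and
#'   \code{provenance} (config echo, JSON-ready).
#' @export
runPipeline <- function(fmap, lmnb1, dam, gaps = GRanges(),
                        config = pipelineConfig(), extraProfiles = list()) {
    stopifnot(is(fmap, "FragmentMap"))
    drop <- intersect(config$excludeChroms,
                      GenomeInfoDb::seqlevels(fmap@ranges))
    if (length(drop)) fmap <- subsetFragmentMap(fmap, drop, invert = TRUE)
    fL <- filterAlignments(lmnb1, config$mapqMin, config$excludeChroms)
    fD <- filterAlignments(dam, config$mapqMin, config$excludeChroms)
    warnL <- qcDepthCheck(fL$report, config$minCleanReads)
    warnD <- qcDepthCheck(fD$report, config$minCleanReads)
    if (fL$report@nFinal == 0 || fD$report@nFinal == 0)
        stop("qc stage: no reads survive filtering")

    tL <- countReads(fmap, fL$alignments, config$countMode, "LaminB1-Dam")
    tD <- countReads(fmap, fD$alignments, config$countMode, "Dam-only")
    profile <- log2Ratio(tL, tD, config$pseudocount)

    smoothFirst <- isTRUE(config$smoothBeforeNormalize)
    if (smoothFirst && config$smoothN > 0)
        profile <- smoothProfile(profile, config$smoothN)
    if (isTRUE(config$quantileNormalize) && length(extraProfiles)) {
        qn <- quantileNormalizeProfiles(c(list(profile), extraProfiles))
        profile <- qn[[1]]
    }
    if (!smoothFirst && config$smoothN > 0)
        profile <- smoothProfile(profile, config$smoothN)

    segs <- cbsSegment(profile, cbsParams(alpha = config$alpha,
                                          nPerm = config$nPerm,
                                          minWidth = config$minWidth,
                                          seed = config$seed))
    lads <- callLADs(segs, gaps = gaps, tau = config$tau,
                     maxGap = config$maxGap, minSize = config$minSize)
    if (length(lads) == 0)
        warning("no LADs called with tau = ", config$tau)

    provenance <- c(config,
                    list(n_fragments = length(fmap),
                         fragment_mode = fmap@mode,
                         reports = list(lmnb1 = reportAsList(fL$report),
                                        dam = reportAsList(fD$report)),
                         depth_warnings = list(lmnb1 = warnL, dam = warnD)))
    list(reports = list(lmnb1 = fL$report, dam = fD$report,
                        warnings = list(lmnb1 = warnL, dam = warnD)),
         tracks = list(lmnb1 = tL, dam = tD),
         profile = profile, segments = segs, lads = lads,
         provenance = provenance)
}
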