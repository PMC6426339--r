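#' @include AllClasses.R AllGenerics.R
NULL

.FLAG_UNMAPPED <- 4L
.FLAG_SECONDARY <- 256L
.FLAG_SUPPLEMENTARY <- 2048L

#' Construct a ContaminationReport from read counts
#'
#' Useful for reproducing published accounting tables: supply the total,
#' mapped and mitochondrial read numbers and the derived fields (percent
#' mitochondrial, post-filter count) are computed.
#'
#' @param nTotal total primary reads.
#' @param nMappedChrs reads mapping unambiguously to reference chromosomes
#'   (including the mitochondrial contig).
#' @param nChrM mitochondrial reads among \code{nMappedChrs}.
#' @param nUnmapped,nLowMapq optional breakdown of the non-counted reads.
#' @param warnings optional QC messages.
#' @return a \linkS4class{ContaminationReport}.
#' @export
contaminationReport <- function(nTotal, nMappedChrs, nChrM,
                                nUnmapped = NA_real_, nLowMapq = NA_real_,
                                warnings = character(0)) {
    new("ContaminationReport", nTotal = as.numeric(nTotal),
        nMappedChrs = as.numeric(nMappedChrs), nChrM = as.numeric(nChrM),
        nFinal = as.numeric(nMappedChrs) - as.numeric(nChrM),
        nUnmapped = as.numeric(nUnmapped), nLowMapq = as.numeric(nLowMapq),
        warnings = warnings)
}

#' Percent of mapped reads that are mitochondrial
#'
#' @param report a \linkS4class{ContaminationReport}.
#' @param digits rounding for display (default one decimal, matching the
#'   conventional table formatting).
#' @return numeric scalar, 0--100.
#' @export
pctChrM <- function(report, digits = 1) {
    if (report@nMappedChrs == 0) return(0)
    round(100 * report@nChrM / report@nMappedChrs, digits)
}

#' Filter alignments and account for contamination
#'
#' Removes unmapped, secondary and supplementary records, records below the
#' mapping-quality cutoff ("ambiguous locations"), and records on excluded
#' contigs (by default the mitochondrial genome, a major nuisance fraction
#' in primary-cell DamID).  Returns the surviving alignments together with
#' the read accounting.
#'
#' @param aln \code{GRanges} from \code{\link{readAlignments}} (metadata
#'   columns \code{mapq}, \code{flag}).
#' @param mapqMin minimum mapping quality (default 10).
#' @param excludeChroms contigs to drop; default recognizes the common
#'   mitochondrial names \code{chrM}, \code{MT}, \code{chrMT}.
#' @param knownChroms optional character vector of reference chromosomes;
#'   reads elsewhere are dropped (and counted as unmapped-to-reference).
#' @return list with elements \code{alignments} (filtered \code{GRanges})
#'   and \code{report} (\linkS4class{ContaminationReport}).
#' @export
filterAlignments <- function(aln, mapqMin = 10,
                             excludeChroms = c("chrM", "MT", "chrMT"),
                             knownChroms = NULL) {
    if (length(aln) == 0) {
        rep0 <- contaminationReport(0, 0, 0, 0, 0,
                                    warnings = "empty alignment input")
        return(list(alignments = aln, report = rep0))
    }
    flag <- if (is.null(aln$flag)) integer(length(aln)) else aln$flag
    mapq <- if (is.null(aln$mapq)) rep(255L, length(aln)) else aln$mapq
    primary <- bitwAnd(flag, .FLAG_SECONDARY) == 0L &
               bitwAnd(flag, .FLAG_SUPPLEMENTARY) == 0L
    aln <- aln[primary]; flag <- flag[primary]; mapq <- mapq[primary]

    chrom <- as.character(GenomicRanges::seqnames(aln))
    mapped <- bitwAnd(flag, .FLAG_UNMAPPED) == 0L & chrom != "*"
    if (!is.null(knownChroms))
        mapped <- mapped & chrom %in% c(knownChroms, excludeChroms)
    passMapq <- mapped & mapq >= mapqMin
    isM <- passMapq & chrom %in% excludeChroms

    nTotal <- length(aln)
    nUnmapped <- sum(!mapped)
    nLowMapq <- sum(mapped & !passMapq)
    nMappedChrs <- sum(passMapq)
    nChrM <- sum(isM)

    keep <- passMapq & !isM
    warnings <- character(0)
    if (nTotal == 0) warnings <- c(warnings, "empty alignment input")
    report <- contaminationReport(nTotal, nMappedChrs, nChrM,
                                  nUnmapped, nLowMapq, warnings)
    out <- aln[keep]
    list(alignments = out, report = report)
}

#' Depth and contamination warnings for a ContaminationReport
#'
#' Emits a low-depth warning when fewer clean reads survive than recommended
#' (at least 30--40 million for a mammalian genome), an informational note
#' when mitochondrial contamination exceeds the top of the range observed in
#' primary hepatocytes (26\%), and an alert when the unmapped fraction is
#' suspiciously high (possible prokaryotic, e.g. mycoplasma, contamination
#' -- which must be ruled out by PCR upstream of sequencing).
#'
#' @param report a \linkS4class{ContaminationReport}.
#' @param minCleanReads minimum acceptable post-filter reads (default 30e6).
#' @param chrMAlertPct mitochondrial percentage above which to note
#'   (default 26).
#' @param unmappedAlertPct unmapped-fraction percentage above which to warn
#'   (default 50).
#' @return character vector of warnings; zero post-filter reads additionally
#'   carries an \code{"ERROR:"} prefix entry.
#' @export
qcDepthCheck <- function(report, minCleanReads = 30e6,
                         chrMAlertPct = 26, unmappedAlertPct = 50) {
    w <- character(0)
    if (report@nFinal < minCleanReads)
        w <- c(w, sprintf(
            "low depth: %.1f M clean reads, below the recommended %.0f M",
            report@nFinal / 1e6, minCleanReads / 1e6))
    p <- pctChrM(report)
    if (p > chrMAlertPct)
        w <- c(w, sprintf(
            "mitochondrial contamination %.1f%% exceeds alert level %.1f%%",
            p, chrMAlertPct))
    if (!is.na(report@nUnmapped) && report@nTotal > 0) {
        up <- 100 * report@nUnmapped / report@nTotal
        if (up > unmappedAlertPct)
            w <- c(w, sprintf(
                "%.1f%% of reads unmapped; check for prokaryotic (mycoplasma) contamination",
                up))
    }
    if (report@nFinal == 0)
        w <- c(w, "ERROR: no reads survive filtering")
    w
}

#' Serialize a ContaminationReport to a plain list (for JSON output)
#' @param report a \linkS4class{ContaminationReport}.
#' @return named list with raw counts, counts in millions and percentages.
#' @export
reportAsList <- function(report) {
    list(n_total = report@nTotal,
         n_mapped_chrs = report@nMappedChrs,
         n_chrM = report@nChrM,
         pct_chrM = pctChrM(report),
         n_final = report@nFinal,
         n_unmapped = report@nUnmapped,
         n_low_mapq = report@nLowMapq,
         millions = list(n_total = round(report@nTotal / 1e6, 1),
                         n_mapped_chrs = round(report@nMappedChrs / 1e6, 1),
                         n_chrM = round(report@nChrM / 1e6, 1),
                         n_final = round(report@nFinal / 1e6, 1)),
         warnings = report@warnings)
}
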