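#' @include AllClasses.R AllGenerics.R digest.R
NULL

#' Construct simulator parameters
#'
#' The defaults define the package's reference study conditions: a 40 Mb
#' nuclear genome on 8 chromosomes plus a 16 kb mitochondrial contig, LADs
#' covering 40\% of the genome with log-uniform lengths in [30 kb, 2 Mb], a
#' mean in-LAD log2(LaminB1-Dam/Dam-only) enrichment of 2, 2 million reads
#' per sample of 90 bp, and 15\% mitochondrial contamination (inside the
#' 7--26\% range seen in primary hepatocytes).
#'
#' @param genomeLength nuclear genome length in bp.
#' @param nChromosomes number of nuclear chromosomes.
#' @param chrMLength mitochondrial contig length in bp.
#' @param ladCoverage target LAD fraction of the nuclear genome (0--0.6).
#' @param ladLengthRange log-uniform LAD length range, bp.
#' @param enrichment target mean in-LAD log2 ratio; determines the in-LAD
#'   contact probability unless \code{contactIn} is given explicitly.
#' @param contactIn in-LAD per-fragment lamina-contact probability
#'   (\code{NA}: derived as \code{min(1, damAccessibility * 2^(enrichment/2))}).
#' @param contactOut contact probability outside LADs.
#' @param damAccessibility per-site methylation probability of the soluble
#'   Dam-only control.
#' @param accessibilityDip if \code{TRUE}, Dam-only accessibility is 0.3
#'   inside LADs (peripheral chromatin is less accessible to free Dam).
#' @param readsPerSample reads per sample.
#' @param chrMFraction fraction of each sample's reads from the
#'   mitochondrial contig.
#' @param readLength read length, bp.
#' @param seed master seed (keep below 2^31 - 10; stages derive their RNG
#'   streams from small offsets of it).
#' @return a \linkS4class{SimParams}.
#' @export
simParams <- function(genomeLength = 40e6, nChromosomes = 8,
                      chrMLength = 16000, ladCoverage = 0.4,
                      ladLengthRange = c(30e3, 2e6), enrichment = 2,
                      contactIn = NA_real_, contactOut = 0.1,
                      damAccessibility = 0.5, accessibilityDip = FALSE,
                      readsPerSample = 2e6, chrMFraction = 0.15,
                      readLength = 90, seed = 1) {
    new("SimParams", genomeLength = genomeLength,
        nChromosomes = as.integer(nChromosomes),
        chrMLength = as.integer(chrMLength), ladCoverage = ladCoverage,
        ladLengthRange = ladLengthRange, enrichment = enrichment,
        contactIn = contactIn, contactOut = contactOut,
        damAccessibility = damAccessibility,
        accessibilityDip = accessibilityDip,
        readsPerSample = readsPerSample, chrMFraction = chrMFraction,
        readLength = as.integer(readLength), seed = as.integer(seed))
}

#' Effective in-LAD contact probability of a parameter set
#' @param params a \linkS4class{SimParams}.
#' @return numeric scalar in [0, 1].
#' @export
contactInProb <- function(params) {
    if (!is.na(params@contactIn)) return(params@contactIn)
    min(1, params@damAccessibility * 2^(params@enrichment / 2))
}

.randomDNA <- function(len) {
    rawToChar(as.raw(c(65L, 67L, 71L, 84L))[sample.int(4L, len, replace = TRUE)])
}

#' Simulate an i.i.d.-uniform genome
#'
#' Nuclear chromosomes of (near-)equal length plus one small mitochondrial
#' contig named \code{chrM}.  Under the uniform base model GATC occurs at
#' density 1/256 per position, so DpnI fragment lengths are geometric with
#' median about 177 bp.  Deterministic given the seed.
#'
#' @param params a \linkS4class{SimParams}.
#' @return named \code{DNAStringSet} (\code{chr1..chrN}, \code{chrM}).
#' @export
simulateGenome <- function(params) {
    stopifnot(is(params, "SimParams"))
    if (params@genomeLength <= 0) stop("genomeLength must be positive")
    set.seed(params@seed)
    n <- params@nChromosomes
    base <- floor(params@genomeLength / n)
    lens <- rep(base, n)
    lens[n] <- params@genomeLength - base * (n - 1)
    seqs <- vapply(lens, .randomDNA, character(1))
    seqs <- c(seqs, .randomDNA(params@chrMLength))
    names(seqs) <- c(paste0("chr", seq_len(n)), "chrM")
    Biostrings::DNAStringSet(seqs)
}

#' Simulate ground-truth LAD structure
#'
#' Places non-overlapping LADs (log-uniform lengths, uniform positions, a
#' minimum separation of 10 kb so that distinct truth LADs remain
#' resolvable) on the nuclear chromosomes until the target coverage is
#' reached; the last LAD's length is capped at the remaining coverage budget
#' (but not below the minimum LAD length), so realized coverage is within
#' one minimum LAD length of the target.  Per-fragment
#' lamina-contact probability is \code{contactInProb(params)} for fragments
#' whose midpoint lies in a LAD and \code{params@contactOut} elsewhere
#' (0 on \code{chrM}).
#'
#' @param params a \linkS4class{SimParams}.
#' @param genome the simulated genome (\code{DNAStringSet}).
#' @param fmap optional precomputed \linkS4class{FragmentMap} of
#'   \code{genome}.
#' @return a \linkS4class{SimTruth}.
#' @export
simulateLADs <- function(params, genome, fmap = buildFragmentMap(genome)) {
    stopifnot(is(params, "SimParams"))
    set.seed(params@seed + 1L)
    nuc <- setdiff(names(genome), "chrM")
    lens <- stats::setNames(BiocGenerics::width(genome), names(genome))[nuc]
    target <- params@ladCoverage * sum(as.numeric(lens))
    minLen <- params@ladLengthRange[1]; maxLen <- params@ladLengthRange[2]
    sep <- 10e3
    placed <- GRanges()
    covered <- 0
    attempts <- 0L
    while (covered < target && target > 0) {
        attempts <- attempts + 1L
        if (attempts > 20000L)
            stop("could not reach LAD coverage ", params@ladCoverage,
                 " after ", attempts, " attempts")
        len <- round(exp(stats::runif(1, log(minLen), log(maxLen))))
        len <- min(len, max(target - covered, minLen))
        chrom <- sample(nuc, 1, prob = lens)
        if (len >= lens[[chrom]]) next
        start <- sample.int(lens[[chrom]] - len, 1)
        cand <- GRanges(factor(chrom, nuc), IRanges::IRanges(start, width = len))
        near <- GenomicRanges::findOverlaps(
            cand + sep, placed, ignore.strand = TRUE)
        if (length(near)) next
        placed <- c(placed, cand)
        covered <- covered + len
    }
    placed <- BiocGenerics::sort(placed)
    fr <- fmap@ranges
    mids <- GRanges(GenomicRanges::seqnames(fr), IRanges::IRanges(
        start = (BiocGenerics::start(fr) - 1L + BiocGenerics::end(fr)) %/% 2L + 1L,
        width = 1L))
    inLad <- GenomicRanges::countOverlaps(mids, placed,
                                          ignore.strand = TRUE) > 0
    prob <- ifelse(inLad, contactInProb(params), params@contactOut)
    prob[as.character(GenomicRanges::seqnames(fr)) == "chrM"] <- 0
    new("SimTruth", lads = placed, contactProb = prob, fmap = fmap)
}

#' Simulate per-site Dam methylation and amplicon selection
#'
#' Each internal GATC cut site is methylated independently; a fragment is
#' amplifiable iff BOTH flanking sites are methylated (DpnI exposes the ends
#' of doubly methylated fragments; DpnII cleaves any unmethylated GATC and
#' destroys the template).  For the LaminB1-Dam sample the per-site
#' methylation probability is the mean lamina-contact probability of the two
#' fragments sharing the site; for the Dam-only control it is the
#' accessibility constant (optionally dipping inside LADs).  Terminal
#' fragments (one flank is a chromosome end, not a cut) are never
#' amplifiable; \code{chrM} fragments are excluded (mitochondrial reads are
#' injected separately).
#'
#' @param truth a \linkS4class{SimTruth}.
#' @param fmap the \linkS4class{FragmentMap} of the simulated genome.
#' @param params a \linkS4class{SimParams}.
#' @param sample \code{"lmnb1"} or \code{"dam"}.
#' @return logical vector: amplifiable status per fragment.
#' @export
simulateMethylation <- function(truth, fmap, params,
                                sample = c("lmnb1", "dam")) {
    sample <- match.arg(sample)
    stopifnot(is(truth, "SimTruth"), is(fmap, "FragmentMap"))
    set.seed(params@seed + if (sample == "lmnb1") 2L else 3L)
    fr <- fmap@ranges
    chrom <- as.character(GenomicRanges::seqnames(fr))
    amp <- logical(length(fr))
    for (ch in unique(chrom)) {
        sel <- which(chrom == ch)
        n <- length(sel)
        if (n < 3 || ch == "chrM") next
        p <- truth@contactProb[sel]
        siteProb <- if (sample == "lmnb1") {
            (p[-n] + p[-1]) / 2
        } else if (params@accessibilityDip) {
            # a site flanking an in-LAD fragment is less accessible
            ifelse((p[-n] + p[-1]) / 2 > params@contactOut,
                   0.3, params@damAccessibility)
        } else rep(params@damAccessibility, n - 1L)
        meth <- stats::runif(n - 1L) < siteProb
        amp[sel[2:(n - 1)]] <- meth[-(n - 1L)] & meth[-1L]
    }
    amp
}

#' Length-mass fraction of amplifiable fragments within a size window
#'
#' On a gel, DamID amplicons appear as a smear; under the default parameters
#' most of the amplifiable length mass falls between 200 and 1500 bp.
#'
#' @param fmap a \linkS4class{FragmentMap}.
#' @param amplifiable logical vector from \code{\link{simulateMethylation}}.
#' @param lower,upper size window in bp (defaults 200 and 1500).
#' @return fraction of total amplifiable length within the window.
#' @export
ampliconMassFraction <- function(fmap, amplifiable, lower = 200, upper = 1500) {
    w <- BiocGenerics::width(fmap@ranges)[amplifiable]
    if (!length(w)) return(NA_real_)
    sum(as.numeric(w[w >= lower & w <= upper])) / sum(as.numeric(w))
}

#' Simulate reads for one sample
#'
#' Per-fragment read counts are Poisson with mean proportional to
#' amplifiability times fragment length; read starts are uniform within the
#' fragment.  Mitochondrial contaminant reads are injected at
#' \code{chrMFraction} (binomially) and placed uniformly on \code{chrM}.
#' Output is sorted and carries \code{mapq = 60}, \code{flag = 0}.
#'
#' @param fmap the \linkS4class{FragmentMap}.
#' @param amplifiable logical per-fragment amplifiability for this sample.
#' @param params a \linkS4class{SimParams}.
#' @param sample \code{"lmnb1"} or \code{"dam"} (selects the RNG stream).
#' @return \code{GRanges} of alignments (see \code{\link{readAlignments}}).
#' @export
simulateReads <- function(fmap, amplifiable, params,
                          sample = c("lmnb1", "dam")) {
    sample <- match.arg(sample)
    set.seed(params@seed + if (sample == "lmnb1") 4L else 5L)
    fr <- fmap@ranges
    chrom <- as.character(GenomicRanges::seqnames(fr))
    seqlens <- GenomeInfoDb::seqlengths(fr)
    total <- params@readsPerSample
    if (total <= 0) {
        out <- GRanges()
        out$mapq <- integer(0); out$flag <- integer(0)
        return(out)
    }
    nChrM <- stats::rbinom(1, total, params@chrMFraction)
    nNuclear <- total - nChrM
    w <- as.numeric(BiocGenerics::width(fr)) * amplifiable
    w[chrom == "chrM"] <- 0
    if (sum(w) == 0 && nNuclear > 0)
        stop("no amplifiable nuclear fragments to draw reads from")
    counts <- if (nNuclear > 0) stats::rpois(length(w), nNuclear * w / sum(w))
              else integer(length(w))
    idx <- rep.int(seq_along(w), counts)
    start0 <- BiocGenerics::start(fr)[idx] - 1L +
        floor(stats::runif(length(idx)) * BiocGenerics::width(fr)[idx])
    rchrom <- chrom[idx]
    if (nChrM > 0) {
        mlen <- seqlens[["chrM"]]
        mstart <- floor(stats::runif(nChrM) * max(mlen - params@readLength, 1))
        start0 <- c(start0, mstart)
        rchrom <- c(rchrom, rep("chrM", nChrM))
    }
    end0 <- pmin(start0 + params@readLength,
                 as.numeric(seqlens[rchrom]))
    gr <- GRanges(rchrom, IRanges::IRanges(start = start0 + 1L, end = end0))
    GenomeInfoDb::seqlevels(gr) <- names(seqlens)
    GenomeInfoDb::seqlengths(gr) <- seqlens
    gr$mapq <- rep(60L, length(gr))
    gr$flag <- rep(0L, length(gr))
    BiocGenerics::sort(gr)
}

#' Simulate a complete DamID experiment
#'
#' Runs the whole generative chain -- genome, fragment map, LAD truth,
#' per-sample methylation and amplicon selection, reads with mitochondrial
#' contamination -- and returns every intermediate plus a truth report.
#' Bit-for-bit reproducible from \code{params@seed}.
#'
#' @param params a \linkS4class{SimParams}.
#' @return list with \code{genome}, \code{fmap}, \code{truth},
#'   \code{amplifiable} (list lmnb1/dam), \code{reads} (list lmnb1/dam) and
#'   \code{truthReport} (plain list, JSON-ready).
#' @export
simulateDamIDExperiment <- function(params = simParams()) {
    genome <- simulateGenome(params)
    fmap <- buildFragmentMap(genome)
    truth <- simulateLADs(params, genome, fmap)
    ampL <- simulateMethylation(truth, fmap, params, "lmnb1")
    ampD <- simulateMethylation(truth, fmap, params, "dam")
    readsL <- simulateReads(fmap, ampL, params, "lmnb1")
    readsD <- simulateReads(fmap, ampD, params, "dam")
    nuclearBp <- sum(as.numeric(BiocGenerics::width(genome)[names(genome) != "chrM"]))
    truthReport <- list(
        seed = params@seed,
        genome_bp = nuclearBp,
        n_lads = length(truth@lads),
        lad_coverage = sum(as.numeric(BiocGenerics::width(truth@lads))) / nuclearBp,
        contact_in = contactInProb(params),
        contact_out = params@contactOut,
        reads_per_sample = params@readsPerSample,
        chrM_fraction = params@chrMFraction,
        n_reads = list(lmnb1 = length(readsL), dam = length(readsD)),
        n_chrM = list(
            lmnb1 = sum(as.character(GenomicRanges::seqnames(readsL)) == "chrM"),
            dam = sum(as.character(GenomicRanges::seqnames(readsD)) == "chrM")))
    list(genome = genome, fmap = fmap, truth = truth,
         amplifiable = list(lmnb1 = ampL, dam = ampD),
         reads = list(lmnb1 = readsL, dam = readsD),
         truthReport = truthReport)
}
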