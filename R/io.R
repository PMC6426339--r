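#' @include AllClasses.R AllGenerics.R
NULL

# All on-disk interval formats are BED-convention 0-based half-open;
# in-memory GRanges are 1-based closed.  rtracklayer does the shifting.

#' Read a reference genome from FASTA
#'
#' @param path path to a (optionally gzip-compressed) multi-record FASTA.
#' @return a named \code{DNAStringSet}; names are truncated at the first
#'   whitespace, sequences uppercased.
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    g <- Biostrings::readDNAStringSet(path)
    names(g) <- sub("\\s.*$", "", names(g))
    if (anyDuplicated(names(g))) stop("duplicate chromosome names in ", path)
    g
}

#' Write a genome to FASTA
#' @param genome named \code{DNAStringSet}.
#' @param path output path.
#' @export
writeGenomeFasta <- function(genome, path) {
    Biostrings::writeXStringSet(genome, path)
    invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED3+ file (0-based half-open on disk).
#' @param genome optional named lengths / \code{DNAStringSet} for seqinfo
#'   cross-checking; intervals on unknown chromosomes raise an error.
#' @return \code{GRanges} (1-based closed), sorted; a warning is issued if
#'   the file was not position-sorted.
#' @export
readBed <- function(path, genome = NULL) {
    if (!file.exists(path)) stop("no such file: ", path)
    gr <- rtracklayer::import(path, format = "BED")
    if (!is.null(genome)) {
        lens <- if (is(genome, "DNAStringSet"))
            stats::setNames(BiocGenerics::width(genome), names(genome))
        else genome
        bad <- setdiff(GenomeInfoDb::seqlevels(gr), names(lens))
        if (length(bad))
            stop("intervals on chromosomes absent from the genome: ",
                 paste(bad, collapse = ", "))
        GenomeInfoDb::seqlengths(gr) <- lens[GenomeInfoDb::seqlevels(gr)]
    }
    if (S4Vectors::isSorted(gr)) gr else {
        warning("intervals in ", path, " were not sorted; sorting")
        BiocGenerics::sort(gr)
    }
}

#' Write intervals to BED
#'
#' @param x a \code{GRanges}, \linkS4class{FragmentMap} (BED4 with
#'   \code{fragment_id} as name), \linkS4class{SegmentSet} (BED5 with the
#'   segment mean as score) or \linkS4class{LADSet} (BED3).
#' @param path output path.
#' @export
writeBed <- function(x, path) {
    gr <- if (is(x, "FragmentMap")) {
        g <- x@ranges
        g$name <- as.character(g$fragment_id)
        g$fragment_id <- NULL
        g
    } else if (is(x, "SegmentSet")) {
        g <- x@segments
        out <- GRanges(GenomicRanges::seqnames(g), IRanges::ranges(g))
        out$name <- paste0("seg_", seq_along(g))
        out$score <- g$mean_value
        out
    } else if (is(x, "LADSet")) {
        x@lads
    } else x
    rtracklayer::export(gr, path, format = "BED")
    invisible(path)
}

#' Read a FragmentMap previously written with writeBed
#'
#' @param path BED4 file (chrom, start, end, fragment_id).
#' @param genome named lengths or \code{DNAStringSet} providing chromosome
#'   lengths (needed for the partition invariant).
#' @param mode fragmentation mode to stamp on the map.
#' @param binSize bin size for \code{"fixed_bin"} maps.
#' @return a \linkS4class{FragmentMap}.
#' @export
readFragmentMap <- function(path, genome, mode = "dpnI", binSize = NA) {
    gr <- readBed(path, genome)
    gr$fragment_id <- as.integer(gr$name)
    gr$name <- NULL
    new("FragmentMap", ranges = gr, mode = mode, binSize = as.integer(binSize))
}

#' Write a RatioProfile as bedGraph
#'
#' Values are per fragment (variable width), one line per fragment.  For
#' genome-browser use, convert with
#' \code{wigToBigWig profile.bedGraph chrom.sizes profile.bw}.
#'
#' @param profile a \linkS4class{RatioProfile}.
#' @param path output path.
#' @export
writeBedGraph <- function(profile, path) {
    gr <- profile@fmap@ranges
    out <- GRanges(GenomicRanges::seqnames(gr), IRanges::ranges(gr),
                   score = profile@values)
    GenomeInfoDb::seqlengths(out) <- GenomeInfoDb::seqlengths(gr)
    rtracklayer::export(out, path, format = "bedGraph")
    invisible(path)
}

#' Read a bedGraph written by writeBedGraph back onto a FragmentMap
#'
#' @param path bedGraph path.
#' @param fmap the \linkS4class{FragmentMap} the values belong to; intervals
#'   must match it exactly.
#' @return a \linkS4class{RatioProfile} (smoothing/normalization flags reset).
#' @export
readBedGraph <- function(path, fmap) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (!S4Vectors::isSorted(gr)) {
        warning("bedGraph lines in ", path, " were not sorted; sorting")
        gr <- BiocGenerics::sort(gr)
    }
    fr <- fmap@ranges
    if (length(gr) != length(fr) ||
        !all(as.character(GenomicRanges::seqnames(gr)) ==
             as.character(GenomicRanges::seqnames(fr))) ||
        !all(BiocGenerics::start(gr) == BiocGenerics::start(fr)) ||
        !all(BiocGenerics::end(gr) == BiocGenerics::end(fr)))
        stop("bedGraph intervals do not match the fragment map")
    new("RatioProfile", fmap = fmap, values = as.numeric(gr$score),
        smoothingN = 0L, quantileNormalized = FALSE)
}

#' Read alignments from SAM/BAM or a BED-like alignment table
#'
#' Accepted formats: \code{.bam}, \code{.sam} (converted through Rsamtools),
#' or a 5-column tab-separated table \code{chrom start end mapq flag}
#' (0-based half-open, SAM flag semantics).  Unmapped records are kept (with
#' empty coordinates) so that total-read accounting stays honest.
#'
#' @param path input path.
#' @return \code{GRanges} with metadata columns \code{mapq} and \code{flag};
#'   unmapped records sit on the pseudo-chromosome \code{"*"}.
#' @export
readAlignments <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    ext <- tolower(tools::file_ext(path))
    if (ext %in% c("bam", "sam")) {
        bam <- if (ext == "sam") {
            Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
        } else path
        p <- Rsamtools::ScanBamParam(
            what = c("rname", "pos", "qwidth", "mapq", "flag"))
        b <- Rsamtools::scanBam(bam, param = p)[[1]]
        mapped <- !bitwAnd(b$flag, 4L)
        chrom <- as.character(b$rname)
        chrom[!mapped | is.na(chrom)] <- "*"
        start <- ifelse(mapped & !is.na(b$pos), b$pos, 1L)
        wid <- ifelse(mapped & !is.na(b$qwidth), b$qwidth, 1L)
        gr <- GRanges(chrom, IRanges::IRanges(start = start,
                                              width = pmax(wid, 1L)))
        gr$mapq <- ifelse(is.na(b$mapq), 0L, b$mapq)
        gr$flag <- b$flag
        gr
    } else {
        tab <- utils::read.table(path, sep = "\t", header = FALSE,
                                 col.names = c("chrom", "start", "end",
                                               "mapq", "flag"),
                                 colClasses = c("character", "integer",
                                                "integer", "integer",
                                                "integer"))
        bad <- which(tab$end <= tab$start & tab$chrom != "*")
        if (length(bad))
            stop("malformed alignment line(s): ",
                 paste(utils::head(bad, 5), collapse = ", "))
        gr <- GRanges(tab$chrom,
                      IRanges::IRanges(start = tab$start + 1L,
                                       end = pmax(tab$end, tab$start + 1L)))
        gr$mapq <- tab$mapq
        gr$flag <- tab$flag
        gr
    }
}

#' Write alignments as the 5-column BED-like table
#'
#' @param aln \code{GRanges} with \code{mapq} and \code{flag} columns.
#' @param path output path.
#' @export
writeAlignments <- function(aln, path) {
    utils::write.table(
        data.frame(chrom = as.character(GenomicRanges::seqnames(aln)),
                   start = BiocGenerics::start(aln) - 1L,
                   end = BiocGenerics::end(aln),
                   mapq = aln$mapq, flag = aln$flag),
        path, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write an object as JSON
#' @param x a list (report, provenance, ...).
#' @param path output path.
#' @export
writeJson <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}
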