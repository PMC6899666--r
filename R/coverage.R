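#' @title BAM coverage extraction
#' @name coverage-module
#' @description Per-nucleotide read depth and region read counts from
#'   coordinate-sorted, indexed BAM files — the mpileup / view equivalents
#'   the congruency score and RPKM are computed from.
NULL

# Permissive read filter mirroring default samtools behaviour: drop unmapped,
# secondary and supplementary records; keep duplicates and QC-fail reads;
# no mapping-quality threshold.
.primary_flag <- function() {
  Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                         isSecondaryAlignment = FALSE,
                         isSupplementaryAlignment = FALSE)
}

.check_bam <- function(bam, region = NULL) {
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  bai <- paste0(bam, ".bai")
  if (!file.exists(bai) && !file.exists(sub("\\.bam$", ".bai", bam))) {
    stop("BAM index not found for ", bam,
         "; index the file first (e.g. Rsamtools::indexBam or samtools index)")
  }
  if (!is.null(region)) {
    chroms <- names(Rsamtools::scanBamHeader(bam)[[1]]$targets)
    chr <- as.character(GenomicRanges::seqnames(region))
    if (!chr %in% chroms) {
      stop("chromosome '", chr, "' not in BAM header; available: ",
           paste(chroms, collapse = ", "))
    }
  }
  invisible(TRUE)
}

# Primary alignments whose reference span overlaps `region`, as GAlignments.
.read_region <- function(bam, region) {
  param <- Rsamtools::ScanBamParam(which = region, flag = .primary_flag())
  GenomicAlignments::readGAlignments(bam, param = param)
}

#' Per-nucleotide read depth over a region
#'
#' Splice-aware pileup: a position's depth is the number of primary
#' alignments whose aligned bases cover it. CIGAR M/=/X and D (deletion)
#' operations count as covering; N (intron skip) segments contribute zero,
#' so a spliced read adds depth only over its exonic blocks. Unmapped,
#' secondary and supplementary records are excluded; duplicates and QC-fail
#' reads are kept and no mapping-quality or depth cap is applied.
#'
#' @param bam Path to a coordinate-sorted, indexed BAM file.
#' @param region A length-1 `GRanges` (see [genomic_interval()]).
#' @param sample_id Label stored on the returned track (default: BAM
#'   basename).
#' @return A `coverage_track`: list with `sample_id`, `region`, `depth`
#'   (integer vector, one entry per nucleotide of `region`),
#'   `reads_in_region` (see [count_reads()]) and `max_depth`.
#' @export
pileup <- function(bam, region, sample_id = NULL) {
  stopifnot(methods::is(region, "GRanges"), length(region) == 1L)
  .check_bam(bam, region)
  galn <- .read_region(bam, region)
  n <- GenomicRanges::width(region)
  if (length(galn) == 0L) {
    depth <- integer(n)
    nreads <- 0L
  } else {
    cvg <- GenomicAlignments::coverage(galn)[[as.character(GenomicRanges::seqnames(region))]]
    lo <- GenomicRanges::start(region); hi <- GenomicRanges::end(region)
    # coverage() Rle may be shorter than hi when no read reaches the region end
    if (length(cvg) < hi) cvg <- c(cvg, S4Vectors::Rle(0L, hi - length(cvg)))
    depth <- as.integer(cvg[lo:hi])
    # >= 1 aligned (non-N) base inside the region
    nreads <- sum(IRanges::overlapsAny(GenomicAlignments::grglist(galn), region,
                                       ignore.strand = TRUE))
  }
  structure(
    list(sample_id = sample_id %||% basename(bam),
         region = region, depth = depth,
         reads_in_region = as.integer(nreads),
         max_depth = if (n) max(depth) else 0L),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat("coverage_track '", x$sample_id, "' over ",
      as.character(GenomicRanges::seqnames(x$region)),
      sprintf("[%d, %d]", GenomicRanges::start(x$region), GenomicRanges::end(x$region)),
      ": ", x$reads_in_region, " reads, max depth ", x$max_depth, "\n", sep = "")
  invisible(x)
}

#' Count reads overlapping a region
#'
#' Number of primary, mapped alignments with at least one aligned base in
#' `region`; each read is counted once even when it spans the region
#' boundary. Reads bridging the region purely through an N (intron) gap do
#' not count. This is the RPKM numerator.
#'
#' @inheritParams pileup
#' @return Non-negative integer.
#' @export
count_reads <- function(bam, region) {
  stopifnot(methods::is(region, "GRanges"), length(region) == 1L)
  .check_bam(bam, region)
  galn <- .read_region(bam, region)
  if (length(galn) == 0L) return(0L)
  as.integer(sum(IRanges::overlapsAny(GenomicAlignments::grglist(galn), region,
                                      ignore.strand = TRUE)))
}

#' Total mapped reads of a sample
#'
#' The million-reads denominator of [rpkm()]. If `override` is supplied
#' (typically the `total_reads_mapped` field of the compendium
#' configuration) it is returned as-is; otherwise the primary mapped records
#' of the whole BAM are counted.
#'
#' @param bam Path to an indexed BAM file (may be `NULL` when `override`
#'   is given).
#' @param override Optional positive integer from the sample metadata.
#' @return Positive integer.
#' @export
total_mapped <- function(bam, override = NULL) {
  if (!is.null(override)) {
    override <- as.integer(override)
    if (is.na(override) || override <= 0L) {
      stop("total_mapped override must be a positive integer")
    }
    return(override)
  }
  if (is.null(bam)) stop("either a BAM path or an override is required")
  .check_bam(bam)
  n <- Rsamtools::countBam(
    bam, param = Rsamtools::ScanBamParam(flag = .primary_flag()))$records
  as.integer(n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
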