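#' Point-biserial congruency between coverage and an exon mask
#'
#' Correlates the continuous per-nucleotide coverage vector of a sample with
#' the dichotomous (exon = 1 / not-exon = 0) vector of a splice variant.
#' With \eqn{M_1, M_0} the mean depths at mask-1 and mask-0 positions,
#' \eqn{n_1, n_0} their counts, \eqn{n = n_1 + n_0} and \eqn{s} the
#' population standard deviation of the full depth vector,
#' \deqn{r_{pb} = \frac{M_1 - M_0}{s}\sqrt{\frac{n_1 n_0}{n^2}},}
#' which is algebraically the Pearson correlation of the two vectors. A value
#' near 1 indicates the sample's read pileup is congruent with that variant's
#' exon structure.
#'
#' The score is undefined (`NaN`) when either vector has zero variance: an
#' all-exon or no-exon mask, or uniform (e.g. all-zero) coverage.
#'
#' @param track A `coverage_track` from [pileup()], or a bare numeric depth
#'   vector.
#' @param mask An `exon_mask` from [build_exon_mask()], or a bare 0/1 vector.
#' @return A value in \[-1, 1\], or `NaN` when undefined.
#' @examples
#' point_biserial(c(5, 5, 5, 0, 0, 1, 4, 4, 6, 5),
#'                c(1, 1, 1, 0, 0, 0, 1, 1, 1, 1))
#' @export
point_biserial <- function(track, mask) {
  x <- if (inherits(track, "coverage_track")) track$depth else track
  m <- if (inherits(mask, "exon_mask")) mask$values else mask
  if (length(x) != length(m)) {
    stop("length mismatch: depth has ", length(x),
         " positions, mask has ", length(m))
  }
  n <- length(x)
  stopifnot(n >= 2L, all(m %in% c(0L, 1L)))
  n1 <- sum(m == 1L); n0 <- n - n1
  if (n1 == 0L || n0 == 0L) return(NaN)               # mask has zero variance
  s <- sqrt(mean((x - mean(x))^2))                    # population sd
  if (s == 0) return(NaN)                             # uniform coverage
  (mean(x[m == 1L]) - mean(x[m == 0L])) / s * sqrt(n1 * n0 / n^2)
}

#' RPKM: reads per kilobase of exon per million mapped reads
#'
#' Standardizes a region read count to the exonic length of the gene (in
#' kilobases) and the sequencing depth of the experiment (in millions of
#' mapped reads):
#' \deqn{\mathrm{RPKM} = \frac{\mathrm{reads}}{(L/1000)\,(N/10^6)}
#'   = \frac{\mathrm{reads} \cdot 10^9}{L \cdot N}.}
#' The numerator counts reads overlapping the full genomic span of the locus
#' (introns included, the samtools-view semantics of [count_reads()]) while
#' the denominator uses the selected variant's exonic length — a deliberate
#' mixed convention, documented as such.
#'
#' @param reads_in_region Non-negative read count over the locus.
#' @param exon_length Exonic length in nucleotides (> 0), see [exon_length()].
#' @param total_mapped Total mapped reads of the experiment (> 0).
#' @return Non-negative real.
#' @examples
#' rpkm(1000, 1000, 1e7)  # 100
#' @export
rpkm <- function(reads_in_region, exon_length, total_mapped) {
  if (exon_length <= 0) stop("exon_length must be positive")
  if (total_mapped <= 0) stop("total_mapped must be positive")
  if (reads_in_region < 0) stop("reads_in_region must be non-negative")
  reads_in_region * 1e9 / (as.numeric(exon_length) * as.numeric(total_mapped))
}

#' Control-relative expression (log2 fold change)
#'
#' `log2(sample RPKM / reference)`, where the reference is the arithmetic
#' mean of the control samples' RPKM values — or, in atlas mode, the median
#' of all samples' RPKM values (used when a compendium has no designated
#' controls, as in a developmental atlas). A value of -2 represents a
#' four-fold decrease relative to the control(s). Undefined (`NaN`) when the
#' reference or the sample RPKM is zero.
#'
#' @param sample_rpkm The sample's RPKM.
#' @param control_rpkms Non-empty numeric vector: the controls' RPKMs, or in
#'   atlas mode all samples' RPKMs.
#' @param atlas_mode If `TRUE`, the reference is `median(control_rpkms)`
#'   instead of the mean.
#' @return Real, or `NaN` when undefined.
#' @examples
#' relative_expression(1, c(2, 4, 6))   # log2(1/4) = -2
#' @export
relative_expression <- function(sample_rpkm, control_rpkms, atlas_mode = FALSE) {
  if (length(control_rpkms) == 0L) stop("control_rpkms must be non-empty")
  reference <- if (atlas_mode) stats::median(control_rpkms) else mean(control_rpkms)
  if (reference == 0 || sample_rpkm == 0) return(NaN)
  log2(sample_rpkm / reference)
}

#' Summarize one sample's expression at one gene
#'
#' Composes the coverage and statistics layers: the point-biserial score for
#' every splice variant of the gene, and the absolute RPKM using the
#' region's read count and the selected variant's exonic length. The
#' control-relative value is left undefined here; it is resolved by
#' [build_table()] once all samples' RPKMs are known.
#'
#' @param track A `coverage_track` over exactly the gene span.
#' @param gene A [gene_model()].
#' @param total_mapped Total mapped reads of the sample (> 0).
#' @param selected_variant Variant ID whose exon length standardizes the
#'   RPKM; defaults to the gene's first variant.
#' @return An `expression_summary`: list with `sample_id`, `gene_id`,
#'   `selected_variant`, `reads_in_region`, `rpkm_absolute`,
#'   `rpkm_relative` (`NaN` until controls are resolved) and
#'   `rpb_by_variant` (named numeric).
#' @export
summarize_sample <- function(track, gene, total_mapped,
                             selected_variant = names(gene$variants)[1L]) {
  stopifnot(inherits(track, "coverage_track"), inherits(gene, "gene_model"))
  if (GenomicRanges::width(track$region) != GenomicRanges::width(gene$span) ||
      GenomicRanges::start(track$region) != GenomicRanges::start(gene$span)) {
    stop("track region does not match the span of gene ", gene$gene_id)
  }
  if (!selected_variant %in% names(gene$variants)) {
    stop("unknown variant '", selected_variant, "' for gene ", gene$gene_id)
  }
  rpb <- vapply(gene$variants, function(v)
    point_biserial(track, build_exon_mask(v, gene$span)), numeric(1))
  structure(
    list(sample_id = track$sample_id,
         gene_id = gene$gene_id,
         selected_variant = selected_variant,
         reads_in_region = track$reads_in_region,
         rpkm_absolute = rpkm(track$reads_in_region,
                              exon_length(gene$variants[[selected_variant]]),
                              total_mapped),
         rpkm_relative = NaN,
         rpb_by_variant = rpb),
    class = "expression_summary"
  )
}
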