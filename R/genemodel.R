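#' @title Gene models, splice variants and exon masks
#' @name genemodel
#' @description Read GFF3 annotation into typed gene models, and build the
#'   per-nucleotide dichotomous exon masks that the point-biserial score
#'   compares against read coverage.
NULL

#' Construct a genomic interval
#'
#' A length-1 [GenomicRanges::GRanges] used as the region type throughout the
#' package. Coordinates are 1-based closed, the Bioconductor convention; all
#' GFF3/BAM I/O converts at the boundary via rtracklayer/Rsamtools.
#'
#' @param chrom Chromosome / sequence name.
#' @param start,end 1-based closed coordinates, `start <= end`.
#' @param strand `"+"`, `"-"` or `"*"` (unknown/unstranded).
#' @return A `GRanges` of length 1.
#' @examples
#' genomic_interval("chrS", 11, 20)  # 10 nucleotides
#' @export
genomic_interval <- function(chrom, start, end, strand = "*") {
  stopifnot(length(chrom) == 1L, length(start) == 1L, length(end) == 1L)
  if (start > end) {
    stop("invalid interval: start (", start, ") > end (", end, ")")
  }
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

#' Construct a splice variant
#'
#' One mRNA structure of a gene: its exons plus optional CDS and 5'/3' UTR
#' intervals. Exons are merged (overlapping records unified) and sorted;
#' every CDS/UTR interval must lie within the exon union.
#'
#' @param variant_id Variant identifier, e.g. `"g1.2"`.
#' @param exons,cds,utr5,utr3 [IRanges::IRanges] of genomic intervals
#'   (1-based closed). Only `exons` is required.
#' @return An object of class `splice_variant`.
#' @export
splice_variant <- function(variant_id, exons, cds = IRanges::IRanges(),
                           utr5 = IRanges::IRanges(), utr3 = IRanges::IRanges()) {
  stopifnot(is.character(variant_id), length(variant_id) == 1L)
  exons <- IRanges::reduce(exons)   # merge overlapping records, sorts by start
  if (length(exons) == 0L || sum(IRanges::width(exons)) == 0L) {
    stop("variant ", variant_id, " has no exonic sequence")
  }
  for (nm in c("cds", "utr5", "utr3")) {
    feat <- get(nm)
    if (length(feat) && !all(IRanges::overlapsAny(feat, exons, type = "within"))) {
      stop("variant ", variant_id, ": ", nm,
           " interval outside the union of exons")
    }
  }
  structure(
    list(variant_id = variant_id, exons = exons,
         cds = IRanges::reduce(cds), utr5 = IRanges::reduce(utr5),
         utr3 = IRanges::reduce(utr3)),
    class = "splice_variant"
  )
}

#' Construct a gene model
#'
#' A locus and its splice variants. The gene span is the union span over all
#' variants' exons, so every variant of the gene is scored against coverage
#' and mask vectors of identical length.
#'
#' @param gene_id Locus identifier.
#' @param chrom Chromosome name.
#' @param variants List of [splice_variant()] objects (at least one).
#' @param strand Gene strand; carried as metadata, ignored by masks and
#'   coverage (unstranded libraries assumed).
#' @return An object of class `gene_model` with elements `gene_id`, `chrom`,
#'   `strand`, `span` (length-1 `GRanges`) and `variants` (named list).
#' @export
gene_model <- function(gene_id, chrom, variants, strand = "*") {
  stopifnot(is.character(gene_id), length(gene_id) == 1L)
  if (length(variants) == 0L) {
    stop("gene ", gene_id, " has no splice variants")
  }
  stopifnot(all(vapply(variants, inherits, logical(1), "splice_variant")))
  names(variants) <- vapply(variants, `[[`, character(1), "variant_id")
  all_exons <- do.call(c, unname(lapply(variants, `[[`, "exons")))
  span <- genomic_interval(chrom, min(IRanges::start(all_exons)),
                           max(IRanges::end(all_exons)), strand = strand)
  structure(
    list(gene_id = gene_id, chrom = chrom, strand = strand,
         span = span, variants = variants),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model", x$gene_id, "on", x$chrom,
      sprintf("[%d, %d]", GenomicRanges::start(x$span), GenomicRanges::end(x$span)),
      "strand", x$strand, "\n")
  for (v in x$variants) {
    cat("  ", v$variant_id, ": ", length(v$exons), " exon(s), ",
        exon_length(v), " nt exonic\n", sep = "")
  }
  invisible(x)
}

#' Total exonic length of a splice variant
#'
#' Sum of exon interval widths, the kilobase denominator of [rpkm()].
#'
#' @param variant A [splice_variant()].
#' @return Nucleotide count (integer).
#' @examples
#' v <- splice_variant("v1", IRanges::IRanges(c(1, 7), c(3, 10)))
#' exon_length(v)  # 7
#' @export
exon_length <- function(variant) {
  stopifnot(inherits(variant, "splice_variant"))
  sum(IRanges::width(variant$exons))
}

#' Build the dichotomous exon mask of a variant over a gene span
#'
#' The mask is a 0/1 vector with one entry per nucleotide of `span`:
#' 1 where the position lies inside an exon of the variant (UTR-covered exon
#' portions count as exon), 0 elsewhere. It is the dichotomous vector the
#' point-biserial score compares with the coverage vector; both have the
#' gene-span length.
#'
#' @param variant A [splice_variant()].
#' @param span The gene span, a length-1 `GRanges` (or `IRanges`) containing
#'   every exon of the variant.
#' @return An object of class `exon_mask`: list with `variant_id`, `values`
#'   (integer 0/1 vector) and `length`.
#' @examples
#' v <- splice_variant("v1", IRanges::IRanges(c(1, 7), c(3, 10)))
#' build_exon_mask(v, genomic_interval("chrS", 1, 10))$values
#' @export
build_exon_mask <- function(variant, span) {
  stopifnot(inherits(variant, "splice_variant"))
  if (methods::is(span, "GRanges")) span <- IRanges::ranges(span)
  stopifnot(length(span) == 1L)
  s0 <- IRanges::start(span); e0 <- IRanges::end(span)
  ex <- variant$exons
  out <- IRanges::start(ex) < s0 | IRanges::end(ex) > e0
  if (any(out)) {
    i <- which(out)[1L]
    stop("variant ", variant$variant_id, ": exon [",
         IRanges::start(ex)[i], ", ", IRanges::end(ex)[i],
         "] lies outside span [", s0, ", ", e0, "]")
  }
  n <- e0 - s0 + 1L
  cov <- IRanges::coverage(IRanges::shift(ex, 1L - s0), width = n)
  structure(
    list(variant_id = variant$variant_id,
         values = as.integer(as.integer(cov) > 0L),
         length = n),
    class = "exon_mask"
  )
}

# Feature types recognised in GFF3 input. Transcript-level rows other than
# mRNA (ncRNA etc.) are not variant containers here and fall through to the
# unknown-type warning.
.gff_gene_types <- "gene"
.gff_mrna_types <- "mRNA"
.gff_feat_types <- c(exon = "exons", CDS = "cds",
                     five_prime_UTR = "utr5", three_prime_UTR = "utr3")

#' Parse GFF3 annotation into gene models
#'
#' Reads a GFF3 file whose `gene` / `mRNA` / `exon` / `CDS` /
#' `five_prime_UTR` / `three_prime_UTR` records are linked by `ID` / `Parent`
#' attributes, and assembles one [gene_model()] per gene. Rows with
#' unrecognised feature types are skipped with a warning, as are exon/CDS/UTR
#' rows whose parent mRNA cannot be resolved; genes that end up with no
#' variants are dropped with a warning.
#'
#' @param path Path to a GFF3 file.
#' @param locus_filter Optional character vector of gene IDs to keep.
#' @return Named list of `gene_model` objects (names = gene IDs).
#' @export
parse_gff <- function(path, locus_filter = NULL) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gff <- rtracklayer::readGFF(path,
                              columns = c("seqid", "type", "start", "end", "strand"),
                              tags = c("ID", "Parent"))
  gff$type <- as.character(gff$type)
  known <- c(.gff_gene_types, .gff_mrna_types, names(.gff_feat_types))
  unknown <- setdiff(unique(gff$type), known)
  if (length(unknown)) {
    warning("ignoring unrecognised GFF3 feature type(s): ",
            paste(unknown, collapse = ", "))
  }
  parent1 <- vapply(gff$Parent, function(p)
    if (length(p)) as.character(p)[1L] else NA_character_, character(1))

  genes_df <- gff[gff$type %in% .gff_gene_types, , drop = FALSE]
  mrna_df <- gff[gff$type %in% .gff_mrna_types, , drop = FALSE]
  feat_df <- gff[gff$type %in% names(.gff_feat_types), , drop = FALSE]
  feat_parent <- parent1[gff$type %in% names(.gff_feat_types)]

  orphan <- !(feat_parent %in% mrna_df$ID) | is.na(feat_parent)
  if (any(orphan)) {
    warning(sum(orphan), " feature record(s) with no resolvable parent mRNA ",
            "were rejected")
    feat_df <- feat_df[!orphan, , drop = FALSE]
    feat_parent <- feat_parent[!orphan]
  }

  mrna_gene <- parent1[gff$type %in% .gff_mrna_types]
  models <- list()
  for (gi in seq_len(nrow(genes_df))) {
    gid <- genes_df$ID[gi]
    if (!is.null(locus_filter) && !(gid %in% locus_filter)) next
    vids <- mrna_df$ID[!is.na(mrna_gene) & mrna_gene == gid]
    variants <- list()
    for (vid in vids) {
      rows <- feat_df[feat_parent == vid, , drop = FALSE]
      by_type <- lapply(names(.gff_feat_types), function(tp) {
        r <- rows[rows$type == tp, , drop = FALSE]
        IRanges::IRanges(r$start, r$end)
      })
      names(by_type) <- unname(.gff_feat_types)
      if (length(by_type$exons) == 0L) next  # mRNA without exons: skip
      variants[[vid]] <- splice_variant(vid, exons = by_type$exons,
                                        cds = by_type$cds,
                                        utr5 = by_type$utr5,
                                        utr3 = by_type$utr3)
    }
    if (length(variants) == 0L) {
      warning("gene ", gid, " has no splice variants and was excluded")
      next
    }
    models[[gid]] <- gene_model(gid, as.character(genes_df$seqid[gi]),
                                variants,
                                strand = as.character(genes_df$strand[gi]))
  }
  models
}
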