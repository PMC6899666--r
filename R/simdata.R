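#' @title Deterministic splice-variant read simulator
#' @name simdata-module
#' @description Generates toy multi-isoform gene models (GFF3) and spliced
#'   short-read alignments (SAM converted to sorted, indexed BAM) drawn from
#'   known isoform mixtures at controlled depth, with full ground truth, so
#'   the entire engine is testable offline. Reads are single-end with
#'   placeholder bases (the engine never reads base identities): coverage
#'   geometry, not sequence, drives every statistic in scope.
NULL

#' Simulation specification
#'
#' Captures everything a simulation run depends on; the seed fixes all
#' randomness, so identical specs give byte-identical GFF3/SAM output.
#'
#' Archetypes realize classic alternative-splicing events with distinct
#' coverage signatures (all with a distinguishing region of at least
#' 50 bp between the two variants):
#' \describe{
#'   \item{skip}{variant 1 has exons A-B-C, variant 2 skips the 200 bp
#'     cassette exon B.}
#'   \item{retention}{variant 1 has three exons; variant 2 retains the
#'     first 150 bp intron, keeping the second one spliced (so neither
#'     variant's exons cover the whole gene span, which would make its
#'     exon mask constant and the congruency score undefined).}
#'   \item{acceptor}{variant 2 uses an acceptor site 100 bp upstream,
#'     extending its second exon.}
#' }
#'
#' @param seed Integer seed fixing all randomness.
#' @param archetype `"skip"`, `"retention"` or `"acceptor"`.
#' @param gene_id Gene identifier (variants become `<gene_id>.1`, `.2`).
#' @param chrom Toy chromosome name.
#' @param origin Genomic start of the gene (1-based).
#' @param mixture Named proportions per variant ID, summing to 1.
#' @param depth Target mean exonic coverage (x).
#' @param read_length Read length in nucleotides.
#' @param n_unmapped Number of additional unmapped records to emit.
#' @param samples Optional list for [make_compendium()]: each element a
#'   list with `name`, `mixture`, and optionally `depth`, `controls`,
#'   `replicate_controls`, `title`, `description`, `color`, `svg_part`.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L,
                     archetype = c("skip", "retention", "acceptor"),
                     gene_id = "g1", chrom = "chrS", origin = 1001L,
                     mixture = NULL, depth = 20, read_length = 50L,
                     n_unmapped = 0L, samples = NULL) {
  archetype <- match.arg(archetype)
  v1 <- paste0(gene_id, ".1"); v2 <- paste0(gene_id, ".2")
  if (is.null(mixture)) {
    mixture <- stats::setNames(c(0.5, 0.5), c(v1, v2))
  }
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture proportions must sum to 1")
  structure(
    list(seed = as.integer(seed), archetype = archetype, gene_id = gene_id,
         chrom = chrom, origin = as.integer(origin), mixture = mixture,
         depth = depth, read_length = as.integer(read_length),
         n_unmapped = as.integer(n_unmapped), samples = samples),
    class = "sim_spec"
  )
}

# Map a transcript-coordinate interval [s, e] (1-based within the spliced
# transcript) onto genomic blocks given the variant's genomic exons.
.tx_to_genomic <- function(exons, s, e) {
  w <- IRanges::width(exons)
  tx_end <- cumsum(w)
  tx_start <- tx_end - w + 1L
  hit <- which(tx_end >= s & tx_start <= e)
  gs <- IRanges::start(exons)[hit] + pmax(s - tx_start[hit], 0L)
  ge <- IRanges::start(exons)[hit] +
    pmin(e - tx_start[hit], w[hit] - 1L)
  IRanges::IRanges(gs, ge)
}

# Exon structures for the three alternative-splicing archetypes.
.archetype_exons <- function(archetype, g0) {
  switch(archetype,
    skip = list(
      IRanges::IRanges(g0 + c(0L, 400L, 700L), g0 + c(299L, 599L, 999L)),
      IRanges::IRanges(g0 + c(0L, 700L), g0 + c(299L, 999L))),
    retention = list(
      IRanges::IRanges(g0 + c(0L, 450L, 900L), g0 + c(299L, 749L, 1199L)),
      IRanges::IRanges(g0 + c(0L, 900L), g0 + c(749L, 1199L))),
    acceptor = list(
      IRanges::IRanges(g0 + c(0L, 500L), g0 + c(299L, 899L)),
      IRanges::IRanges(g0 + c(0L, 400L), g0 + c(299L, 899L)))
  )
}

#' Generate a toy multi-isoform gene model
#'
#' Builds the two-variant [gene_model()] for the spec's archetype, with a
#' 60 nt 5' UTR and an 80 nt 3' UTR (in transcript coordinates) and the CDS
#' in between, and optionally writes it as GFF3 via [write_gff()].
#' Deterministic: the same spec always yields the same model and
#' byte-identical GFF3.
#'
#' @param spec A [sim_spec()].
#' @param gff_path Optional output GFF3 path.
#' @return A `gene_model`.
#' @export
make_gene <- function(spec, gff_path = NULL) {
  stopifnot(inherits(spec, "sim_spec"))
  exon_sets <- .archetype_exons(spec$archetype, spec$origin)
  variants <- lapply(seq_along(exon_sets), function(i) {
    ex <- exon_sets[[i]]
    L <- sum(IRanges::width(ex))
    u5 <- 60L; u3 <- 80L
    stopifnot(L > u5 + u3)
    splice_variant(paste0(spec$gene_id, ".", i), exons = ex,
                   utr5 = .tx_to_genomic(ex, 1L, u5),
                   cds = .tx_to_genomic(ex, u5 + 1L, L - u3),
                   utr3 = .tx_to_genomic(ex, L - u3 + 1L, L))
  })
  gene <- gene_model(spec$gene_id, spec$chrom, variants, strand = "+")
  if (!is.null(gff_path)) write_gff(gene, gff_path)
  gene
}

#' Write a gene model as GFF3
#'
#' Emits gene / mRNA / exon / CDS / five_prime_UTR / three_prime_UTR
#' records linked by ID/Parent attributes, deterministically ordered.
#' `parse_gff(write_gff(gene))` reproduces the model's interval sets.
#'
#' @param gene A [gene_model()].
#' @param path Output GFF3 path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(gene, path) {
  stopifnot(inherits(gene, "gene_model"))
  line <- function(type, s, e, attrs) {
    paste(gene$chrom, "splicecov_sim", type, s, e, ".",
          gene$strand, ".", attrs, sep = "\t")
  }
  out <- c("##gff-version 3",
           line("gene", GenomicRanges::start(gene$span),
                GenomicRanges::end(gene$span), paste0("ID=", gene$gene_id)))
  for (v in gene$variants) {
    out <- c(out,
             line("mRNA", min(IRanges::start(v$exons)),
                  max(IRanges::end(v$exons)),
                  paste0("ID=", v$variant_id, ";Parent=", gene$gene_id)))
    feat <- c(exon = "exons", five_prime_UTR = "utr5", CDS = "cds",
              three_prime_UTR = "utr3")
    for (tp in names(feat)) {
      ir <- v[[feat[[tp]]]]
      if (length(ir)) {
        out <- c(out, line(tp, IRanges::start(ir), IRanges::end(ir),
                           paste0("Parent=", v$variant_id)))
      }
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Simulate spliced reads from an isoform mixture
#'
#' Draws each read by sampling a variant from the mixture, then a start
#' position uniform over that variant's transcript coordinates; the read's
#' genomic alignment follows the variant's exon chain, with N (intron skip)
#' CIGAR operations across introns. The read count targets the requested
#' mean exonic coverage (`reads = depth x mixture-weighted exon length /
#' read length`). Records are written as SAM text (kept alongside the BAM
#' for inspection), then converted to a coordinate-sorted, indexed BAM.
#' Optional unmapped records are appended. Fully deterministic given the
#' spec's seed.
#'
#' @param gene A `gene_model` from [make_gene()] (same spec).
#' @param spec A [sim_spec()]; `mixture`, `depth`, `read_length`,
#'   `n_unmapped` and `seed` are used.
#' @param out_prefix Output path prefix: writes `<prefix>.sam`,
#'   `<prefix>.bam`, `<prefix>.bam.bai`.
#' @return List with `bam`, `sam` paths and `ground_truth`: `mixture`,
#'   `read_counts` (named, per variant), `total_mapped`, `n_unmapped`.
#' @export
simulate_reads <- function(gene, spec, out_prefix) {
  stopifnot(inherits(gene, "gene_model"), inherits(spec, "sim_spec"))
  vids <- names(spec$mixture)
  if (!all(vids %in% names(gene$variants))) {
    stop("mixture names variants absent from the gene model")
  }
  set.seed(spec$seed)
  L <- spec$read_length
  exlen <- vapply(gene$variants[vids], exon_length, numeric(1))
  if (any(exlen < L & spec$mixture > 0)) {
    stop("read_length exceeds the exonic length of a sampled variant")
  }
  n_total <- round(spec$depth * sum(spec$mixture * exlen) / L)
  counts <- if (n_total > 0) {
    as.vector(stats::rmultinom(1L, n_total, prob = spec$mixture))
  } else integer(length(vids))
  names(counts) <- vids

  chrom_len <- GenomicRanges::end(gene$span) + 1000L
  sam <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", gene$chrom, "\tLN:", chrom_len))
  seqstr <- strrep("A", L)
  ri <- 0L
  for (vid in vids) {
    ex <- gene$variants[[vid]]$exons
    nv <- counts[[vid]]
    if (nv == 0L) next
    starts <- sample.int(exlen[[vid]] - L + 1L, nv, replace = TRUE)
    for (s in starts) {
      ri <- ri + 1L
      blocks <- .tx_to_genomic(ex, s, s + L - 1L)
      bs <- IRanges::start(blocks); be <- IRanges::end(blocks)
      cig <- paste0(be[1L] - bs[1L] + 1L, "M")
      if (length(bs) > 1L) {
        for (k in 2L:length(bs)) {
          cig <- paste0(cig, bs[k] - be[k - 1L] - 1L, "N",
                        be[k] - bs[k] + 1L, "M")
        }
      }
      sam <- c(sam, paste(sprintf("r%06d_%s", ri, vid), 0L, gene$chrom,
                          bs[1L], 60L, cig, "*", 0L, 0L, seqstr, "*",
                          sep = "\t"))
    }
  }
  if (spec$n_unmapped > 0L) {
    for (k in seq_len(spec$n_unmapped)) {
      sam <- c(sam, paste(sprintf("u%06d", k), 4L, "*", 0L, 0L, "*", "*",
                          0L, 0L, seqstr, "*", sep = "\t"))
    }
  }
  sam_path <- paste0(out_prefix, ".sam")
  writeLines(sam, sam_path)
  bam_path <- Rsamtools::asBam(sam_path, out_prefix, overwrite = TRUE,
                               indexDestination = TRUE)
  list(bam = bam_path, sam = sam_path,
       ground_truth = list(mixture = spec$mixture, read_counts = counts,
                           total_mapped = as.integer(sum(counts)),
                           n_unmapped = spec$n_unmapped))
}

#' Simulate a multi-sample compendium
#'
#' Generates one gene model (GFF3) and, per sample in `spec$samples`, a
#' simulated BAM plus a [sample_record()] wired with the sample's declared
#' controls, then writes the compendium configuration XML readable by
#' [read_config()]. Per-sample seeds are derived deterministically from the
#' spec seed and the sample index. Emulates, at toy scale, a curated
#' multi-experiment RNA-seq compendium.
#'
#' @param spec A [sim_spec()] with a non-empty `samples` list.
#' @param dir Output directory (created if needed).
#' @param atlas_mode Dataset-level flag: median-as-control relative mode.
#' @return List with `compendium`, `gene`, `config_path`, `gff_path`, and
#'   `ground_truth` (named per sample).
#' @export
make_compendium <- function(spec, dir, atlas_mode = FALSE) {
  stopifnot(inherits(spec, "sim_spec"))
  if (length(spec$samples) == 0L) stop("spec$samples must list at least one sample")
  nms <- vapply(spec$samples, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate sample name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gff_path <- file.path(dir, paste0(spec$gene_id, ".gff3"))
  gene <- make_gene(spec, gff_path = gff_path)

  records <- list(); truth <- list()
  for (i in seq_along(spec$samples)) {
    sm <- spec$samples[[i]]
    sspec <- spec
    sspec$seed <- (spec$seed + 7919L * i) %% .Machine$integer.max
    sspec$mixture <- sm$mixture
    if (!is.null(sm$depth)) sspec$depth <- sm$depth
    sim <- simulate_reads(gene, sspec, file.path(dir, sm$name))
    truth[[sm$name]] <- sim$ground_truth
    records[[i]] <- sample_record(
      name = sm$name, bam_url = sim$bam,
      total_reads_mapped = sim$ground_truth$total_mapped,
      title = sm$title %||% sm$name,
      description = sm$description %||% "",
      color = sm$color %||% "#CC3333",
      svg_part = sm$svg_part %||% "",
      read_map_method = "simulated",
      controls = sm$controls %||% character(),
      replicate_controls = sm$replicate_controls %||% character()
    )
  }
  comp <- compendium(spec$gene_id, records, atlas_mode = atlas_mode)
  config_path <- file.path(dir, "config.xml")
  write_config(comp, config_path)
  list(compendium = comp, gene = gene, config_path = config_path,
       gff_path = gff_path, ground_truth = truth)
}
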