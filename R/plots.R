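#' @title Coverage and gene-structure rendering
#' @name plots-module
NULL

# Open a png (cairo) or svg device based on the file extension.
.open_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = grDevices::png(path, width = width, height = height,
                              type = "cairo"),
         svg = grDevices::svg(path, width = width / 96, height = height / 96),
         stop("unsupported image format '", ext, "'; use .png or .svg"))
}

#' Render a coverage profile
#'
#' A filled per-nucleotide read-depth profile over the track's region. The
#' y-axis is normalized per track to its own maximum depth (annotated on
#' the plot), so two tracks of identical shape at different depths render
#' identically apart from the label — the per-sample scaling that makes
#' profile shapes comparable across samples. A zero-depth track renders as
#' a flat baseline.
#'
#' @param track A `coverage_track` from [pileup()].
#' @param color Fill color (the sample's tissue color).
#' @param path Output `.png` or `.svg` path.
#' @param width,height Image size in pixels.
#' @return Invisibly, a list with `path` and the device-pixel extents of the
#'   plotted data range (`x_device`, `y_device`), useful for aligning the
#'   raster with genomic coordinates.
#' @export
render_coverage <- function(track, color = "#CC3333", path,
                            width = 900, height = 260) {
  stopifnot(inherits(track, "coverage_track"))
  d <- track$depth
  n <- length(d)
  stopifnot(n > 0L)
  s <- GenomicRanges::start(track$region)
  pos <- seq.int(s, length.out = n)
  ymax <- max(1L, track$max_depth)
  .open_device(path, width, height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(3.5, 3.5, 1.5, 0.5), mgp = c(2.2, 0.7, 0))
  plot(NA, xlim = c(pos[1L] - 0.5, pos[n] + 0.5), ylim = c(0, 1),
       xaxs = "i", yaxs = "i", xlab = paste0("position on ",
       as.character(GenomicRanges::seqnames(track$region))),
       ylab = "depth / max depth", main = track$sample_id, cex.main = 0.9)
  if (track$max_depth > 0L) {
    xs <- as.vector(rbind(pos - 0.5, pos + 0.5))
    ys <- as.vector(rbind(d, d)) / ymax
    graphics::polygon(c(xs[1L], xs, xs[length(xs)]), c(0, ys, 0),
                      col = color, border = NA)
  } else {
    graphics::abline(h = 0, col = color, lwd = 2)
  }
  graphics::mtext(paste("max depth:", track$max_depth), side = 3,
                  adj = 1, cex = 0.8, line = 0.2)
  geom <- list(
    x_device = graphics::grconvertX(c(pos[1L] - 0.5, pos[n] + 0.5),
                                    "user", "device"),
    y_device = graphics::grconvertY(c(0, 1), "user", "device"))
  invisible(c(list(path = path), geom))
}

#' Render the gene structure of all splice variants
#'
#' One row per variant: exons as dark-green boxes, UTR-covered portions
#' overlaid in light green, introns as thin connectors — the NCBI-style
#' gene-structure color scheme. The x-axis spans the gene span, aligned
#' with [render_coverage()] of the same gene.
#'
#' @param gene A [gene_model()].
#' @param path Output `.png` or `.svg` path.
#' @param width,height Image size in pixels.
#' @param exon_col,utr_col Fill colors for exon/CDS and UTR segments.
#' @return `path`, invisibly.
#' @export
render_gene_structure <- function(gene, path, width = 900,
                                  height = 60 + 50 * length(gene$variants),
                                  exon_col = "#1B7837", utr_col = "#A6DBA0") {
  stopifnot(inherits(gene, "gene_model"))
  nv <- length(gene$variants)
  s <- GenomicRanges::start(gene$span); e <- GenomicRanges::end(gene$span)
  .open_device(path, width, height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mar = c(3.5, 7, 1.5, 0.5), mgp = c(2.2, 0.7, 0))
  plot(NA, xlim = c(s - 0.5, e + 0.5), ylim = c(0.5, nv + 0.5),
       xaxs = "i", yaxt = "n", xlab = paste0("position on ", gene$chrom),
       ylab = "", main = gene$gene_id, cex.main = 0.9)
  graphics::axis(2, at = rev(seq_len(nv)), labels = names(gene$variants),
                 las = 1, tick = FALSE, cex.axis = 0.8)
  for (i in seq_len(nv)) {
    v <- gene$variants[[i]]
    y <- nv - i + 1L   # first variant on top
    ex <- v$exons
    graphics::segments(min(IRanges::start(ex)), y, max(IRanges::end(ex)), y,
                       col = "grey40")
    graphics::rect(IRanges::start(ex) - 0.5, y - 0.18,
                   IRanges::end(ex) + 0.5, y + 0.18,
                   col = exon_col, border = NA)
    utr <- c(v$utr5, v$utr3)
    if (length(utr)) {
      graphics::rect(IRanges::start(utr) - 0.5, y - 0.18,
                     IRanges::end(utr) + 0.5, y + 0.18,
                     col = utr_col, border = NA)
    }
  }
  invisible(path)
}
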