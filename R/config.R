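#' @title Compendium configuration (extended annots.xml dialect)
#' @name config-module
#' @description Read/write the XML configuration listing a compendium's
#'   samples and their metadata. The dialect extends the genome-browser
#'   `annots.xml` sample-listing style with expression-browser fields:
#'   `<files dataset_id atlas_mode><file name bam_url title description
#'   sra_id total_reads_mapped read_map_method svg_part svg_subpart color
#'   url controls replicate_controls/></files>`, with `controls` /
#'   `replicate_controls` as comma-separated sample-name lists and
#'   `atlas_mode` a dataset-level boolean selecting median-as-control
#'   relative expression.
NULL

# Known <file> attributes, in canonical (write) order.
.sample_attrs <- c("name", "bam_url", "title", "description", "sra_id",
                   "total_reads_mapped", "read_map_method", "svg_part",
                   "svg_subpart", "color", "url", "controls",
                   "replicate_controls")

#' Construct a sample record
#'
#' One compendium entry: the BAM locator plus display and normalization
#' metadata.
#'
#' @param name Unique sample name.
#' @param bam_url Path (or URI) of the sample's indexed BAM file.
#' @param total_reads_mapped Positive integer; the RPKM denominator.
#' @param title,description Display text (searchable by [filter_table()]).
#' @param sra_id Sequence Read Archive accession ("" if none).
#' @param read_map_method Aligner / pipeline note.
#' @param svg_part,svg_subpart Tissue pictograph image key (and subpart).
#' @param color Hex color for this sample's coverage plot.
#' @param url Publication link.
#' @param controls,replicate_controls Character vectors of control sample
#'   names within the same compendium.
#' @param extra Named character vector of unknown attributes, preserved for
#'   round-tripping.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(name, bam_url, total_reads_mapped,
                          title = name, description = "", sra_id = "",
                          read_map_method = "", svg_part = "", svg_subpart = "",
                          color = "#B0C4DE", url = "",
                          controls = character(), replicate_controls = character(),
                          extra = character()) {
  total_reads_mapped <- as.integer(total_reads_mapped)
  if (is.na(total_reads_mapped) || total_reads_mapped <= 0L) {
    stop("sample '", name, "': total_reads_mapped must be a positive integer")
  }
  extra <- if (length(extra)) extra else character()
  structure(
    list(name = name, bam_url = bam_url, title = title,
         description = description, sra_id = sra_id,
         total_reads_mapped = total_reads_mapped,
         read_map_method = read_map_method,
         svg_part = svg_part, svg_subpart = svg_subpart,
         color = color, url = url,
         controls = as.character(controls),
         replicate_controls = as.character(replicate_controls),
         extra = extra),
    class = "sample_record"
  )
}

#' Construct a compendium
#'
#' An ordered set of [sample_record()]s; document order defines the default
#' display order and the sort tie-break in [sort_table()].
#'
#' @param dataset_id Dataset identifier.
#' @param samples List of `sample_record`s (non-empty, unique names).
#' @param atlas_mode If `TRUE`, relative expression uses the median RPKM
#'   across all samples as the control reference.
#' @return An object of class `compendium`.
#' @export
compendium <- function(dataset_id, samples, atlas_mode = FALSE) {
  if (length(samples) == 0L) stop("a compendium needs at least one sample")
  stopifnot(all(vapply(samples, inherits, logical(1), "sample_record")))
  nms <- vapply(samples, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop("duplicate sample name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  names(samples) <- nms
  structure(
    list(dataset_id = dataset_id, atlas_mode = isTRUE(atlas_mode),
         samples = samples),
    class = "compendium"
  )
}

#' @export
print.compendium <- function(x, ...) {
  cat("compendium '", x$dataset_id, "': ", length(x$samples), " sample(s)",
      if (x$atlas_mode) ", atlas (median-as-control) mode", "\n", sep = "")
  invisible(x)
}

.split_names <- function(s) {
  if (is.na(s) || !nzchar(s)) character() else trimws(strsplit(s, ",")[[1L]])
}

#' Read a compendium configuration
#'
#' Parses the extended annots.xml-dialect file. Unknown `<file>` attributes
#' are preserved on each record for lossless round-tripping. Control names
#' are validated against the sample set: a dangling reference is dropped
#' with a warning (the record is kept).
#'
#' @param path Path to the XML configuration.
#' @return A [compendium()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  doc <- xml2::read_xml(path)   # malformed XML: xml2 error carries the line
  root <- xml2::xml_name(doc)
  if (root != "files") stop("expected <files> root element, found <", root, ">")
  dataset_id <- xml2::xml_attr(doc, "dataset_id")
  if (is.na(dataset_id)) dataset_id <- ""
  atlas_mode <- tolower(xml2::xml_attr(doc, "atlas_mode")) %in% c("true", "1", "yes")

  samples <- lapply(xml2::xml_find_all(doc, "./file"), function(node) {
    at <- xml2::xml_attrs(node)
    get1 <- function(k, default = "") if (k %in% names(at)) at[[k]] else default
    extra <- at[setdiff(names(at), .sample_attrs)]
    sample_record(
      name = get1("name"), bam_url = get1("bam_url"),
      title = get1("title"), description = get1("description"),
      sra_id = get1("sra_id"),
      total_reads_mapped = get1("total_reads_mapped", NA),
      read_map_method = get1("read_map_method"),
      svg_part = get1("svg_part"), svg_subpart = get1("svg_subpart"),
      color = get1("color"), url = get1("url"),
      controls = .split_names(get1("controls")),
      replicate_controls = .split_names(get1("replicate_controls")),
      extra = extra
    )
  })
  comp <- compendium(dataset_id, samples, atlas_mode = atlas_mode)

  all_names <- names(comp$samples)
  comp$samples <- lapply(comp$samples, function(s) {
    for (fld in c("controls", "replicate_controls")) {
      dangling <- setdiff(s[[fld]], all_names)
      if (length(dangling)) {
        warning("sample '", s$name, "': dropping dangling ", fld,
                " reference(s): ", paste(dangling, collapse = ", "))
        s[[fld]] <- intersect(s[[fld]], all_names)
      }
    }
    s
  })
  names(comp$samples) <- all_names
  comp
}

#' Write a compendium configuration
#'
#' Emits the extended annots.xml dialect with a deterministic attribute
#' order: the canonical fields first (empty strings included, never
#' omitted), then any preserved unknown attributes sorted by name.
#' `read_config(write_config(x))` is attribute-equal to `x`.
#'
#' @param comp A [compendium()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(comp, path) {
  stopifnot(inherits(comp, "compendium"))
  doc <- xml2::xml_new_root("files",
                            dataset_id = comp$dataset_id,
                            atlas_mode = if (comp$atlas_mode) "true" else "false")
  for (s in comp$samples) {
    at <- c(name = s$name, bam_url = s$bam_url, title = s$title,
            description = s$description, sra_id = s$sra_id,
            total_reads_mapped = as.character(s$total_reads_mapped),
            read_map_method = s$read_map_method,
            svg_part = s$svg_part, svg_subpart = s$svg_subpart,
            color = s$color, url = s$url,
            controls = paste(s$controls, collapse = ","),
            replicate_controls = paste(s$replicate_controls, collapse = ","))
    if (length(s$extra)) at <- c(at, s$extra[order(names(s$extra))])
    node <- xml2::xml_add_child(doc, "file")
    do.call(xml2::xml_set_attrs, list(node, at))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Resolve the control RPKM values for a sample
#'
#' In atlas mode, every sample's RPKM is returned (the median is applied by
#' [relative_expression()]); otherwise the RPKMs of the union of the
#' sample's `controls` and `replicate_controls`. A non-atlas sample with no
#' resolvable control yields an empty vector with a warning, and its
#' relative value stays undefined.
#'
#' @param comp A [compendium()].
#' @param sample A `sample_record` (or a sample name in `comp`).
#' @param rpkms Named numeric vector of RPKM per sample name, covering every
#'   referenced control (all samples in atlas mode).
#' @return Numeric vector of control RPKMs.
#' @export
resolve_controls <- function(comp, sample, rpkms) {
  stopifnot(inherits(comp, "compendium"))
  if (is.character(sample)) sample <- comp$samples[[sample]]
  stopifnot(inherits(sample, "sample_record"))
  if (comp$atlas_mode) {
    missing <- setdiff(names(comp$samples), names(rpkms))
    if (length(missing)) {
      stop("atlas mode: rpkms missing for sample(s): ",
           paste(missing, collapse = ", "))
    }
    return(unname(rpkms[names(comp$samples)]))
  }
  ctrl <- union(sample$controls, sample$replicate_controls)
  ctrl <- ctrl[ctrl %in% names(rpkms)]
  if (length(ctrl) == 0L) {
    warning("sample '", sample$name,
            "' has no resolvable controls; relative value undefined")
    return(numeric())
  }
  unname(rpkms[ctrl])
}
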