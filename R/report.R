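#' @title Result tables: assemble, sort, filter, export
#' @name report-module
#' @description One row per sample of a compendium, scoring a gene of
#'   interest: read count, absolute/relative RPKM and the point-biserial
#'   congruency to every splice variant — the sortable/filterable table at
#'   the heart of the browser workflow.
NULL

#' Build the per-sample result table for a gene
#'
#' Runs the full engine over a compendium: per sample, pileup over the gene
#' span, read count, total-mapped resolution (the configuration's
#' `total_reads_mapped` overrides a BAM scan), point-biserial score for
#' every variant and absolute RPKM for the selected variant. In relative
#' mode, once all samples' RPKMs are known, each sample's control reference
#' is resolved ([resolve_controls()]) and the log2 ratio computed. A sample
#' whose BAM cannot be read yields a row flagged `failed` with the reason;
#' the table is still returned.
#'
#' @param gene A [gene_model()].
#' @param comp A [compendium()].
#' @param selected_variant Variant ID (default: first variant of the gene).
#' @param mode `"absolute"` or `"relative"`.
#' @return A `result_table`: list with `gene_id`, `selected_variant`,
#'   `mode`, `variant_ids`, `rows` (list of row records), `sort_key`,
#'   `sort_direction`.
#' @export
build_table <- function(gene, comp,
                        selected_variant = names(gene$variants)[1L],
                        mode = c("absolute", "relative")) {
  mode <- match.arg(mode)
  stopifnot(inherits(gene, "gene_model"), inherits(comp, "compendium"))
  if (!selected_variant %in% names(gene$variants)) {
    stop("unknown variant '", selected_variant, "' for gene ", gene$gene_id)
  }
  rows <- vector("list", length(comp$samples))
  for (i in seq_along(comp$samples)) {
    s <- comp$samples[[i]]
    t0 <- proc.time()[["elapsed"]]
    row <- tryCatch({
      track <- pileup(s$bam_url, gene$span, sample_id = s$name)
      tm <- total_mapped(s$bam_url, override = s$total_reads_mapped)
      summ <- summarize_sample(track, gene, tm,
                               selected_variant = selected_variant)
      list(sample = s, summary = summ, status = "ok", reason = "",
           config_index = i)
    }, error = function(e) {
      list(sample = s, summary = NULL, status = "failed",
           reason = conditionMessage(e), config_index = i)
    })
    message(sprintf("sample %s: %s (%.2fs)", s$name, row$status,
                    proc.time()[["elapsed"]] - t0))
    rows[[i]] <- row
  }
  if (mode == "relative") {
    ok <- vapply(rows, function(r) identical(r$status, "ok"), logical(1))
    rpkms <- vapply(rows[ok], function(r) r$summary$rpkm_absolute, numeric(1))
    names(rpkms) <- vapply(rows[ok], function(r) r$sample$name, character(1))
    for (i in which(ok)) {
      ctrl <- if (comp$atlas_mode) {
        unname(rpkms)   # median-as-control: all (computable) samples
      } else {
        resolve_controls(comp, rows[[i]]$sample, rpkms)
      }
      rows[[i]]$summary$rpkm_relative <-
        if (length(ctrl) == 0L) NaN else
          relative_expression(rows[[i]]$summary$rpkm_absolute, ctrl,
                              atlas_mode = comp$atlas_mode)
    }
  }
  structure(
    list(gene_id = gene$gene_id, selected_variant = selected_variant,
         mode = mode, variant_ids = names(gene$variants), rows = rows,
         sort_key = "config_order", sort_direction = "asc"),
    class = "result_table"
  )
}

#' @export
print.result_table <- function(x, ...) {
  cat("result_table for gene ", x$gene_id, " (variant ", x$selected_variant,
      ", ", x$mode, " mode): ", length(x$rows), " row(s), sorted by ",
      x$sort_key, " ", x$sort_direction, "\n", sep = "")
  print(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

# Numeric sort value of each row under a key; undefined -> NA.
.row_values <- function(t, key) {
  vapply(t$rows, function(r) {
    if (is.null(r$summary)) return(NA_real_)
    v <- switch(key,
                rpkm = if (t$mode == "relative") r$summary$rpkm_relative
                       else r$summary$rpkm_absolute,
                rpb = r$summary$rpb_by_variant[[t$selected_variant]],
                stop("unknown sort key: ", key))
    if (is.nan(v)) NA_real_ else v
  }, numeric(1))
}

#' Sort a result table
#'
#' Stable sort on the RPKM column (absolute or relative per the table's
#' mode) or on the selected variant's point-biserial score. Ties are broken
#' by configuration order, and undefined values (failed rows, `NaN` scores)
#' are placed last regardless of direction. Sorting on decreasing
#' \eqn{r_{pb}} is the workflow for spotting the samples most congruent with
#' a splice variant.
#'
#' @param t A `result_table`.
#' @param key `"rpkm"` or `"rpb"`.
#' @param direction `"desc"` (default) or `"asc"`.
#' @return The reordered `result_table`.
#' @export
sort_table <- function(t, key = c("rpkm", "rpb"),
                       direction = c("desc", "asc")) {
  stopifnot(inherits(t, "result_table"))
  key <- match.arg(key); direction <- match.arg(direction)
  v <- .row_values(t, key)
  cfg <- vapply(t$rows, `[[`, numeric(1), "config_index")
  ord <- order(v, cfg, na.last = TRUE, method = "radix",
               decreasing = c(direction == "desc", FALSE))
  t$rows <- t$rows[ord]
  t$sort_key <- key
  t$sort_direction <- direction
  t
}

#' Filter a result table by keyword
#'
#' Keeps rows whose title or description contains `keyword`
#' (case-insensitive substring); relative order is preserved. An empty
#' keyword is the identity.
#'
#' @param t A `result_table`.
#' @param keyword Search text.
#' @return The filtered `result_table`.
#' @export
filter_table <- function(t, keyword) {
  stopifnot(inherits(t, "result_table"))
  if (!nzchar(keyword)) return(t)
  kw <- tolower(keyword)
  keep <- vapply(t$rows, function(r) {
    grepl(kw, tolower(r$sample$title), fixed = TRUE) ||
      grepl(kw, tolower(r$sample$description), fixed = TRUE)
  }, logical(1))
  t$rows <- t$rows[keep]
  t
}

#' @export
as.data.frame.result_table <- function(x, ...) {
  vids <- x$variant_ids
  rows <- x$rows
  chr <- function(f) vapply(rows, function(r) f(r), character(1))
  num <- function(f) {
    v <- vapply(rows, function(r)
      if (is.null(r$summary)) NA_real_ else as.numeric(f(r$summary)),
      numeric(1))
    v[is.nan(v)] <- NA_real_
    v
  }
  df <- data.frame(
    sample = chr(function(r) r$sample$name),
    title = chr(function(r) r$sample$title),
    sra_id = chr(function(r) r$sample$sra_id),
    reads_in_region = num(function(s) s$reads_in_region),
    rpkm_absolute = num(function(s) s$rpkm_absolute),
    rpkm_relative = num(function(s) s$rpkm_relative),
    stringsAsFactors = FALSE
  )
  for (vid in vids) {
    df[[paste0("rpb_", vid)]] <-
      num(function(s) s$rpb_by_variant[[vid]])
  }
  df$status <- chr(function(r)
    if (r$status == "ok") "ok" else paste0("failed: ", r$reason))
  df
}

#' Export a result table
#'
#' Writes one record per row (sample name, title, SRA id, read count,
#' absolute and relative RPKM, \eqn{r_{pb}} per variant, status). Numbers
#' are fixed at 6 significant digits; undefined values become empty fields
#' (tsv/csv) or `null` (json). Failed rows are exported with their failure
#' reason in the `status` column, never silently dropped.
#'
#' @param t A `result_table`.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_table <- function(t, format = c("tsv", "csv", "json"), path) {
  stopifnot(inherits(t, "result_table"))
  format <- match.arg(format)
  df <- as.data.frame(t)
  is_num <- vapply(df, is.numeric, logical(1))
  df[is_num] <- lapply(df[is_num], signif, digits = 6L)
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                         digits = NA, auto_unbox = TRUE, pretty = TRUE)
  } else {
    out <- df
    out[is_num] <- lapply(out[is_num], function(v) {
      s <- vapply(v, function(x)
        if (is.na(x)) "" else format(x, scientific = FALSE, trim = TRUE),
        character(1))
      s
    })
    utils::write.table(out, path, sep = if (format == "tsv") "\t" else ",",
                       quote = format == "csv", row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Construct an expression color scale
#'
#' @param mode `"absolute"` (yellow-to-red over `[0, max]`) or `"relative"`
#'   (blue-yellow-red over `[-max, +max]`, yellow at 0).
#' @param max Positive ceiling: the maximum RPKM (absolute mode) or the
#'   symmetric log2-ratio bound (relative mode).
#' @return An object of class `efp_scale`.
#' @export
efp_scale <- function(mode = c("absolute", "relative"), max) {
  mode <- match.arg(mode)
  if (!is.finite(max) || max <= 0) stop("scale max must be positive")
  structure(list(mode = mode, max = max), class = "efp_scale")
}

#' Default color scale for a result table
#'
#' Absolute mode: ceiling at the table's maximum RPKM. Relative mode:
#' symmetric bound at the largest absolute log2 ratio, keeping 0 at yellow.
#'
#' @param t A `result_table`.
#' @return An [efp_scale()], or `NULL` when no value is defined.
#' @export
table_scale <- function(t) {
  v <- .row_values(t, "rpkm")
  if (all(is.na(v))) return(NULL)
  m <- if (t$mode == "relative") max(abs(v), na.rm = TRUE)
       else max(v, na.rm = TRUE)
  if (m <= 0) m <- 1
  efp_scale(t$mode, m)
}

.lerp_channel <- function(a, b, f) as.integer(round(a + (b - a) * f))

#' Map an expression value to a pictograph color
#'
#' Absolute mode: linear interpolation yellow `#FFFF00` to red `#FF0000`
#' over `[0, max]`, clamped. Relative mode: blue `#0000FF` to yellow over
#' `[-max, 0]` and yellow to red over `[0, +max]`, clamped. Undefined
#' values map to grey `#D3D3D3`.
#'
#' @param value Numeric vector of expression values (`NA`/`NaN` allowed).
#' @param scale An [efp_scale()].
#' @return Character vector of `#RRGGBB` colors.
#' @examples
#' sc <- efp_scale("relative", 2)
#' efp_color(c(-2, 0, 2, NA), sc)
#' @export
efp_color <- function(value, scale) {
  stopifnot(inherits(scale, "efp_scale"))
  vapply(value, function(v) {
    if (is.na(v)) return("#D3D3D3")
    if (scale$mode == "absolute") {
      f <- min(max(v / scale$max, 0), 1)
      sprintf("#%02X%02X%02X", 255L, .lerp_channel(255, 0, f), 0L)
    } else if (v < 0) {
      f <- min(-v / scale$max, 1)          # yellow -> blue going negative
      sprintf("#%02X%02X%02X", .lerp_channel(255, 0, f),
              .lerp_channel(255, 0, f), .lerp_channel(0, 255, f))
    } else {
      f <- min(v / scale$max, 1)           # yellow -> red going positive
      sprintf("#%02X%02X%02X", 255L, .lerp_channel(255, 0, f), 0L)
    }
  }, character(1))
}
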