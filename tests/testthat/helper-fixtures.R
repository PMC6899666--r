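# In-code fixtures shared across test files.

# A simulated single-sample fixture: gene + GFF3 + SAM/BAM for one mixture.
sim_fixture <- function(seed = 1, archetype = "skip", mixture = NULL,
                        depth = 20, n_unmapped = 0, dir = withr::local_tempdir(
                          .local_envir = parent.frame())) {
  spec <- sim_spec(seed = seed, archetype = archetype, mixture = mixture,
                   depth = depth, n_unmapped = n_unmapped)
  gff <- file.path(dir, "gene.gff3")
  gene <- make_gene(spec, gff_path = gff)
  sim <- simulate_reads(gene, spec, file.path(dir, "sample"))
  list(spec = spec, gene = gene, gff = gff, sim = sim, dir = dir)
}

# A synthetic result_table with randomized values (ties and NaNs included),
# built directly from the row structure — no BAMs involved.
random_table <- function(n, seed) {
  set.seed(seed)
  titles <- c("heat stress leaf", "control root", "drought flower",
              "heat stress root", "cold shoot apex", "control leaf")
  rows <- lapply(seq_len(n), function(i) {
    s <- sample_record(name = sprintf("s%03d", i), bam_url = "none",
                       total_reads_mapped = 1e6,
                       title = sample(titles, 1L),
                       description = sample(c("seedling", "mature", ""), 1L))
    rpb <- round(stats::runif(2L), 1L)      # coarse values: ties are common
    if (stats::runif(1L) < 0.1) rpb[] <- NaN
    summ <- structure(
      list(sample_id = s$name, gene_id = "g", selected_variant = "v1",
           reads_in_region = stats::rpois(1L, 100),
           rpkm_absolute = round(stats::runif(1L, 0, 50), 1L),
           rpkm_relative = NaN,
           rpb_by_variant = c(v1 = rpb[1L], v2 = rpb[2L])),
      class = "expression_summary")
    list(sample = s, summary = summ, status = "ok", reason = "",
         config_index = i)
  })
  structure(
    list(gene_id = "g", selected_variant = "v1", mode = "absolute",
         variant_ids = c("v1", "v2"), rows = rows,
         sort_key = "config_order", sort_direction = "asc"),
    class = "result_table")
}

table_names <- function(t) vapply(t$rows, function(r) r$sample$name, "")

# A small hand-wired compendium config file; returns its path.
write_fixture_config <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<files dataset_id="demo" atlas_mode="false">',
    '  <file name="s1" bam_url="s1.bam" title="Aerial rosette" description="21 d" sra_id="SRR000001" total_reads_mapped="1000000" read_map_method="sim" svg_part="leaf" svg_subpart="" color="#00FF00" url="" controls="s2" replicate_controls="" custom_note="kept"/>',
    '  <file name="s2" bam_url="s2.bam" title="Root" description="" sra_id="" total_reads_mapped="2000000" read_map_method="sim" svg_part="root" svg_subpart="tip" color="#0000FF" url="" controls="s1,s2" replicate_controls=""/>',
    '</files>'), path)
  path
}
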