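test_that("archetype gene models realize the advertised splicing events", {
  g_skip <- make_gene(sim_spec(archetype = "skip"))
  expect_length(g_skip$variants[[1]]$exons, 3L)
  expect_length(g_skip$variants[[2]]$exons, 2L)
  # retained intron: v2's exon union exceeds v1's by exactly the first intron
  g_ret <- make_gene(sim_spec(archetype = "retention"))
  u1 <- g_ret$variants[[1]]$exons
  u2 <- g_ret$variants[[2]]$exons
  extra <- IRanges::setdiff(u2, u1)
  expect_length(extra, 1L)
  expect_equal(IRanges::start(extra), IRanges::end(u1)[1] + 1L)
  expect_equal(IRanges::end(extra), IRanges::start(u1)[2] - 1L)
  # neither variant's exon mask is constant over the union span
  for (v in g_ret$variants) {
    m <- build_exon_mask(v, g_ret$span)$values
    expect_true(any(m == 0) && any(m == 1))
  }
  # alternative acceptor: second exon of v2 starts upstream
  g_acc <- make_gene(sim_spec(archetype = "acceptor"))
  expect_lt(IRanges::start(g_acc$variants[[2]]$exons)[2],
            IRanges::start(g_acc$variants[[1]]$exons)[2])
  # distinguishing regions of at least 50 bp in every archetype
  for (g in list(g_skip, g_ret, g_acc)) {
    m1 <- build_exon_mask(g$variants[[1]], g$span)$values
    m2 <- build_exon_mask(g$variants[[2]], g$span)$values
    expect_gte(sum(m1 != m2), 50)
  }
})

test_that("generated GFF3 and SAM are deterministic and round-trip", {
  dir <- withr::local_tempdir()
  spec <- sim_spec(seed = 77, archetype = "acceptor", mixture = c(g1.1 = 1))
  g1p <- file.path(dir, "a.gff3"); g2p <- file.path(dir, "b.gff3")
  gene <- make_gene(spec, gff_path = g1p)
  make_gene(spec, gff_path = g2p)
  expect_identical(readLines(g1p), readLines(g2p))
  s1 <- simulate_reads(gene, spec, file.path(dir, "s1"))
  s2 <- simulate_reads(gene, spec, file.path(dir, "s2"))
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  # GFF3 re-parsed by the annotation module equals the in-memory model
  reparsed <- parse_gff(g1p)[[spec$gene_id]]
  expect_equal(reparsed$variants, gene$variants)
  expect_equal(GenomicRanges::start(reparsed$span), GenomicRanges::start(gene$span))
})

test_that("pure-mixture reads land only in the generating variant's exons", {
  fx <- sim_fixture(seed = 14, archetype = "skip", mixture = c(g1.1 = 1),
                    depth = 30)
  g <- fx$gene
  tr <- pileup(fx$sim$bam, g$span)
  m1 <- build_exon_mask(g$variants$g1.1, g$span)$values
  expect_true(all(tr$depth[m1 == 0] == 0))
  # mean exonic depth close to the 30x target, intronic depth zero
  expect_equal(mean(tr$depth[m1 == 1]), 30, tolerance = 0.2)
})

test_that("ground truth is conserved and mixtures are sampled binomially", {
  fx <- sim_fixture(seed = 15, archetype = "skip",
                    mixture = c(g1.1 = 0.5, g1.2 = 0.5), depth = 30,
                    n_unmapped = 3)
  gt <- fx$sim$ground_truth
  rec <- read_sam_records(fx$sim$sam)
  mapped <- rec[.keep_primary(rec$flag), ]
  expect_equal(sum(gt$read_counts), nrow(mapped))
  expect_equal(gt$total_mapped, nrow(mapped))
  expect_equal(total_mapped(fx$sim$bam), gt$total_mapped)
  expect_equal(sum(!.keep_primary(rec$flag)), 3L)
  # per-read variant labels in the SAM agree with the recorded counts
  lab <- sub("^r[0-9]+_", "", mapped$qname)
  expect_equal(as.vector(table(lab)[names(gt$read_counts)]),
               unname(gt$read_counts))
  # 99% binomial bounds around 50/50
  n <- sum(gt$read_counts)
  bounds <- stats::qbinom(c(0.005, 0.995), n, 0.5)
  expect_gte(gt$read_counts[["g1.1"]], bounds[1])
  expect_lte(gt$read_counts[["g1.1"]], bounds[2])
})

test_that("zero depth yields an empty but valid BAM", {
  fx <- sim_fixture(seed = 16, archetype = "skip", mixture = c(g1.1 = 1),
                    depth = 0)
  expect_equal(total_mapped(fx$sim$bam), 0L)
  tr <- pileup(fx$sim$bam, fx$gene$span)
  expect_true(all(tr$depth == 0L))
})

test_that("make_compendium wires controls and is readable by the config module", {
  dir <- withr::local_tempdir()
  samples <- list(
    list(name = "a", mixture = c(g1.1 = 1), controls = "a"),
    list(name = "b", mixture = c(g1.2 = 1), controls = "a"),
    list(name = "c", mixture = c(g1.1 = 0.5, g1.2 = 0.5), controls = "a",
         replicate_controls = "b"))
  spec <- sim_spec(seed = 18, archetype = "retention", samples = samples)
  cp <- make_compendium(spec, dir)
  comp <- read_config(cp$config_path)
  expect_named(comp$samples, c("a", "b", "c"))
  expect_equal(comp$samples$c$replicate_controls, "b")
  for (nm in names(comp$samples)) {
    expect_equal(comp$samples[[nm]]$total_reads_mapped,
                 cp$ground_truth[[nm]]$total_mapped)
    expect_true(file.exists(comp$samples[[nm]]$bam_url))
  }
  dup <- spec; dup$samples[[2]]$name <- "a"
  expect_error(make_compendium(dup, file.path(dir, "dup")), "duplicate")
})
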