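---
title: "Scoring splice-variant congruency from RNA-seq coverage"
author: "splicecov"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring splice-variant congruency from RNA-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecov)
```

## The problem

Given a compendium of RNA-seq samples (each an indexed BAM file plus
metadata) and a gene of interest with several annotated splice variants,
two questions recur constantly in expression-atlas exploration:

1. *Where is this gene expressed, and how strongly?*
2. *In which samples does the read pileup disagree with the reference
   splice variant — i.e. where might alternative splicing be happening?*

splicecov answers both headlessly: it computes, for every sample, the
gene-level read count, absolute and control-relative RPKM, and a
per-variant *congruency score*, and assembles them into a sortable,
filterable, exportable table with accompanying coverage and gene-structure
plots.

## The congruency score

For one sample and one splice variant, two vectors of identical length
(the number of nucleotides in the gene span) are compared:

* the **coverage vector** $x$ — the number of reads aligned over each
  nucleotide (splice-aware: a read's intron gap contributes nothing);
* the **exon mask** $m$ — a dichotomous vector, 1 where the nucleotide is
  inside an exon of the variant, 0 elsewhere.

Their association is the point-biserial correlation

$$
r_{pb} \;=\; \frac{M_1 - M_0}{s}\,\sqrt{\frac{n_1 n_0}{n^2}},
$$

where $M_1$, $M_0$ are the mean depths over mask-1 and mask-0 positions,
$n_1$, $n_0$ the class sizes, $n = n_1 + n_0$, and $s$ the population
standard deviation of $x$. This is algebraically the Pearson correlation
of $x$ with the 0/1 mask (a property the test suite verifies against an
independent Pearson implementation to $10^{-12}$), so $r_{pb} \in [-1, 1]$
and it is invariant under positive rescaling of the coverage — only the
*shape* of the pileup matters, not the sequencing depth. A value near 1
means reads fall where that variant has exons and nowhere else; ranking
samples by $r_{pb}$, or variants within a sample, surfaces candidate
alternative-splicing events.

**Which standard deviation?** The population ($n$-denominator) form is
used. Since the score equals a Pearson correlation when both vectors use
the same convention, the choice cancels and rankings are unaffected.

**Undefined scores.** When either vector is constant — uniform or all-zero
coverage, or a mask that is all ones or all zeros — the correlation does
not exist. Such scores are `NaN`, rendered grey in color output, exported
as empty/`null` fields, and sorted after all defined values regardless of
sort direction, so degenerate samples remain visible but never contaminate
a ranking.

**The gene span.** All variants of a gene are scored over the *union* span
of every variant's exons, so every mask and coverage vector for a gene has
the same length and scores are comparable across variants. The
per-variant-span alternative would change individual values slightly but
requires re-extracting coverage per variant and breaks cross-variant
comparison on a single track; the union convention is therefore used
throughout. One consequence is worth knowing: a variant whose exons cover
the entire union span (e.g. a transcript retaining *every* intron) has a
constant mask and an undefined score.

## Expression summaries

**Absolute RPKM.** Reads per kilobase of exon per million mapped reads:
$\mathrm{RPKM} = 10^9 \cdot \mathrm{reads} / (L \cdot N)$ with $L$ the
*selected variant's* exonic length (nt) and $N$ the sample's total mapped
reads. The numerator counts primary alignments with at least one aligned
base in the gene's full genomic span — introns included. This mixed
convention (span-based numerator, exon-based denominator) mirrors how the
counts are obtained from a samtools-view-style regional query, and is
implemented verbatim and deliberately; it slightly inflates RPKM for genes
with substantial intronic signal.

**Relative mode.** $\log_2(\mathrm{RPKM}_{\mathrm{sample}} /
\overline{\mathrm{RPKM}}_{\mathrm{controls}})$, the controls being named
per sample in the compendium configuration; $-2$ means a four-fold
decrease. Datasets without designated controls (developmental atlases) set
the dataset-level `atlas_mode` flag, and the reference becomes the
*median* RPKM across all samples. The flag is declarative in the XML, not
inferred. Zero sample RPKM or a zero reference leaves the value undefined
rather than $\pm\infty$.

## Reading the data

* **Annotation** comes from local GFF3 with `gene`/`mRNA`/`exon`/`CDS`/
  `five_prime_UTR`/`three_prime_UTR` records linked by `ID`/`Parent`.
  Unknown feature types and orphan records are skipped with warnings;
  UTR-covered exon portions count as exon in the mask (coverage includes
  UTR reads). Overlapping exon records of one variant are merged — the
  mask is dichotomous.
* **Coordinates** are 1-based closed throughout, the Bioconductor
  (IRanges/GRanges) convention shared by every I/O layer used; GFF3 and
  BAM conversions happen inside rtracklayer/Rsamtools, so no manual
  off-by-one handling exists anywhere in the package.
* **Alignments**: unmapped, secondary (0x100) and supplementary (0x800)
  records are excluded; duplicates and QC-fail reads are kept; no
  mapping-quality threshold and no depth cap. These permissive,
  samtools-like defaults are a documented choice. CIGAR M/=/X and D count
  as covering a position; N (intron skip) does not — the standard
  treatment of spliced RNA-seq alignments. Strand is carried but ignored:
  unstranded libraries are assumed.
* **Total mapped reads** for the RPKM denominator comes from the
  configuration's `total_reads_mapped` field when present (the curated
  value), else from a whole-file count of primary mapped records.

## The compendium configuration

Samples are listed in an extended annots.xml-style document:
`<files dataset_id atlas_mode>` wrapping one `<file/>` element per sample
with attributes `name bam_url title description sra_id total_reads_mapped
read_map_method svg_part svg_subpart color url controls
replicate_controls` (control lists comma-separated). Unknown attributes
are preserved on read and re-emitted on write, and the writer uses a fixed
attribute order, so read–write round-trips are attribute-identical.
Dangling control references are dropped with a warning; the union of
`controls` and `replicate_controls` feeds the relative-mode reference.

## The simulator

Every statistic above is testable offline because the `simdata` functions
generate the full input stack — GFF3, coordinate-sorted indexed BAM, and
configuration XML — from a seed, with complete ground truth (true mixture,
per-variant read counts, totals).

Three two-variant archetypes cover the classic event classes, each with a
distinguishing region of at least 50 bp: a **skipped exon** (200 bp
cassette), a **retained intron** (150 bp; the retaining variant keeps a
second, spliced intron so neither mask is constant — see the union-span
caveat above), and an **alternative acceptor** (100 bp exon extension).
Genes are ~1.2–2.1 kb on a toy chromosome. Reads are single-end, 50 nt,
drawn by sampling a variant from the mixture (multinomial) and a start
position uniform over that variant's transcript; genomic CIGARs carry N
operations across introns. Read number targets a mean exonic coverage
(default 20×): $\mathrm{reads} = \mathrm{depth} \times \sum_v p_v L_v /
\ell$. Bases are placeholder `A`s — nothing downstream reads base
identities, base qualities or pairing, so none are modelled.

What the simulator deliberately does **not** emulate: sequencing errors
and mapping ambiguity, positional/GC bias, fragment-length effects,
paired-end structure, strandedness, multi-gene backgrounds (each BAM
contains one locus, so a sample's `total_reads_mapped` is the locus read
count and absolute RPKMs are unrealistically large — ratios and rankings,
which is what the engine computes, are unaffected). Passing tests
therefore demonstrate the *engine's* correctness on idealized spliced
alignments, not robustness to alignment artefacts in real data.

### Chosen study conditions

Test problem sizes are the package's own choices, made once:

* Variant-recovery checks use pure single-variant samples at 20× coverage
  across 20 seeded replicates of the three archetypes; the generating
  variant must win the score ranking in at least 19.
* The six-sample mixture course (variant-2 proportion 0, 0.2, …, 1) uses
  200× coverage. The expected $r_{pb}$(v2) curve is strictly increasing
  but saturates near the pure-v2 end, so the smallest expected step is a
  few hundredths; the course depth was chosen by a replicate power
  analysis so that every successive step clears the coverage-sampling
  noise with several standard deviations of margin, making strict
  monotonicity a reliable property rather than a coin flip. 200× is
  unremarkable for a moderately expressed gene in a deep bulk compendium.
* Oracle-equivalence checks (pileup and read counting against brute-force
  per-base counting over the SAM text) run on every simulated fixture and
  are exact, not approximate.

## Rendering and color

Coverage profiles are filled step plots normalized per track to the
track's own maximum depth (annotated as text), so profile *shapes* are
comparable across samples of very different depths — two tracks differing
only by a scale factor render identically apart from the label. Gene
structures draw exons dark green with UTR portions light green (the
NCBI-style scheme) and introns as thin connectors, x-aligned with the
coverage plot. Both renderers write PNG (cairo) or SVG by file extension.

Expression-to-color mapping uses linear RGB interpolation: absolute mode
yellow `#FFFF00` → red `#FF0000` over $[0, \mathrm{max}]$; relative mode
blue `#0000FF` → yellow over $[-\mathrm{max}, 0]$ and yellow → red over
$[0, \mathrm{max}]$, clamped at the ends, grey `#D3D3D3` for undefined.
The default ceilings are the table's maximum RPKM (absolute) and the
largest $|\log_2|$ ratio (relative, symmetric so 0 stays yellow). The hex
endpoints and clamping are this package's documented conventions; upstream
descriptions of such scales name the colors but not the arithmetic.

## Worked example

```{r example, eval = FALSE}
dir <- tempfile(); dir.create(dir)
samples <- lapply(0:3, function(k) list(
  name = sprintf("s%d", k),
  mixture = c(g1.1 = 1 - k / 3, g1.2 = k / 3),
  title = sprintf("heat stress %d min", 15 * k),
  controls = "s0"))
cp <- make_compendium(sim_spec(seed = 7, archetype = "skip", depth = 25,
                               samples = samples), dir)
gene <- parse_gff(cp$gff_path)[["g1"]]
tb <- build_table(gene, cp$compendium, selected_variant = "g1.2",
                  mode = "relative")
as.data.frame(sort_table(tb, "rpb", "desc"))
```

The `rpb_g1.2` column rises with the simulated variant-2 fraction, and
sorting on it puts the most v2-congruent samples first — the workflow for
spotting condition-dependent splicing, here under a known ground truth.

## Limitations

* The score compares one continuous and one dichotomous vector; it cannot
  deconvolve a mixture into proportions, only rank congruence. Mixtures of
  similar variants compress the score range.
* RPKM-based relative values are indicative, not inferential; calling
  differential expression properly requires count-based models with
  dispersion estimation, which is explicitly out of scope here.
* Scores weight every nucleotide equally, so long shared exons dilute
  short distinguishing regions; very similar isoforms need deep coverage
  to separate.
* Local files only: no remote BAM access; annotation from local GFF3 only.
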