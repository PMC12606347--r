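---
title: "Allele-specific expression from spliced long reads: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific expression from spliced long reads: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aselong)
library(dplyr)
```

## The problem

In an F1 hybrid between two inbred strains, hundreds of thousands of exonic
single-nucleotide variants distinguish the parental chromosomes. A spliced
long read that covers even one such phased SNV can be assigned to the
maternal or paternal haplotype directly, without the haplotype-block
reconstruction that short reads require. `aselong` implements this analysis
as a set of tibble-in / tibble-out functions:

1. **Haplotagging** (`haplotag()`, `tag_read()`): assign each read to a
   parental allele by voting over the phased SNVs its alignment covers.
2. **Splitting** (`split_by_haplotype()`): partition alignments into
   maternal / paternal / untagged streams.
3. **Counting** (`count_alleles()`, `count_isoform_alleles()`): stranded,
   union-mode gene counting per stream, plus first-exon-anchored isoform
   counting for loci with overlapping isoforms of distinct allelic status.
4. **Classification** (`classify_alleles()`, `detect_escape()`): allelic
   ratios, a hard informativeness filter, maternal/paternal/biallelic
   categories, and X-inactivation escape calls under a skewed-XCI design.
5. **Concordance** (`concordance_report()`): compare two call tables
   (e.g. long-read vs short-read) for overlap, direction agreement and
   ratio correlation.

A synthetic F1-hybrid generator (`sim_config()`, `sim_genome()`,
`sim_reads()`) provides datasets with known allelic truth for validation.

## The model and its parameters

The **allelic ratio** of a feature is

$$r = \frac{n_\mathrm{maternal}}{n_\mathrm{maternal} + n_\mathrm{paternal}},$$

so $r = 1$ is fully maternal and $r = 0$ fully paternal; $r$ is undefined
(NA) when no tagged reads exist. Classification uses hard cutoffs
(`ase_thresholds()`), all configurable:

* `min_informative_reads` (default **10**; use **20** for short-read count
  tables): a feature is *informative* only if at least this many assigned
  reads overlap one or more SNVs. The unit is the read — a read covering
  three SNVs counts once. We compute this on gene-assigned reads, i.e.
  after union-mode ambiguity filtering; computing it before assignment
  would count reads that can never contribute to the ratio.
* `low_cut` / `high_cut` (defaults **0.3** / **0.7**): $r \ge 0.7$ is
  `MATERNAL`, $r \le 0.3$ `PATERNAL`, strictly between is `BIALLELIC`.
  The boundary values themselves are allele-specific, which the acceptance
  sweeps verify exactly.
* `xci_subject_ratio` (default **0.9**): under a skewed-XCI design with
  the maternal X active, informative X genes with active-allele ratio
  above 0.9 are `SUBJECT` to inactivation. Genes at or below `low_cut`
  show the inactive-X-only pattern of Xist (`INACTIVE_X_EXPRESSED`).
  Everything else with at least `min_inactive_reads` (default **2**)
  inactive-X reads is an `ESCAPE_CANDIDATE`. The two-read floor is our
  own guard against single-read noise: a lone mis-tagged or mismapped read
  should not nominate an escape gene. X genes between the cutoffs with
  fewer than two inactive reads receive an NA flag — the evidence supports
  neither call.

### Voting rule

A covered SNV votes maternal when the read base equals the maternal allele
(at base quality at least `min_base_quality`, default 0 because HiFi-grade
reads are ~Q40), paternal likewise; bases matching neither allele are
recorded as mismatches and never break ties. The read label is a simple
majority; ties — including zero coverage — stay untagged. Production
haplotaggers use likelihood models whose details are not portable; the
majority vote is deterministic, transparent, and exactly testable against
a per-base brute-force oracle, which the test suite does on 10,000 fuzzed
spliced alignments. Votes are pooled across primary and supplementary
records of a read; secondary alignments neither vote nor receive tags.

### Counting rules

Gene counting is **union-mode and stranded**: a read counts toward the set
of (strand-matched) genes whose merged exon union any aligned block
overlaps; only singleton sets are assigned, larger sets are discarded as
ambiguous. Strandedness is what keeps antisense gene pairs apart — an
imprinted gene inside the intron of a host gene on the opposite strand is
counted correctly where unstranded data cannot resolve it. Gene exon
unions are rebuilt from transcript structures rather than trusting gene
records in the GTF.

Isoform counting anchors each read at its 5' end: a read is attributed to
the unique transcript whose *first exon* contains the read's 5'-most
aligned base within `tss_tolerance` (default **50 bp**) and whose splice
chain is compatible with the read (all blocks inside the exon union, every
skipped intron matching a transcript intron within the tolerance). Reads
starting in shared 3' exons, or compatible with several transcripts, stay
unassigned rather than guessed. The 50 bp default absorbs small TSS
wobble while staying far below the spacing of alternative first exons at
loci like the one simulated here; the anchoring rule itself is our
formalisation of what is usually done by eye in genome browsers.

## The synthetic F1 hybrid

The generator emulates the essential features of a strain cross with
skewed X inactivation:

* three chromosomes (two autosomes and `chrX`) of 600 kb, 30 genes each,
  2–8 exons per gene — small enough for seconds-scale tests, large enough
  that class counts and the informativeness filter are exercised;
* phased exonic SNVs, Poisson with mean 2 per exon (maternal allele =
  reference base, paternal = alternate), mirroring dense strain catalogues;
* per-gene depth is negative-binomial (mean 100, dispersion 8), not fixed,
  so some genes legitimately fail the 10-read filter; no per-gene depth
  distribution is published for such data, so the negative binomial is an
  assumption, chosen as the field's default overdispersed count model;
* autosomal classes: 70% biallelic ($f_m = 0.5$), 10% each maternally /
  paternally imprinted ($f_m = 1$ / $0$), 5% each strain-biased
  ($f_m = 0.85$ / $0.15$) — bias strong enough to be called
  allele-specific, distinct from full imprinting;
* skewed XCI: non-escape X genes fully maternal, an Xist-like noncoding
  gene fully paternal, and two escape genes at $f_m = 0.67$, near the
  published escape-gene read proportions;
* one autosomal locus with four same-strand isoforms sharing three 3'
  exons but starting from distinct first exons, with statuses biallelic
  (weight 0.5), maternal-only (0.2), paternal-only (0.3) and silent (0) —
  the organisation of the Gnas imprinted cluster. (The real cluster also
  contains antisense transcripts; the generator models the allelic
  statuses on one strand and exercises antisense resolution with separate
  intronic antisense gene pairs.)
* reads are full-length transcripts emitted as already-aligned spliced
  records (exon-length match blocks, intron-length skips), with uniform
  per-base substitution errors (default 0).

What this deliberately does **not** model: HiFi chemistry error profiles,
5'/3' truncation, poly-A artifacts, multi-mapping and alignment error,
indels. Passing recovery tests therefore demonstrates correctness of the
tagging/counting/classification logic under known truth — not robustness
to mapping artifacts, which in real data are handled upstream by the
aligner and its unique-mapping filters.

## Worked example

```{r example}
cfg <- sim_config(seed = 101)
genome <- sim_genome(cfg)
reads <- sim_reads(genome)
tagged <- haplotag(reads$alignments, genome$variants)
attr(tagged, "summary")

counts <- count_alleles(tagged, genome$annotation, variants = genome$variants)
calls <- classify_alleles(counts)
glance(calls)
```

Every stage is a plain tibble, so the usual dplyr verbs work throughout:

```{r example2}
calls |>
  filter(informative, category != "BIALLELIC") |>
  arrange(ratio) |>
  select(gene_id, chrom, maternal, paternal, ratio, category) |>
  head()
```

Isoform-level allelic counts at the multi-isoform locus, and escape calls
on the X:

```{r example3}
count_isoform_alleles(tagged, genome$annotation, "gnasl")

detect_escape(calls, active_allele = "maternal") |>
  count(xci_flag)
```

Cross-platform concordance against an independently resampled,
higher-depth count table (standing in for a short-read pipeline's output,
classified with the 20-read filter):

```{r example4}
short <- classify_alleles(sim_count_table(genome, depth_mean = 500),
                          ase_thresholds(min_informative_reads = 20L))
concordance_report(calls, short)
```

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; conversion happens only at
  the VCF (1-based) and GTF (1-based closed) boundaries.
* An undefined ratio (zero tagged reads) is `NOT_INFORMATIVE`, never
  `BIALLELIC`.
* Duplicate VCF positions keep the first record with a warning;
  multi-allelic, indel, unphased and homozygous records are skipped and
  tallied in a load report.
* Chromosome names must match exactly between alignments, variants and
  annotation; counting errors out listing the offenders rather than
  silently dropping reads. Reads on chromosomes without variants are
  untagged with a warning.
* Pearson correlation in concordance reports uses the t-transform p-value
  on $n-2$ degrees of freedom; zero-variance input yields NA with a
  warning. The implementation delegates to `stats::cor.test()`; the test
  suite checks it against a two-pass covariance computation to 1e-12.
* Determinism: all simulation randomness flows from `sim_config()$seed`
  (genome and reads use distinct derived streams), so identical
  configurations produce byte-identical fixture files.

## Problem sizes used in validation

The shipped tests run the generator at its defaults (≈ 90 genes, ≈ 9,000
reads per run) plus targeted small configurations; oracle-equivalence
suites use 10,000 fuzzed spliced alignments against 1,500 variants.
These sizes give tight recovery checks (3-SE binomial bounds at depth
≥ 50) while keeping the whole suite in the minutes range on one core.

## Known limitations

* The voting tagger is not a likelihood model; at high error rates with
  few covered SNVs it will untag (ties) more often than a probabilistic
  tagger would rescue.
* Isoform anchoring requires distinct first exons; loci whose isoforms
  differ only internally are reported unassigned.
* Escape detection presumes the skewed-XCI design; in a balanced-XCI
  sample, inactive-X reads are not diagnostic and `detect_escape()` should
  not be applied.
* Statistical testing of allelic imbalance (binomial tests, FDR) is out of
  scope by design: classification follows the hard-cutoff scheme, whose
  boundary semantics are part of the contract.
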