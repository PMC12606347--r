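test_that("union-mode assignment follows strand and multiplicity rules", {
  ann <- toy_annotation()
  # fully inside gA's exons, same strand
  r1 <- toy_alignment("r1", 110, "50M")
  a1 <- assign_reads_to_genes(r1, ann)
  expect_equal(a1$status, "assigned")
  expect_equal(a1$gene_id, "gA")

  # '-' read over the '+' gene in stranded mode: no feature;
  # unstranded: assigned
  r2 <- toy_alignment("r2", 110, "50M", strand = "-")
  expect_equal(assign_reads_to_genes(r2, ann)$status, "no_feature")
  expect_equal(assign_reads_to_genes(r2, ann, stranded = FALSE)$status,
               "assigned")

  # spliced read touching both exons of gA stays a singleton
  r3 <- toy_alignment("r3", 100, "100M200N100M")
  expect_equal(assign_reads_to_genes(r3, ann)$gene_id, "gA")

  # read spanning gA and a same-strand second gene is ambiguous
  ann2 <- ase_annotation(dplyr::bind_rows(
    ann$tx_exons[, c("transcript_id", "gene_id", "chrom", "strand", "start", "end")],
    tibble::tibble(transcript_id = "tC", gene_id = "gC", chrom = "chr1",
                   strand = "+", start = 600L, end = 700L)
  ))
  r4 <- toy_alignment("r4", 450, "200M")
  expect_equal(assign_reads_to_genes(r4, ann2)$status, "ambiguous")

  # antisense overlap does not conflict when stranded
  r5 <- toy_alignment("r5", 1010, "50M", strand = "-")
  expect_equal(assign_reads_to_genes(r5, ann)$gene_id, "gB")
})

test_that("gene assignment matches the brute-force overlap enumerator", {
  set.seed(404)
  for (rep in 1:20) {
    # fuzzed annotation: genes with 1-3 exons, random strands, on one chrom
    n_genes <- sample(2:5, 1)
    te <- dplyr::bind_rows(lapply(seq_len(n_genes), function(g) {
      n_ex <- sample(1:3, 1)
      starts <- sort(sample.int(3000L, n_ex)) + (g - 1L) * 800L
      tibble::tibble(
        transcript_id = paste0("t", g), gene_id = paste0("g", g),
        chrom = "chr1", strand = sample(c("+", "-"), 1),
        start = starts, end = starts + sample(50:200, n_ex, replace = TRUE)
      )
    }))
    te <- te |>
      dplyr::group_by(gene_id) |>
      dplyr::filter(!any(start < dplyr::lag(end, default = -1L))) |>
      dplyr::ungroup()
    ann <- ase_annotation(te)
    alns <- dplyr::bind_rows(lapply(sprintf("x%02d", 1:30), function(id) {
      random_alignment(id, chrom_len = 6000L)
    }))
    for (stranded in c(TRUE, FALSE)) {
      got <- assign_reads_to_genes(alns, ann, stranded = stranded)
      for (i in seq_len(nrow(alns))) {
        blocks <- read_blocks_of(alns[i, ])
        want <- oracle_assign_gene(blocks, alns$strand[i], ann$gene_exons,
                                   stranded = stranded)
        g <- got[got$read_id == alns$read_id[i], ]
        if (want %in% c("no_feature", "ambiguous")) {
          expect_equal(g$status, want)
        } else {
          expect_equal(g$gene_id, want)
        }
      }
    }
  }
})

test_that("disabling strandedness never shrinks a read's gene set", {
  set.seed(505)
  ann <- toy_annotation()
  alns <- dplyr::bind_rows(lapply(sprintf("y%02d", 1:60), function(id) {
    random_alignment(id, chrom_len = 1500L)
  }))
  s <- attr(assign_reads_to_genes(alns, ann, stranded = TRUE), "gene_hits")
  u <- attr(assign_reads_to_genes(alns, ann, stranded = FALSE), "gene_hits")
  key_s <- paste(s$read_id, s$gene_id)
  key_u <- paste(u$read_id, u$gene_id)
  expect_true(all(key_s %in% key_u))
})

test_that("gene-level allelic counts match the simulator truth", {
  sim <- default_sim()
  counts <- count_alleles(sim$tagged, sim$genome$annotation,
                          variants = sim$genome$variants)
  expect_setequal(counts$gene_id, sim$genome$annotation$genes$gene_id)

  tt <- tag_vs_truth(sim$tagged, sim$reads$truth)
  truth_counts <- tt |>
    dplyr::filter(tag != "U") |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(m = sum(tag == "M"), p = sum(tag == "P"))
  chk <- dplyr::left_join(counts, truth_counts, by = "gene_id") |>
    dplyr::mutate(m = dplyr::coalesce(m, 0L), p = dplyr::coalesce(p, 0L))
  # antisense partner genes sit inside a host intron: gene-level counts are
  # exactly the tagged truth restricted to gene-assigned reads, which here
  # is every tagged read of the gene
  expect_equal(chk$maternal, chk$m)
  expect_equal(chk$paternal, chk$p)
})

test_that("snp-overlap read counting is read-level and bounds tagged totals", {
  sim <- default_sim()
  counts <- count_alleles(sim$tagged, sim$genome$annotation,
                          variants = sim$genome$variants)
  # every tagged read overlapped a SNV
  expect_true(all(counts$maternal + counts$paternal <= counts$snp_overlap_reads))
  # noiseless: tagged total equals snp-overlap count (one vote needs one SNV,
  # and covered SNVs always produce a tag because ties need >= 2 SNVs with
  # discordant bases, impossible without errors)
  expect_equal(counts$maternal + counts$paternal, counts$snp_overlap_reads)

  # a read covering 3 SNVs contributes 1
  vars <- tibble::tibble(chrom = "chr1", pos = c(110L, 120L, 130L),
                         maternal_base = "A", paternal_base = "G")
  ann <- toy_annotation()
  a <- toy_alignment("r1", 100, "100M")
  so <- snp_overlap_read_count(a, vars, ann)
  expect_equal(so$snp_overlap_reads, 1L)

  # gene with no exonic SNV counts zero regardless of depth
  far_vars <- tibble::tibble(chrom = "chr1", pos = 5000L,
                             maternal_base = "A", paternal_base = "G")
  so2 <- snp_overlap_read_count(a, far_vars, ann)
  expect_equal(nrow(so2), 0)
})

test_that("count_alleles validates chromosome names and keeps zero rows", {
  sim <- default_sim()
  bad <- sim$tagged
  bad$chrom[1] <- "scaffold_7"
  expect_error(count_alleles(bad, sim$genome$annotation), "scaffold_7")

  empty <- sim$tagged[0, ]
  counts <- count_alleles(empty, sim$genome$annotation)
  expect_equal(nrow(counts), nrow(sim$genome$annotation$genes))
  expect_true(all(counts$maternal == 0))
})

test_that("isoform anchoring requires a unique first exon and a compatible chain", {
  sim <- default_sim()
  ann <- sim$genome$annotation
  txs <- dplyr::filter(ann$transcripts, gene_id == "gnasl")
  exons_of <- function(tx) dplyr::filter(ann$tx_exons, transcript_id == tx) |>
    dplyr::arrange(start)

  # a full-length read of each expressed isoform is assigned to it
  for (tx in txs$transcript_id) {
    e <- exons_of(tx)
    widths <- e$end - e$start
    gaps <- e$start[-1] - e$end[-nrow(e)]
    cig <- paste0(widths, "M")
    cig <- paste(c(rbind(cig[-length(cig)], paste0(gaps, "N")), cig[length(cig)]),
                 collapse = "")
    rd <- toy_alignment("iso", e$start[1], cig, chrom = e$chrom[1])
    expect_equal(assign_read_to_isoform(rd, ann, "gnasl"), tx)
  }

  # a read covering only the shared 3' exons has no first-exon evidence
  e <- exons_of(txs$transcript_id[1])
  shared <- e[(nrow(e) - 2):nrow(e), ]
  widths <- shared$end - shared$start
  gaps <- shared$start[-1] - shared$end[-nrow(shared)]
  cig <- paste0(widths, "M")
  cig <- paste(c(rbind(cig[-length(cig)], paste0(gaps, "N")), cig[length(cig)]),
               collapse = "")
  rd <- toy_alignment("sh", shared$start[1], cig, chrom = shared$chrom[1])
  expect_true(is.na(assign_read_to_isoform(rd, ann, "gnasl")))

  # two transcripts with an identical first exon are ambiguous
  dup <- ase_annotation(tibble::tibble(
    transcript_id = c("u1", "u1", "u2", "u2"),
    gene_id = "dup", chrom = "chr1", strand = "+",
    start = c(100L, 500L, 100L, 800L), end = c(200L, 600L, 200L, 900L)
  ))
  rd2 <- toy_alignment("amb", 100, "100M")
  expect_true(is.na(assign_read_to_isoform(rd2, dup, "dup")))
})

test_that("isoform-level counts recover the locus truth", {
  sim <- default_sim()
  iso <- count_isoform_alleles(sim$tagged, sim$genome$annotation, "gnasl")
  get <- function(tx) iso[iso$transcript_id == tx, ]
  expect_equal(get("gnasl_nespas")$maternal + get("gnasl_nespas")$paternal, 0L)
  expect_equal(get("gnasl_nesp")$paternal, 0L)
  expect_gt(get("gnasl_nesp")$maternal, 0L)
  expect_equal(get("gnasl_ex1a")$maternal, 0L)
  expect_gt(get("gnasl_ex1a")$paternal, 0L)
  expect_gt(get("gnasl_gsa")$maternal, 0L)
  expect_gt(get("gnasl_gsa")$paternal, 0L)

  # per-isoform truth agreement, read by read
  truth <- sim$reads$truth |>
    dplyr::filter(gene_id == "gnasl") |>
    dplyr::count(transcript_id, haplotype)
  for (i in seq_len(nrow(truth))) {
    row <- get(truth$transcript_id[i])
    col <- if (truth$haplotype[i] == "M") row$maternal else row$paternal
    expect_equal(col, truth$n[i])
  }

  # assigned + unassigned partitions the locus-assigned reads
  counts <- count_alleles(sim$tagged, sim$genome$annotation)
  locus_total <- counts$maternal[counts$gene_id == "gnasl"] +
    counts$paternal[counts$gene_id == "gnasl"] +
    counts$untagged[counts$gene_id == "gnasl"]
  expect_equal(sum(iso$maternal + iso$paternal + iso$untagged), locus_total)

  # exact simulated TSS: tolerance 0 and 50 agree
  iso0 <- count_isoform_alleles(sim$tagged, sim$genome$annotation, "gnasl",
                                tss_tolerance = 0L)
  expect_equal(as.data.frame(iso0), as.data.frame(iso))
})
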