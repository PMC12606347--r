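test_that("VCF loader keeps phased biallelic SNVs and reports the rest", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "mix.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tF1",
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "chr1\t201\t.\tC\tT\t.\tPASS\t.\tGT\t1|0",
    "chr1\t301\t.\tG\tGA\t.\tPASS\t.\tGT\t0|1",   # indel
    "chr1\t401\t.\tT\tA\t.\tPASS\t.\tGT\t0/1",    # unphased
    "chr1\t501\t.\tA\tC,G\t.\tPASS\t.\tGT\t1|2",  # multi-allelic
    "chr1\t601\t.\tA\tC\t.\tPASS\t.\tGT\t1|1",    # homozygous
    "chr2\t101\t.\tG\tC\t.\tPASS\t.\tGT\t0|1"
  ), vcf)
  v <- read_phased_variants(vcf)
  expect_equal(nrow(v), 3)
  rep <- attr(v, "skip_report")
  expect_equal(rep[["indel"]], 1L)
  expect_equal(rep[["unphased"]], 1L)
  expect_equal(rep[["multiallelic"]], 1L)
  expect_equal(rep[["non_heterozygous"]], 1L)
  # GT 0|1: maternal = REF; GT 1|0: maternal = ALT
  expect_equal(v$maternal_base[v$chrom == "chr1" & v$pos == 100L], "A")
  expect_equal(v$maternal_base[v$pos == 200L], "T")
  expect_equal(v$paternal_base[v$pos == 200L], "C")
})

test_that("an empty VCF body loads as an empty variant set", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "empty.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tF1"
  ), vcf)
  v <- read_phased_variants(vcf)
  expect_equal(nrow(v), 0)
})

test_that("duplicated variant positions keep the first record with a warning", {
  d <- withr::local_tempdir()
  vcf <- file.path(d, "dup.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tF1",
    "chr1\t101\t.\tA\tG\t.\tPASS\t.\tGT\t0|1",
    "chr1\t101\t.\tA\tC\t.\tPASS\t.\tGT\t0|1"
  ), vcf)
  expect_warning(v <- read_phased_variants(vcf), "duplicated")
  expect_equal(nrow(v), 1)
  expect_equal(v$paternal_base, "G")
})

test_that("read_alleles honours CIGAR geometry", {
  vars <- tibble::tibble(
    chrom = "chr1", pos = c(103L, 150L, 199L, 250L),
    maternal_base = "A", paternal_base = "G"
  )
  # 5S10M starting at ref 100: block offset 3 -> query index 8
  a <- toy_alignment("r1", 100, "5S10M",
                     seq = paste0("NNNNN", "AACTAAGGTT"))
  al <- read_alleles(a, vars)
  expect_equal(nrow(al), 1)
  expect_equal(al$pos, 103L)
  expect_equal(al$observed_base, substr(a$seq, 9, 9))

  # spliced read 100M100N100M over [100,200)+[300,400): 250 is in the intron,
  # 199 is the last base of the first block
  b <- toy_alignment("r2", 100, "100M100N100M")
  al2 <- read_alleles(b, vars)
  expect_setequal(al2$pos, c(103L, 150L, 199L))
  expect_false(250L %in% al2$pos)

  # a variant under a deletion is reported as a gap
  cvars <- tibble::tibble(chrom = "chr1", pos = 105L,
                          maternal_base = "A", paternal_base = "G")
  c_ <- toy_alignment("r3", 100, "5M2D5M")
  al3 <- read_alleles(c_, cvars)
  expect_equal(nrow(al3), 1)
  expect_true(is.na(al3$observed_base))
})

test_that("tag_read votes by majority with ties untagged", {
  vars <- tibble::tibble(chrom = "chr1", pos = c(105L, 110L, 115L, 120L),
                         maternal_base = "A", paternal_base = "G")
  mk <- function(bases) {
    seq <- strrep("C", 30)
    for (i in seq_along(bases)) substr(seq, 6 + 5 * (i - 1), 6 + 5 * (i - 1)) <- bases[i]
    toy_alignment("r", 100, "30M", seq = seq)
  }
  # one covered SNV with the maternal allele is sufficient
  one <- toy_alignment("r", 100, "10M", seq = paste0(strrep("C", 5), "A", strrep("C", 4)))
  t1 <- tag_read(one, vars)
  expect_equal(t1$label, "MATERNAL")
  expect_equal(c(t1$maternal_votes, t1$paternal_votes), c(1L, 0L))

  # 2 maternal vs 2 paternal is a tie
  t2 <- tag_read(mk(c("A", "A", "G", "G")), vars)
  expect_equal(t2$label, "UNTAGGED")
  expect_equal(c(t2$maternal_votes, t2$paternal_votes), c(2L, 2L))

  # mismatching bases count as mismatch votes and never break ties
  t3 <- tag_read(mk(c("T", "T", "T", "T")), vars)
  expect_equal(t3$label, "UNTAGGED")
  expect_equal(t3$mismatch_votes, 4L)

  # zero coverage is untagged with zero votes
  far <- toy_alignment("r", 5000, "10M")
  t4 <- tag_read(far, vars)
  expect_equal(t4$label, "UNTAGGED")
  expect_equal(t4$maternal_votes + t4$paternal_votes, 0L)

  expect_error(tag_read(one[0, ], vars), "at least one record")
})

test_that("base quality below the threshold suppresses votes", {
  vars <- tibble::tibble(chrom = "chr1", pos = 105L,
                         maternal_base = "A", paternal_base = "G")
  a <- toy_alignment("r", 100, "10M", seq = paste0(strrep("C", 5), "A", strrep("C", 4)))
  a$qual <- paste0(strrep("I", 5), "#", strrep("I", 4))  # Q2 at the SNV
  expect_equal(tag_read(a, vars, min_base_quality = 10L)$label, "UNTAGGED")
  expect_equal(tag_read(a, vars, min_base_quality = 0L)$label, "MATERNAL")
})

test_that("tagging agrees with the per-base expansion oracle on fuzzed reads", {
  set.seed(202)
  vars <- random_variants(n = 500L)
  alns <- dplyr::bind_rows(lapply(
    sprintf("f%04d", 1:300), random_alignment
  ))
  tagged <- haplotag(alns, vars)
  got <- tagged |>
    dplyr::distinct(read_id, haplotype, maternal_votes, paternal_votes,
                    mismatch_votes)
  for (i in seq_len(nrow(got))) {
    o <- oracle_tag(alns[alns$read_id == got$read_id[i], ], vars)
    expect_equal(got$maternal_votes[i], o$maternal)
    expect_equal(got$paternal_votes[i], o$paternal)
    expect_equal(got$mismatch_votes[i], o$mismatch)
    expect_equal(
      c(M = "MATERNAL", P = "PATERNAL", U = "UNTAGGED")[[got$haplotype[i]]],
      o$label
    )
  }
})

test_that("swapping the parental alleles swaps the labels exactly", {
  set.seed(303)
  vars <- random_variants(n = 300L)
  alns <- dplyr::bind_rows(lapply(sprintf("s%03d", 1:120), random_alignment))
  fwd <- haplotag(alns, vars)
  swapped <- dplyr::rename(vars, maternal_base = paternal_base,
                           paternal_base = maternal_base)
  rev <- haplotag(alns, swapped)
  remap <- c(M = "P", P = "M", U = "U")
  expect_equal(unname(remap[fwd$haplotype]), rev$haplotype)
  expect_equal(fwd$maternal_votes, rev$paternal_votes)
})

test_that("noiseless simulated reads are tagged to their true haplotype", {
  sim <- default_sim()
  tt <- tag_vs_truth(sim$tagged, sim$reads$truth)
  covered <- dplyr::filter(tt, tag != "U")
  expect_gt(nrow(covered), 0)
  expect_true(all(covered$tag == covered$haplotype))
})

test_that("supplementary records inherit the read tag; chromosomes without variants warn", {
  vars <- tibble::tibble(chrom = "chr1", pos = 105L,
                         maternal_base = "A", paternal_base = "G")
  prim <- toy_alignment("r", 100, "10M", seq = paste0(strrep("C", 5), "A", strrep("C", 4)))
  supp <- toy_alignment("r", 3000, "10M")
  supp$flag <- 2048L
  tg <- haplotag(dplyr::bind_rows(prim, supp), vars)
  expect_equal(tg$haplotype, c("M", "M"))

  off <- toy_alignment("q", 100, "10M", chrom = "chr9")
  expect_warning(tg2 <- haplotag(off, vars), "chr9")
  expect_equal(tg2$haplotype, "U")
})

test_that("split partitions records by tag and conserves the input", {
  sim <- default_sim()
  streams <- split_by_haplotype(sim$tagged)
  expect_equal(
    nrow(streams$maternal) + nrow(streams$paternal) + nrow(streams$untagged),
    nrow(sim$tagged)
  )
  expect_true(all(streams$maternal$haplotype == "M"))
  expect_true(all(streams$paternal$haplotype == "P"))
  # re-sorted concatenation equals the input
  back <- dplyr::arrange(dplyr::bind_rows(streams), chrom, pos, read_id)
  orig <- dplyr::arrange(sim$tagged, chrom, pos, read_id)
  expect_equal(as.data.frame(back), as.data.frame(orig))
  # maternal stream of noiseless data contains only truth-maternal reads
  tm <- dplyr::left_join(
    dplyr::distinct(streams$maternal, read_id), sim$reads$truth, by = "read_id"
  )
  expect_true(all(tm$haplotype == "M"))
})

test_that("removing all variants leaves every read untagged", {
  sim <- default_sim()
  empty_vars <- sim$genome$variants[0, ]
  tg <- suppressWarnings(haplotag(head(sim$reads$alignments, 50), empty_vars))
  expect_true(all(tg$haplotype == "U"))
})

test_that("mis-tag rate under noise stays within the binomial bound", {
  cfg <- sim_config(seed = 77, base_error_rate = 0.02,
                    chromosomes = tibble::tibble(name = c("chr1", "chrX"),
                                                 length = c(300000L, 300000L)),
                    n_genes = 15L, include_gnas_like = FALSE,
                    antisense_pair_count = 0L)
  g <- sim_genome(cfg)
  r <- sim_reads(g)
  tg <- haplotag(r$alignments, g$variants)
  tt <- tag_vs_truth(tg, r$truth)
  votes <- tg |>
    dplyr::distinct(read_id, maternal_votes, paternal_votes, mismatch_votes)
  tt <- dplyr::left_join(tt, votes, by = "read_id")
  k <- tt$maternal_votes + tt$paternal_votes + tt$mismatch_votes
  # corrupting a covered SNV base toward the other allele has prob e/3;
  # a mis-tag needs at least ceiling(k/2) such corruptions
  p_bound <- stats::pbinom(ceiling(k / 2) - 1, k, 0.02 / 3, lower.tail = FALSE)
  mis <- tt$tag != "U" & tt$tag != tt$haplotype
  bound <- sum(p_bound) + 3 * sqrt(sum(p_bound * (1 - p_bound)))
  expect_lte(sum(mis), bound)
})
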