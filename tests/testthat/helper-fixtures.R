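# shared small simulation fixtures, built once per test run

small_config <- function(seed = 11, ...) {
  sim_config(
    seed = seed,
    chromosomes = tibble::tibble(
      name = c("chr1", "chr2", "chrX"),
      length = c(200000L, 200000L, 200000L)
    ),
    n_genes = 10L,
    depth_mean = 60,
    ...
  )
}

# a cached default-condition simulation used by several test files
sim_cache <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(sim_cache$sim)) {
    cfg <- sim_config(seed = 101)
    genome <- sim_genome(cfg)
    reads <- sim_reads(genome)
    tagged <- haplotag(reads$alignments, genome$variants)
    sim_cache$sim <- list(
      config = cfg, genome = genome, reads = reads, tagged = tagged
    )
  }
  sim_cache$sim
}

# read-level tag vs truth join
tag_vs_truth <- function(tagged, truth) {
  tagged |>
    dplyr::filter(bitwAnd(flag, 256L) == 0L) |>
    dplyr::distinct(read_id, tag = haplotype) |>
    dplyr::left_join(truth, by = "read_id")
}

# hand-built two-gene annotation on one chromosome:
#   gA '+' exons [100,200) and [400,500); gB '-' single exon [1000,1100)
toy_annotation <- function() {
  ase_annotation(
    tibble::tibble(
      transcript_id = c("tA", "tA", "tB"),
      gene_id = c("gA", "gA", "gB"),
      chrom = "chr1", strand = c("+", "+", "-"),
      start = c(100L, 400L, 1000L), end = c(200L, 500L, 1100L)
    ),
    genes = tibble::tibble(gene_id = c("gA", "gB"),
                           biotype = c("coding", "noncoding"))
  )
}

toy_alignment <- function(read_id, pos, cigar, strand = "+", seq_len = NULL,
                          chrom = "chr1", seq = NULL) {
  if (is.null(seq)) {
    if (is.null(seq_len)) {
      m <- stringr::str_match_all(cigar, "(\\d+)([MIS])")[[1]]
      seq_len <- sum(as.integer(m[, 2]))
    }
    seq <- strrep("A", seq_len)
  }
  tibble::tibble(
    read_id = read_id, chrom = chrom, strand = strand, pos = as.integer(pos),
    cigar = cigar, seq = seq, qual = strrep("I", nchar(seq)),
    flag = if (strand == "-") 16L else 0L
  )
}
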