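#' Write phased SNVs to a single-sample VCF
#'
#' Emits VCF v4.2 with one sample (`F1`) and phased genotypes. The maternal
#' allele is written as REF and the paternal allele as ALT with genotype
#' `0|1`, so the allele order in GT encodes maternal|paternal.
#'
#' @param variants Tibble with columns `chrom`, `pos` (0-based),
#'   `maternal_base`, `paternal_base`.
#' @param path Output path.
#' @param ref_lengths Named integer vector of chromosome lengths for the
#'   `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, ref_lengths = NULL) {
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(ref_lengths)) {
    header <- c(header, sprintf(
      "##contig=<ID=%s,length=%d>", names(ref_lengths), as.integer(ref_lengths)
    ))
  }
  header <- c(header, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tF1")
  body <- if (nrow(variants) > 0) {
    sprintf(
      "%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t0|1",
      variants$chrom, variants$pos + 1L,
      variants$maternal_base, variants$paternal_base
    )
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Load phased biallelic SNVs from a VCF
#'
#' Keeps only biallelic SNVs with a phased heterozygous genotype in the
#' first sample. The allele order in GT defines maternal|paternal: `0|1`
#' gives maternal = REF, `1|0` gives maternal = ALT. Indels, multi-allelic
#' records, unphased or homozygous genotypes are skipped and tallied in the
#' `skip_report` attribute. Duplicated positions keep the first record with
#' a warning.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return Tibble with columns `chrom`, `pos` (0-based), `maternal_base`,
#'   `paternal_base`; attribute `skip_report` is a named integer vector with
#'   entries `indel`, `multiallelic`, `unphased`, `non_heterozygous`.
#' @export
read_phased_variants <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  skip <- c(indel = 0L, multiallelic = 0L, unphased = 0L, non_heterozygous = 0L)
  empty <- tibble::tibble(
    chrom = character(), pos = integer(),
    maternal_base = character(), paternal_base = character()
  )
  if (nrow(fix) == 0) {
    attr(empty, "skip_report") <- skip
    return(empty)
  }
  if (ncol(v@gt) < 2) {
    rlang::abort("VCF has no sample column; a phased single-sample VCF is required")
  }
  fmt <- strsplit(v@gt[, 1], ":", fixed = TRUE)
  gt_idx <- vapply(fmt, function(f) match("GT", f), integer(1))
  if (any(is.na(gt_idx))) rlang::abort("VCF FORMAT lacks a GT field")
  gt <- vapply(seq_len(nrow(fix)), function(i) {
    strsplit(v@gt[i, 2], ":", fixed = TRUE)[[1]][gt_idx[i]]
  }, character(1))
  if (any(is.na(gt) | gt == "")) rlang::abort("malformed GT field in VCF sample column")

  ref <- fix$REF; alt <- fix$ALT
  multi <- grepl(",", alt, fixed = TRUE)
  indel <- !multi & (nchar(ref) != 1L | nchar(alt) != 1L)
  unphased <- !multi & !indel & !grepl("|", gt, fixed = TRUE)
  het <- gt %in% c("0|1", "1|0")
  nonhet <- !multi & !indel & !unphased & !het
  keep <- !multi & !indel & !unphased & het
  skip["multiallelic"] <- sum(multi)
  skip["indel"] <- sum(indel)
  skip["unphased"] <- sum(unphased)
  skip["non_heterozygous"] <- sum(nonhet)

  out <- tibble::tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]) - 1L,
    maternal_base = ifelse(gt[keep] == "0|1", ref[keep], alt[keep]),
    paternal_base = ifelse(gt[keep] == "0|1", alt[keep], ref[keep])
  )
  dup <- duplicated(out[, c("chrom", "pos")])
  if (any(dup)) {
    rlang::warn(paste0(sum(dup), " duplicated variant position(s); keeping first record"))
    out <- out[!dup, ]
  }
  attr(out, "skip_report") <- skip
  out
}

#' Write alignments to a coordinate-sorted SAM file
#'
#' Tagged reads carry `HP:i:1` (maternal) or `HP:i:2` (paternal) plus a
#' `hv:Z:` tag with maternal,paternal,mismatch vote counts; untagged reads
#' carry no haplotype tag.
#'
#' @param alignments Alignment tibble (`read_id`, `chrom`, `strand`, `pos`
#'   0-based, `cigar`, `seq`, `qual`, `flag`, optionally `haplotype` and
#'   vote columns).
#' @param path Output path.
#' @param ref_lengths Named integer vector of chromosome lengths.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, path, ref_lengths) {
  header <- c(
    "@HD\tVN:1.6\tSO:coordinate",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths))
  )
  a <- alignments |>
    dplyr::mutate(.chrord = match(.data$chrom, names(ref_lengths))) |>
    dplyr::arrange(.data$.chrord, .data$pos, .data$read_id)
  if (any(is.na(a$.chrord))) {
    rlang::abort("alignments reference chromosomes absent from ref_lengths")
  }
  body <- sprintf(
    "%s\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
    a$read_id, a$flag, a$chrom, a$pos + 1L, a$cigar, a$seq, a$qual
  )
  if ("haplotype" %in% names(a)) {
    hp <- dplyr::case_when(
      a$haplotype == "M" ~ "\tHP:i:1",
      a$haplotype == "P" ~ "\tHP:i:2",
      TRUE ~ ""
    )
    body <- paste0(body, hp)
    if (all(c("maternal_votes", "paternal_votes", "mismatch_votes") %in% names(a))) {
      body <- paste0(body, sprintf(
        "\thv:Z:%d,%d,%d", a$maternal_votes, a$paternal_votes, a$mismatch_votes
      ))
    }
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read spliced alignments from SAM or BAM into a tibble
#'
#' SAM input is converted to BAM with [Rsamtools::asBam()] and scanned with
#' [Rsamtools::scanBam()]. Positions are returned 0-based. An `HP` tag, when
#' present, populates the `haplotype` column (`1` = maternal `"M"`,
#' `2` = paternal `"P"`, absent = `"U"`).
#'
#' @param path SAM or BAM path.
#' @return Alignment tibble as produced by [sim_reads()], plus `haplotype`
#'   when the file carries HP tags.
#' @export
read_sam <- function(path) {
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(fileext = ""), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "strand", "pos", "cigar", "seq", "qual"),
    tag = "HP"
  )
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  hp <- x$tag$HP
  out <- tibble::tibble(
    read_id = x$qname,
    chrom = as.character(x$rname),
    strand = as.character(x$strand),
    pos = x$pos - 1L,
    cigar = x$cigar,
    seq = as.character(x$seq),
    qual = as.character(x$qual),
    flag = x$flag
  )
  if (!is.null(hp) && !all(is.na(hp))) {
    out$haplotype <- dplyr::case_when(hp %in% 1L ~ "M", hp %in% 2L ~ "P", TRUE ~ "U")
  }
  out
}

#' Write annotation to GTF
#'
#' Emits `exon` features with `gene_id`, `transcript_id` and `gene_biotype`
#' attributes (1-based closed coordinates, per GTF convention).
#'
#' @param annotation An [ase_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  te <- annotation$tx_exons |>
    dplyr::left_join(
      dplyr::select(annotation$genes, "gene_id", "biotype"), by = "gene_id"
    )
  gr <- GenomicRanges::GRanges(
    seqnames = te$chrom,
    ranges = IRanges::IRanges(te$start + 1L, te$end),
    strand = te$strand,
    type = "exon",
    source = "aselong",
    gene_id = te$gene_id,
    transcript_id = te$transcript_id,
    gene_biotype = te$biotype
  )
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read gene/transcript annotation from GTF
#'
#' Imports `exon` features via [rtracklayer::import()] and rebuilds the
#' per-gene exon unions from the transcript structures.
#'
#' @param path GTF path.
#' @param x_chrom Chromosome name treated as the X.
#' @return An [ase_annotation()].
#' @export
read_annotation <- function(path, x_chrom = "chrX") {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) return(empty_annotation())
  te <- tibble::tibble(
    transcript_id = gr$transcript_id,
    gene_id = gr$gene_id,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(BiocGenerics::strand(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr)
  )
  genes <- NULL
  if ("gene_biotype" %in% names(S4Vectors::mcols(gr))) {
    genes <- tibble::tibble(gene_id = gr$gene_id, biotype = gr$gene_biotype) |>
      dplyr::distinct(.data$gene_id, .keep_all = TRUE)
  }
  ase_annotation(te, genes, x_chrom = x_chrom)
}

#' Read / write allelic count and call tables
#'
#' TSVs with a header line, round-trippable: integer count columns, double
#' ratio, logical `informative`.
#'
#' @param x Table to write.
#' @param path File path.
#' @return `read_allelic_table()` returns a tibble; `write_allelic_table()`
#'   returns `path` invisibly.
#' @export
write_allelic_table <- function(x, path) {
  readr::write_tsv(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_allelic_table
#' @export
read_allelic_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
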