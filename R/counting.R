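#' Assign reads to genes with stranded union semantics
#'
#' A read counts toward the set of genes whose merged exon union is
#' overlapped by any of its aligned match blocks (strand-matched when
#' `stranded`). An empty set is `no_feature`, a singleton assigns the gene,
#' anything larger is `ambiguous`. Antisense overlap does not conflict in
#' stranded mode, which resolves sense/antisense gene pairs.
#'
#' @param alignments Alignment tibble (records of multi-record reads are
#'   pooled per `read_id`; secondary alignments are ignored).
#' @param annotation An [ase_annotation()].
#' @param stranded Require the alignment strand to match the gene strand.
#' @return Tibble with one row per read: `read_id`, `status`
#'   (`"assigned"`, `"no_feature"`, `"ambiguous"`), `gene_id` (NA unless
#'   assigned); attribute `gene_hits` holds the full read-by-gene overlap
#'   table used for ambiguity bookkeeping.
#' @export
assign_reads_to_genes <- function(alignments, annotation, stranded = TRUE) {
  alignments <- alignments[bitwAnd(alignments$flag, FLAG_SECONDARY) == 0L, , drop = FALSE]
  read_ids <- unique(alignments$read_id)
  empty <- tibble::tibble(
    read_id = read_ids, status = rep("no_feature", length(read_ids)),
    gene_id = rep(NA_character_, length(read_ids))
  )
  blocks <- alignment_blocks(alignments)
  if (nrow(blocks) == 0 || nrow(annotation$gene_exons) == 0) {
    attr(empty, "gene_hits") <- tibble::tibble(read_id = character(), gene_id = character())
    return(empty)
  }

  lv <- unique(c(blocks$chrom, annotation$gene_exons$chrom))
  bgr <- GenomicRanges::GRanges(
    seqnames = factor(blocks$chrom, levels = lv),
    ranges = IRanges::IRanges(blocks$ref_start + 1L, blocks$ref_end),
    strand = if (stranded) alignments$strand[blocks$aln] else "*"
  )
  ggr <- gene_exon_granges(annotation, seqlevels = lv)
  hits <- GenomicRanges::findOverlaps(bgr, ggr, ignore.strand = !stranded)

  gene_hits <- tibble::tibble(
    read_id = blocks$read_id[S4Vectors::queryHits(hits)],
    gene_id = S4Vectors::mcols(ggr)$gene_id[S4Vectors::subjectHits(hits)]
  ) |>
    dplyr::distinct()

  per_read <- gene_hits |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      n_genes = dplyr::n(),
      gene_id = ifelse(dplyr::n() == 1L, .data$gene_id[1], NA_character_),
      .groups = "drop"
    )
  out <- tibble::tibble(read_id = read_ids) |>
    dplyr::left_join(per_read, by = "read_id") |>
    dplyr::mutate(
      status = dplyr::case_when(
        is.na(.data$n_genes) ~ "no_feature",
        .data$n_genes == 1L ~ "assigned",
        TRUE ~ "ambiguous"
      )
    ) |>
    dplyr::select("read_id", "status", "gene_id")
  attr(out, "gene_hits") <- gene_hits
  out
}

# read-level haplotype of each read in a tagged alignment tibble
read_haplotypes <- function(tagged) {
  tagged |>
    dplyr::filter(bitwAnd(.data$flag, FLAG_SECONDARY) == 0L) |>
    dplyr::distinct(.data$read_id, .data$haplotype)
}

#' Gene-level allelic counting over haplotype streams
#'
#' Counts, for every annotated gene (zero rows kept), the maternal,
#' paternal and untagged reads assigned to it under stranded union
#' semantics. Reads overlapping several same-strand genes are ambiguous and
#' excluded from all allelic columns; the per-gene `ambiguous` column counts
#' how many ambiguous reads touched the gene. When `variants` are supplied,
#' `snp_overlap_reads` gives the number of gene-assigned reads whose blocks
#' cover at least one SNV — the informativeness denominator of the
#' downstream filter.
#'
#' @param tagged Output of [haplotag()], or the stream list from
#'   [split_by_haplotype()].
#' @param annotation An [ase_annotation()].
#' @param variants Optional phased variant tibble.
#' @param stranded Strand-matched counting (default TRUE).
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `biotype`,
#'   `is_x_linked`, `maternal`, `paternal`, `untagged`, `ambiguous` and
#'   (when `variants` given) `snp_overlap_reads`; attribute
#'   `assignment_summary` tallies read-level statuses.
#' @export
count_alleles <- function(tagged, annotation, variants = NULL, stranded = TRUE) {
  if (is.list(tagged) && !is.data.frame(tagged)) {
    tagged <- dplyr::bind_rows(tagged)
  }
  if (!"haplotype" %in% names(tagged)) {
    rlang::abort("input has no haplotype column; run haplotag() first")
  }
  bad <- setdiff(unique(tagged$chrom), unique(annotation$genes$chrom))
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "alignment chromosomes absent from annotation: ", paste(bad, collapse = ", ")
    ))
  }

  assignment <- assign_reads_to_genes(tagged, annotation, stranded = stranded)
  haps <- read_haplotypes(tagged)
  per_read <- dplyr::left_join(assignment, haps, by = "read_id")

  counts <- per_read |>
    dplyr::filter(.data$status == "assigned") |>
    dplyr::count(.data$gene_id, .data$haplotype) |>
    tidyr::pivot_wider(
      names_from = "haplotype", values_from = "n", values_fill = 0L
    )
  for (col in c("M", "P", "U")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }

  amb_reads <- per_read$read_id[per_read$status == "ambiguous"]
  gene_hits <- attr(assignment, "gene_hits")
  amb_per_gene <- gene_hits |>
    dplyr::filter(.data$read_id %in% amb_reads) |>
    dplyr::count(.data$gene_id, name = "ambiguous")

  out <- annotation$genes |>
    dplyr::select("gene_id", "chrom", "strand", "biotype", "is_x_linked") |>
    dplyr::left_join(counts, by = "gene_id") |>
    dplyr::left_join(amb_per_gene, by = "gene_id") |>
    dplyr::mutate(
      maternal = as.integer(dplyr::coalesce(.data$M, 0L)),
      paternal = as.integer(dplyr::coalesce(.data$P, 0L)),
      untagged = as.integer(dplyr::coalesce(.data$U, 0L)),
      ambiguous = as.integer(dplyr::coalesce(.data$ambiguous, 0L))
    ) |>
    dplyr::select(-dplyr::any_of(c("M", "P", "U")))

  if (!is.null(variants)) {
    so <- snp_overlap_read_count(tagged, variants, annotation, stranded = stranded)
    out <- out |>
      dplyr::left_join(so, by = "gene_id") |>
      dplyr::mutate(
        snp_overlap_reads = as.integer(dplyr::coalesce(.data$snp_overlap_reads, 0L))
      )
  }
  attr(out, "assignment_summary") <- dplyr::count(assignment, .data$status)
  out
}

#' Per-gene count of assigned reads covering at least one SNV
#'
#' The unit is the read, not the SNV: a read covering three variants
#' contributes one. Computed over gene-assigned reads (ambiguous and
#' featureless reads excluded).
#'
#' @inheritParams count_alleles
#' @param alignments Alignment tibble (tagged or not).
#' @return Tibble `gene_id`, `snp_overlap_reads` (genes with zero omitted;
#'   [count_alleles()] completes them).
#' @export
snp_overlap_read_count <- function(alignments, variants, annotation, stranded = TRUE) {
  assignment <- assign_reads_to_genes(alignments, annotation, stranded = stranded)
  assigned <- dplyr::filter(assignment, .data$status == "assigned")
  prim <- alignments[bitwAnd(alignments$flag, FLAG_SECONDARY) == 0L &
                       alignments$read_id %in% assigned$read_id, , drop = FALSE]
  al <- read_alleles(prim, variants)
  covered <- unique(al$read_id)
  assigned |>
    dplyr::filter(.data$read_id %in% covered) |>
    dplyr::count(.data$gene_id, name = "snp_overlap_reads")
}

tx_introns <- function(tx_exons_one) {
  e <- dplyr::arrange(tx_exons_one, .data$start)
  if (nrow(e) < 2) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  tibble::tibble(start = e$end[-nrow(e)], end = e$start[-1])
}

# splice-chain compatibility of pooled read blocks with one transcript
chain_compatible <- function(blocks, exons, tol) {
  blocks <- blocks[order(blocks$ref_start), , drop = FALSE]
  exons <- dplyr::arrange(exons, .data$start)
  # every read intron must match a transcript intron within tol at both ends
  ri <- if (nrow(blocks) > 1) {
    tibble::tibble(
      start = blocks$ref_end[-nrow(blocks)], end = blocks$ref_start[-1]
    )
  } else {
    tibble::tibble(start = integer(), end = integer())
  }
  ti <- tx_introns(exons)
  if (nrow(ri) > 0) {
    ok <- vapply(seq_len(nrow(ri)), function(k) {
      any(abs(ti$start - ri$start[k]) <= tol & abs(ti$end - ri$end[k]) <= tol)
    }, logical(1))
    if (!all(ok)) return(FALSE)
  }
  # every read block must lie inside the exon union (tol slack at the edges)
  ir_ex <- IRanges::reduce(IRanges::IRanges(exons$start + 1L - tol, exons$end + tol))
  ir_bl <- IRanges::IRanges(blocks$ref_start + 1L, blocks$ref_end)
  cov <- IRanges::countOverlaps(ir_bl, ir_ex, type = "within")
  all(cov >= 1L)
}

#' Anchor a read to one isoform by its first exon and splice chain
#'
#' For loci whose isoforms share 3' exons but start from distinct first
#' exons (the organisation of the Gnas imprinted cluster), a read is
#' attributed to the unique transcript whose first exon contains the read's
#' 5'-most aligned base (within `tss_tolerance`) and whose exon chain is
#' compatible with the read's block chain (all blocks inside the exon
#' union; every skipped intron matching a transcript intron within
#' tolerance). Reads starting in shared exons, or matching several
#' transcripts, stay unassigned.
#'
#' @param records Alignment tibble rows of one read.
#' @param annotation An [ase_annotation()].
#' @param gene Gene id of the locus.
#' @param tss_tolerance Slack in bp around the first exon (default 50).
#' @return A transcript id, or `NA_character_` when unassigned.
#' @export
assign_read_to_isoform <- function(records, annotation, gene, tss_tolerance = 50L) {
  stopifnot(tss_tolerance >= 0)
  records <- records[bitwAnd(records$flag, FLAG_SECONDARY) == 0L, , drop = FALSE]
  if (nrow(records) == 0) return(NA_character_)
  blocks <- alignment_blocks(records)
  strand <- records$strand[1]
  p5 <- if (strand == "+") min(blocks$ref_start) else max(blocks$ref_end) - 1L

  txs <- dplyr::filter(
    annotation$transcripts, .data$gene_id == gene, .data$strand == strand
  )
  if (nrow(txs) == 0) return(NA_character_)
  anchored <- txs |>
    dplyr::filter(
      p5 >= .data$first_exon_start - tss_tolerance,
      p5 < .data$first_exon_end + tss_tolerance
    )
  if (nrow(anchored) == 0) return(NA_character_)
  compatible <- vapply(anchored$transcript_id, function(tx) {
    exons <- dplyr::filter(annotation$tx_exons, .data$transcript_id == tx)
    chain_compatible(blocks, exons, tss_tolerance)
  }, logical(1))
  hits <- anchored$transcript_id[compatible]
  if (length(hits) == 1L) hits else NA_character_
}

#' Isoform-level allelic counting at a multi-isoform locus
#'
#' Restricts to reads gene-assigned to the locus, anchors each to an
#' isoform with [assign_read_to_isoform()], and tabulates maternal /
#' paternal / untagged counts per transcript plus an `UNASSIGNED` row, so
#' assigned + unassigned equals the locus-assigned read count.
#'
#' @inheritParams count_alleles
#' @param gene Gene id of the locus.
#' @param tss_tolerance Slack in bp for the first-exon anchor.
#' @return Tibble `transcript_id`, `gene_id`, `maternal`, `paternal`,
#'   `untagged` with one row per locus transcript (zeros kept) and a final
#'   `UNASSIGNED` row.
#' @export
count_isoform_alleles <- function(tagged, annotation, gene, tss_tolerance = 50L,
                                  stranded = TRUE) {
  if (is.list(tagged) && !is.data.frame(tagged)) tagged <- dplyr::bind_rows(tagged)
  if (!"haplotype" %in% names(tagged)) {
    rlang::abort("input has no haplotype column; run haplotag() first")
  }
  assignment <- assign_reads_to_genes(tagged, annotation, stranded = stranded)
  locus_reads <- assignment$read_id[
    assignment$status == "assigned" & assignment$gene_id %in% gene
  ]
  prim <- tagged[bitwAnd(tagged$flag, FLAG_SECONDARY) == 0L, , drop = FALSE]
  haps <- read_haplotypes(tagged)

  iso <- vapply(locus_reads, function(r) {
    recs <- prim[prim$read_id == r, , drop = FALSE]
    out <- assign_read_to_isoform(recs, annotation, gene, tss_tolerance)
    if (is.na(out)) "UNASSIGNED" else out
  }, character(1))

  tab <- tibble::tibble(read_id = locus_reads, transcript_id = unname(iso)) |>
    dplyr::left_join(haps, by = "read_id") |>
    dplyr::count(.data$transcript_id, .data$haplotype) |>
    tidyr::pivot_wider(names_from = "haplotype", values_from = "n", values_fill = 0L)
  for (col in c("M", "P", "U")) {
    if (!col %in% names(tab)) tab[[col]] <- 0L
  }

  all_tx <- dplyr::filter(annotation$transcripts, .data$gene_id %in% gene)
  tibble::tibble(
    transcript_id = c(all_tx$transcript_id, "UNASSIGNED"),
    gene_id = gene
  ) |>
    dplyr::left_join(tab, by = "transcript_id") |>
    dplyr::mutate(
      maternal = as.integer(dplyr::coalesce(.data$M, 0L)),
      paternal = as.integer(dplyr::coalesce(.data$P, 0L)),
      untagged = as.integer(dplyr::coalesce(.data$U, 0L))
    ) |>
    dplyr::select("transcript_id", "gene_id", "maternal", "paternal", "untagged")
}
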