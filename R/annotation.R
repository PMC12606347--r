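#' Build a stranded gene/transcript annotation object
#'
#' Container for the exon structures used throughout the pipeline: per-gene
#' merged exon unions (for union-mode gene counting) and per-transcript
#' ordered exon chains (for first-exon-anchored isoform assignment).
#' All coordinates are 0-based half-open; conversion to the 1-based
#' conventions of GTF happens only in [read_annotation()] and
#' [write_annotation_gtf()].
#'
#' @param tx_exons Tibble of transcript exons with columns `transcript_id`,
#'   `gene_id`, `chrom`, `strand` (`"+"` or `"-"`), `start`, `end`
#'   (0-based half-open).
#' @param genes Tibble of gene metadata with columns `gene_id`, `biotype`
#'   (`"coding"` or `"noncoding"`); `chrom`, `strand` and `is_x_linked` are
#'   derived from the exons when absent.
#' @param x_chrom Chromosome name treated as the X when deriving
#'   `is_x_linked`.
#'
#' @return An object of class `ase_annotation`: a list of tibbles `genes`,
#'   `gene_exons` (merged union per gene), `transcripts` (with first-exon
#'   coordinates) and `tx_exons` (with 5'-to-3' `exon_rank`).
#' @export
ase_annotation <- function(tx_exons, genes = NULL, x_chrom = "chrX") {
  req <- c("transcript_id", "gene_id", "chrom", "strand", "start", "end")
  miss <- setdiff(req, names(tx_exons))
  if (length(miss) > 0) {
    rlang::abort(paste0("tx_exons is missing columns: ", paste(miss, collapse = ", ")))
  }
  tx_exons <- tibble::as_tibble(tx_exons) |>
    dplyr::mutate(start = as.integer(.data$start), end = as.integer(.data$end))
  if (any(tx_exons$end <= tx_exons$start)) {
    rlang::abort("tx_exons contains empty or reversed intervals")
  }
  if (!all(tx_exons$strand %in% c("+", "-"))) {
    rlang::abort("strand must be '+' or '-'")
  }

  tx_exons <- tx_exons |>
    dplyr::arrange(.data$chrom, .data$gene_id, .data$transcript_id, .data$start) |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::mutate(
      exon_rank = if (.data$strand[1] == "+") dplyr::row_number()
                  else dplyr::n() - dplyr::row_number() + 1L
    ) |>
    dplyr::ungroup()

  transcripts <- tx_exons |>
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$chrom, .data$strand) |>
    dplyr::summarise(
      n_exons = dplyr::n(),
      start = min(.data$start),
      end = max(.data$end),
      first_exon_start = .data$start[.data$exon_rank == 1L],
      first_exon_end = .data$end[.data$exon_rank == 1L],
      .groups = "drop"
    )

  # gene exon union is rebuilt from transcripts; gene records are not trusted
  gene_exons <- tx_exons |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::group_modify(function(d, key) {
      ir <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
      tibble::tibble(start = BiocGenerics::start(ir) - 1L, end = BiocGenerics::end(ir))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chrom, .data$start)

  gene_meta <- gene_exons |>
    dplyr::distinct(.data$gene_id, .data$chrom, .data$strand) |>
    dplyr::mutate(is_x_linked = .data$chrom == x_chrom)
  if (!is.null(genes) && nrow(genes) > 0) {
    keep <- intersect(c("gene_id", "biotype", "is_x_linked"), names(genes))
    gene_meta <- gene_meta |>
      dplyr::select(-dplyr::any_of(setdiff(keep, "gene_id"))) |>
      dplyr::left_join(dplyr::select(genes, dplyr::all_of(keep)), by = "gene_id")
  }
  if (!"biotype" %in% names(gene_meta)) gene_meta$biotype <- "coding"
  gene_meta$biotype[is.na(gene_meta$biotype)] <- "coding"

  structure(
    list(
      genes = gene_meta,
      gene_exons = gene_exons,
      transcripts = transcripts,
      tx_exons = tx_exons
    ),
    class = "ase_annotation"
  )
}

#' @export
print.ase_annotation <- function(x, ...) {
  cat(
    "<ase_annotation> ", nrow(x$genes), " genes, ",
    nrow(x$transcripts), " transcripts on ",
    length(unique(x$genes$chrom)), " chromosome(s)\n",
    sep = ""
  )
  invisible(x)
}

# GRanges of merged gene exons, one range per exon, gene_id in mcols
gene_exon_granges <- function(annotation, seqlevels = NULL) {
  ge <- annotation$gene_exons
  lv <- unique(c(seqlevels, ge$chrom))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(ge$chrom, levels = lv),
    ranges = IRanges::IRanges(ge$start + 1L, ge$end),
    strand = ge$strand
  )
  S4Vectors::mcols(gr)$gene_id <- ge$gene_id
  gr
}
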