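#' @importFrom rlang .data
NULL

FLAG_SECONDARY <- 256L
FLAG_SUPPLEMENTARY <- 2048L

# CIGAR walk: reference blocks (M/=/X runs) with the query offset of each
# block start, plus deletion spans (query gap). N skips and I/S ops advance
# one cursor only. Returns one tibble row per block/deletion per alignment.
alignment_blocks <- function(alignments, include_deletions = FALSE) {
  if (nrow(alignments) == 0) {
    return(tibble::tibble(
      aln = integer(), read_id = character(), chrom = character(),
      ref_start = integer(), ref_end = integer(), q_start = integer(),
      is_deletion = logical()
    ))
  }
  ops <- stringr::str_match_all(alignments$cigar, "(\\d+)([MIDNSHP=X])")
  out <- vector("list", nrow(alignments))
  for (i in seq_len(nrow(alignments))) {
    m <- ops[[i]]
    len <- as.integer(m[, 2]); op <- m[, 3]
    ref <- alignments$pos[i]; q <- 0L
    rs <- integer(0); re <- integer(0); qs <- integer(0); del <- logical(0)
    for (j in seq_along(op)) {
      o <- op[j]; l <- len[j]
      if (o %in% c("M", "=", "X")) {
        rs <- c(rs, ref); re <- c(re, ref + l); qs <- c(qs, q); del <- c(del, FALSE)
        ref <- ref + l; q <- q + l
      } else if (o %in% c("I", "S")) {
        q <- q + l
      } else if (o == "D") {
        if (include_deletions) {
          rs <- c(rs, ref); re <- c(re, ref + l); qs <- c(qs, NA_integer_)
          del <- c(del, TRUE)
        }
        ref <- ref + l
      } else if (o == "N") {
        ref <- ref + l
      } # H, P: consume nothing we track
    }
    out[[i]] <- tibble::tibble(
      aln = i, read_id = alignments$read_id[i], chrom = alignments$chrom[i],
      ref_start = rs, ref_end = re, q_start = qs, is_deletion = del
    )
  }
  dplyr::bind_rows(out)
}

#' Observed bases at phased SNVs covered by spliced alignments
#'
#' Walks each alignment's CIGAR to locate, for every phased variant falling
#' inside an aligned match block, the query base (and its base quality)
#' placed on that reference position. Variants under intron skips are not
#' reported; variants under deletions are reported with `observed_base` NA
#' (a gap).
#'
#' @param alignments Alignment tibble (see [sim_reads()] for the schema).
#' @param variants Phased variant tibble (`chrom`, `pos` 0-based,
#'   `maternal_base`, `paternal_base`).
#' @return Tibble with one row per (alignment, covered variant):
#'   `aln` (row index into `alignments`), `read_id`, `chrom`, `pos`,
#'   `maternal_base`, `paternal_base`, `observed_base` (NA for gaps),
#'   `base_quality` (Phred, NA for gaps).
#' @export
read_alleles <- function(alignments, variants) {
  blocks <- alignment_blocks(alignments, include_deletions = TRUE)
  empty <- tibble::tibble(
    aln = integer(), read_id = character(), chrom = character(),
    pos = integer(), maternal_base = character(), paternal_base = character(),
    observed_base = character(), base_quality = integer()
  )
  if (nrow(blocks) == 0 || nrow(variants) == 0) return(empty)

  res <- list()
  for (ch in intersect(unique(blocks$chrom), unique(variants$chrom))) {
    b <- blocks[blocks$chrom == ch, ]
    v <- variants[variants$chrom == ch, ]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(v$pos + 1L, v$pos + 1L),
      IRanges::IRanges(b$ref_start + 1L, b$ref_end)
    )
    if (length(hits) == 0) next
    vi <- S4Vectors::queryHits(hits); bi <- S4Vectors::subjectHits(hits)
    qpos <- b$q_start[bi] + (v$pos[vi] - b$ref_start[bi])  # NA under deletions
    arow <- b$aln[bi]
    obs <- ifelse(
      is.na(qpos), NA_character_,
      substr(alignments$seq[arow], qpos + 1L, qpos + 1L)
    )
    bq <- ifelse(
      is.na(qpos), NA_integer_,
      vapply(seq_along(qpos), function(k) {
        if (is.na(qpos[k])) return(NA_integer_)
        utf8ToInt(substr(alignments$qual[arow[k]], qpos[k] + 1L, qpos[k] + 1L)) - 33L
      }, integer(1))
    )
    res[[length(res) + 1L]] <- tibble::tibble(
      aln = arow, read_id = b$read_id[bi], chrom = ch,
      pos = v$pos[vi], maternal_base = v$maternal_base[vi],
      paternal_base = v$paternal_base[vi],
      observed_base = obs, base_quality = as.integer(bq)
    )
  }
  if (length(res) == 0) return(empty)
  dplyr::bind_rows(res) |> dplyr::arrange(.data$aln, .data$pos)
}

vote_labels <- function(m, p) {
  dplyr::case_when(m > p ~ "M", p > m ~ "P", TRUE ~ "U")
}

#' Haplotype-tag a single read by majority vote over covered SNVs
#'
#' Pools votes over all primary and supplementary records of one read: a
#' covered variant votes maternal when the observed base equals the maternal
#' allele (at sufficient base quality), paternal likewise; bases matching
#' neither allele count as mismatches and never break ties. Ties (including
#' zero coverage) are untagged.
#'
#' @param records Alignment tibble rows sharing one `read_id`.
#' @param variants Phased variant tibble.
#' @param min_base_quality Minimum Phred base quality for a vote (default 0;
#'   HiFi-grade reads need no filtering).
#' @return One-row tibble: `read_id`, `label` (`"MATERNAL"`, `"PATERNAL"`,
#'   `"UNTAGGED"`), `maternal_votes`, `paternal_votes`, `mismatch_votes`.
#' @export
tag_read <- function(records, variants, min_base_quality = 0L) {
  if (nrow(records) == 0) rlang::abort("tag_read requires at least one record")
  if (length(unique(records$read_id)) != 1L) {
    rlang::abort("tag_read expects records of a single read")
  }
  records <- records[bitwAnd(records$flag, FLAG_SECONDARY) == 0L, ]
  if (nrow(records) == 0) rlang::abort("tag_read received only secondary alignments")
  al <- read_alleles(records, variants)
  al <- al[!is.na(al$observed_base) & al$base_quality >= min_base_quality, ]
  m <- sum(al$observed_base == al$maternal_base)
  p <- sum(al$observed_base == al$paternal_base)
  x <- nrow(al) - m - p
  lab <- c(M = "MATERNAL", P = "PATERNAL", U = "UNTAGGED")[vote_labels(m, p)]
  tibble::tibble(
    read_id = records$read_id[1], label = unname(lab),
    maternal_votes = m, paternal_votes = p, mismatch_votes = x
  )
}

#' Assign every read to its parental haplotype
#'
#' Re-implementation of the haplotag stage: for each read, votes from all
#' phased SNVs covered by its primary and supplementary alignments are
#' pooled and the read is labelled maternal (`"M"`), paternal (`"P"`) or
#' untagged (`"U"`) by simple majority (ties untagged). Every record of a
#' read inherits the read-level tag; secondary alignments neither vote nor
#' receive a tag. Reads on chromosomes absent from the variant set are
#' untagged with a warning.
#'
#' @param alignments Alignment tibble.
#' @param variants Phased variant tibble.
#' @param min_base_quality Minimum Phred base quality for a vote.
#' @return The input tibble with columns `haplotype`, `maternal_votes`,
#'   `paternal_votes`, `mismatch_votes` appended; attribute `summary` holds
#'   a per-label tibble (`label`, `n_reads`, `n_votes_mean`).
#' @export
haplotag <- function(alignments, variants, min_base_quality = 0L) {
  secondary <- bitwAnd(alignments$flag, FLAG_SECONDARY) != 0L
  missing_chrom <- setdiff(unique(alignments$chrom), unique(variants$chrom))
  if (length(missing_chrom) > 0 && nrow(alignments) > 0) {
    rlang::warn(paste0(
      "no phased variants on: ", paste(missing_chrom, collapse = ", "),
      "; reads there stay untagged"
    ))
  }

  al <- read_alleles(alignments[!secondary, , drop = FALSE], variants)
  al <- al[!is.na(al$observed_base) & al$base_quality >= min_base_quality, ]
  votes <- al |>
    dplyr::mutate(
      vm = .data$observed_base == .data$maternal_base,
      vp = .data$observed_base == .data$paternal_base
    ) |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      maternal_votes = sum(.data$vm),
      paternal_votes = sum(.data$vp),
      mismatch_votes = dplyr::n() - sum(.data$vm) - sum(.data$vp),
      .groups = "drop"
    )

  out <- alignments |>
    dplyr::left_join(votes, by = "read_id") |>
    dplyr::mutate(
      maternal_votes = dplyr::coalesce(.data$maternal_votes, 0L),
      paternal_votes = dplyr::coalesce(.data$paternal_votes, 0L),
      mismatch_votes = dplyr::coalesce(.data$mismatch_votes, 0L),
      haplotype = vote_labels(.data$maternal_votes, .data$paternal_votes)
    )
  out$haplotype[secondary] <- "U"

  reads <- out |>
    dplyr::filter(bitwAnd(.data$flag, FLAG_SECONDARY) == 0L) |>
    dplyr::distinct(
      .data$read_id, .data$haplotype,
      .data$maternal_votes, .data$paternal_votes
    )
  summary <- reads |>
    dplyr::group_by(label = .data$haplotype) |>
    dplyr::summarise(
      n_reads = dplyr::n(),
      n_votes_mean = mean(.data$maternal_votes + .data$paternal_votes),
      .groups = "drop"
    )
  attr(out, "summary") <- summary
  out
}

#' Split tagged alignments into haplotype streams
#'
#' Partitions records by the read-level haplotype tag: every record lands in
#' exactly one of the maternal, paternal or untagged streams.
#'
#' @param tagged Output of [haplotag()].
#' @return Named list of tibbles `maternal`, `paternal`, `untagged`.
#' @export
split_by_haplotype <- function(tagged) {
  if (!"haplotype" %in% names(tagged)) {
    rlang::abort("input has no haplotype column; run haplotag() first")
  }
  list(
    maternal = dplyr::filter(tagged, .data$haplotype == "M"),
    paternal = dplyr::filter(tagged, .data$haplotype == "P"),
    untagged = dplyr::filter(tagged, .data$haplotype == "U")
  )
}
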