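# Independent brute-force oracles used to check the CIGAR walk, the voting
# tagger and the union-mode gene assigner. These expand alignments base by
# base (or enumerate gene/exon pairs) instead of using interval arithmetic,
# so they share no code path with the implementation.

# full per-base query-to-reference map of one alignment
oracle_expand_alignment <- function(pos, cigar, seq, qual) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")[[1]]
  ref <- pos; q <- 0L
  out_ref <- integer(0); out_q <- integer(0)
  for (j in seq_len(nrow(m))) {
    l <- as.integer(m[j, 2]); o <- m[j, 3]
    if (o %in% c("M", "=", "X")) {
      out_ref <- c(out_ref, ref:(ref + l - 1L))
      out_q <- c(out_q, q:(q + l - 1L))
      ref <- ref + l; q <- q + l
    } else if (o %in% c("I", "S")) {
      q <- q + l
    } else if (o %in% c("D", "N")) {
      ref <- ref + l
    }
  }
  data.frame(
    ref = out_ref,
    base = substring(seq, out_q + 1L, out_q + 1L),
    quality = utf8ToInt(qual)[out_q + 1L] - 33L
  )
}

# majority-vote tagger over the per-base expansion
oracle_tag <- function(records, variants, min_base_quality = 0L) {
  m <- 0L; p <- 0L; x <- 0L
  for (i in seq_len(nrow(records))) {
    if (bitwAnd(records$flag[i], 256L) != 0L) next
    exp <- oracle_expand_alignment(
      records$pos[i], records$cigar[i], records$seq[i], records$qual[i]
    )
    v <- variants[variants$chrom == records$chrom[i], ]
    hit <- merge(exp, v, by.x = "ref", by.y = "pos")
    hit <- hit[hit$quality >= min_base_quality, , drop = FALSE]
    m <- m + sum(hit$base == hit$maternal_base)
    p <- p + sum(hit$base == hit$paternal_base)
    x <- x + sum(hit$base != hit$maternal_base & hit$base != hit$paternal_base)
  }
  label <- if (m > p) "MATERNAL" else if (p > m) "PATERNAL" else "UNTAGGED"
  list(label = label, maternal = m, paternal = p, mismatch = x)
}

# exhaustive overlap enumerator for union-mode gene assignment
oracle_assign_gene <- function(blocks, strand, gene_exons, stranded = TRUE) {
  hits <- character(0)
  for (g in unique(gene_exons$gene_id)) {
    ge <- gene_exons[gene_exons$gene_id == g, ]
    if (stranded && ge$strand[1] != strand) next
    found <- FALSE
    for (i in seq_len(nrow(ge))) {
      for (j in seq_len(nrow(blocks))) {
        if (blocks$ref_start[j] < ge$end[i] && ge$start[i] < blocks$ref_end[j]) {
          found <- TRUE
        }
      }
    }
    if (found) hits <- c(hits, g)
  }
  if (length(hits) == 0) "no_feature"
  else if (length(hits) == 1) hits
  else "ambiguous"
}

# two-pass covariance Pearson (textbook formula)
oracle_pearson <- function(x, y) {
  dx <- x - mean(x); dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# random spliced alignment over a reference of given length
random_alignment <- function(id, chrom = "chr1", chrom_len = 10000L) {
  n_blocks <- sample(1:4, 1)
  pos <- sample.int(chrom_len %/% 2, 1) - 1L
  cig <- character(0)
  qlen <- 0L
  lead_s <- sample(0:6, 1)
  if (lead_s > 0) { cig <- c(cig, paste0(lead_s, "S")); qlen <- qlen + lead_s }
  for (b in seq_len(n_blocks)) {
    mlen <- sample(5:60, 1)
    cig <- c(cig, paste0(mlen, "M")); qlen <- qlen + mlen
    if (b < n_blocks) {
      gap_op <- sample(c("N", "D", "I"), 1)
      glen <- if (gap_op == "N") sample(20:200, 1) else sample(1:5, 1)
      cig <- c(cig, paste0(glen, gap_op))
      if (gap_op == "I") qlen <- qlen + glen
    }
  }
  seq <- paste(sample(c("A", "C", "G", "T"), qlen, replace = TRUE), collapse = "")
  qual <- paste(intToUtf8(sample(33:73, qlen, replace = TRUE), multiple = TRUE),
                collapse = "")
  tibble::tibble(
    read_id = id, chrom = chrom, strand = sample(c("+", "-"), 1),
    pos = pos, cigar = paste(cig, collapse = ""), seq = seq, qual = qual,
    flag = 0L
  )
}

random_variants <- function(chrom = "chr1", chrom_len = 10000L, n = 400L) {
  pos <- sort(sample.int(chrom_len, n) - 1L)
  mat <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  pat <- vapply(mat, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1))
  tibble::tibble(chrom = chrom, pos = pos,
                 maternal_base = mat, paternal_base = unname(pat))
}

# reference match blocks of one alignment row, derived from the per-base
# expansion (independent of alignment_blocks)
read_blocks_of <- function(a) {
  exp <- oracle_expand_alignment(a$pos, a$cigar, a$seq, a$qual)
  r <- sort(unique(exp$ref))
  if (length(r) == 0) {
    return(data.frame(ref_start = integer(0), ref_end = integer(0)))
  }
  grp <- cumsum(c(1L, diff(r) != 1L))
  do.call(rbind, lapply(split(r, grp), function(v) {
    data.frame(ref_start = min(v), ref_end = max(v) + 1L)
  }))
}
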