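#' Configuration for the synthetic F1-hybrid simulator
#'
#' The generator emulates an F1 hybrid between two inbred strains whose
#' exonic SNVs make parental read assignment possible: a small diploid
#' genome in which the maternal haplotype is the reference and the paternal
#' haplotype carries the alternate base at every phased SNV. Autosomal genes
#' are biallelic, imprinted (maternally or paternally expressed) or
#' strain-biased; the X chromosome models fully skewed X inactivation with
#' the maternal X active, an Xist-like gene expressed only from the inactive
#' (paternal) X, and a configurable number of escape genes. Optionally one
#' autosomal locus carries four overlapping isoforms with distinct first
#' exons, shared 3' exons and allelic statuses biallelic / maternal-only /
#' paternal-only / silent, mirroring the organisation of the Gnas imprinted
#' cluster.
#'
#' @param seed Integer seed; identical configurations produce byte-identical
#'   outputs.
#' @param chromosomes Tibble with columns `name` and `length` (bp). The
#'   default provides two autosomes and one `chrX`.
#' @param n_genes Genes per chromosome.
#' @param exons_per_gene Integer range (length 2) of exons per gene.
#' @param snp_per_exon_rate Poisson mean of SNVs per exon.
#' @param depth_mean,depth_dispersion Negative-binomial read depth per gene
#'   (mean and size/dispersion), so low-depth genes exercise the
#'   informativeness filter.
#' @param base_error_rate Per-base substitution probability in `[0, 0.05]`.
#' @param gene_class_fractions Named proportions over the autosomal classes
#'   `biallelic`, `maternal_imprinted`, `paternal_imprinted`,
#'   `maternal_strain_bias`, `paternal_strain_bias`; must sum to 1.
#' @param strain_bias_fraction True maternal fraction of a
#'   maternal-strain-biased gene (paternal bias uses its complement).
#' @param xci_skewed If `TRUE`, non-escape X genes are fully maternal and an
#'   Xist-like noncoding gene is fully paternal.
#' @param escape_gene_count Number of X-linked escape genes.
#' @param escape_maternal_fraction True maternal fraction of escape genes.
#' @param include_gnas_like Add the four-isoform imprinted locus.
#' @param antisense_pair_count Number of antisense gene pairs (a single-exon
#'   gene on the opposite strand inside a host gene's intron), which stranded
#'   counting must keep apart.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = tibble::tibble(
                         name = c("chr1", "chr2", "chrX"),
                         length = c(600000L, 600000L, 600000L)
                       ),
                       n_genes = 30L,
                       exons_per_gene = c(2L, 8L),
                       snp_per_exon_rate = 2,
                       depth_mean = 100,
                       depth_dispersion = 8,
                       base_error_rate = 0,
                       gene_class_fractions = c(
                         biallelic = 0.70,
                         maternal_imprinted = 0.10,
                         paternal_imprinted = 0.10,
                         maternal_strain_bias = 0.05,
                         paternal_strain_bias = 0.05
                       ),
                       strain_bias_fraction = 0.85,
                       xci_skewed = TRUE,
                       escape_gene_count = 2L,
                       escape_maternal_fraction = 0.67,
                       include_gnas_like = TRUE,
                       antisense_pair_count = 1L) {
  stopifnot(
    is.numeric(seed), length(seed) == 1,
    all(c("name", "length") %in% names(chromosomes)),
    all(chromosomes$length > 0),
    n_genes >= 0,
    length(exons_per_gene) == 2, exons_per_gene[1] >= 1,
    exons_per_gene[2] >= exons_per_gene[1],
    snp_per_exon_rate >= 0,
    depth_mean > 0, depth_dispersion > 0,
    escape_gene_count >= 0, antisense_pair_count >= 0,
    escape_maternal_fraction >= 0, escape_maternal_fraction <= 1,
    strain_bias_fraction > 0.5, strain_bias_fraction < 1
  )
  if (base_error_rate < 0 || base_error_rate > 0.05) {
    rlang::abort("base_error_rate must be in [0, 0.05]")
  }
  classes <- c("biallelic", "maternal_imprinted", "paternal_imprinted",
               "maternal_strain_bias", "paternal_strain_bias")
  if (!setequal(names(gene_class_fractions), classes)) {
    rlang::abort("gene_class_fractions must be named over the five autosomal classes")
  }
  if (abs(sum(gene_class_fractions) - 1) > 1e-9) {
    rlang::abort("gene_class_fractions must sum to 1")
  }
  structure(
    list(
      seed = as.integer(seed),
      chromosomes = tibble::as_tibble(chromosomes),
      n_genes = as.integer(n_genes),
      exons_per_gene = as.integer(exons_per_gene),
      snp_per_exon_rate = snp_per_exon_rate,
      depth_mean = depth_mean,
      depth_dispersion = depth_dispersion,
      base_error_rate = base_error_rate,
      gene_class_fractions = gene_class_fractions[classes],
      strain_bias_fraction = strain_bias_fraction,
      xci_skewed = isTRUE(xci_skewed),
      escape_gene_count = as.integer(escape_gene_count),
      escape_maternal_fraction = escape_maternal_fraction,
      include_gnas_like = isTRUE(include_gnas_like),
      antisense_pair_count = as.integer(antisense_pair_count)
    ),
    class = "sim_config"
  )
}

BASES <- c("A", "C", "G", "T")

# draw exon/intron structure for one gene inside [slot_start, slot_start+slot)
draw_gene_structure <- function(slot_start, slot, exons_range, chrom, margin = 200L) {
  avail <- slot - margin
  n_ex <- sample(seq(exons_range[1], exons_range[2]), 1L)
  repeat {
    ex_len <- sample(100:400, n_ex, replace = TRUE)
    budget <- avail - sum(ex_len)
    if (n_ex == 1L) {
      if (budget >= 0) break
    } else if (budget >= 200L * (n_ex - 1L)) {
      break
    }
    n_ex <- n_ex - 1L
    if (n_ex < 1L) {
      rlang::abort(paste0("chromosome ", chrom, " too short for requested gene count"))
    }
  }
  if (n_ex > 1L) {
    in_max <- floor(budget / (n_ex - 1L))
    in_len <- sample(200:max(200L, min(1500L, in_max)), n_ex - 1L, replace = TRUE)
  } else {
    in_len <- integer(0)
  }
  starts <- slot_start + cumsum(c(0L, ex_len[-n_ex] + in_len))
  tibble::tibble(start = as.integer(starts), end = as.integer(starts + ex_len))
}

gnas_like_structure <- function(slot_start) {
  # four transcripts: distinct first exons, three shared 3' exons, '+' strand
  first_starts <- slot_start + c(0L, 1200L, 2400L, 3600L)
  shared <- tibble::tibble(
    start = slot_start + c(6000L, 7500L, 9000L),
    end = slot_start + c(6300L, 7800L, 9400L)
  )
  tx <- tibble::tibble(
    transcript_id = paste0("gnasl_", c("nesp", "nespas", "ex1a", "gsa")),
    status = c("maternal_only", "silent", "paternal_only", "biallelic"),
    maternal_fraction = c(1, NA, 0, 0.5),
    weight = c(0.2, 0, 0.3, 0.5)
  )
  exons <- purrr::map2_dfr(tx$transcript_id, first_starts, function(id, fs) {
    dplyr::bind_rows(
      tibble::tibble(start = fs, end = fs + 300L),
      shared
    ) |>
      dplyr::mutate(transcript_id = id)
  })
  list(tx = tx, exons = exons)
}

#' Generate the synthetic diploid genome, variants, annotation and truth
#'
#' Builds a random reference genome, places stranded multi-exon genes on
#' each chromosome, draws phased exonic SNVs (Poisson per exon; maternal
#' allele = reference base, paternal = alternate), assigns every gene a true
#' maternal expression fraction according to its class, and records the
#' ground truth used by recovery tests.
#'
#' @param config A [sim_config()].
#' @return An object of class `sim_genome`: list with `reference`
#'   (a [Biostrings::DNAStringSet]), `variants` (tibble `chrom`, `pos`
#'   0-based, `maternal_base`, `paternal_base`), `annotation`
#'   (an [ase_annotation()]), `truth` (list of tibbles `genes` and
#'   `isoforms`) and the `config`.
#' @export
sim_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  reference <- Biostrings::DNAStringSet(vapply(
    config$chromosomes$length,
    function(n) paste(sample(BASES, n, replace = TRUE), collapse = ""),
    character(1)
  ))
  names(reference) <- config$chromosomes$name

  autosomes <- setdiff(config$chromosomes$name, "chrX")
  gnas_chrom <- if (config$include_gnas_like && length(autosomes) > 0) {
    autosomes[length(autosomes)]
  } else {
    NA_character_
  }

  tx_exons <- list()
  gene_rows <- list()
  iso_truth <- NULL

  for (ci in seq_len(nrow(config$chromosomes))) {
    chrom <- config$chromosomes$name[ci]
    clen <- config$chromosomes$length[ci]
    n <- config$n_genes
    if (n == 0) next
    slot <- clen %/% n
    min_need <- 100L + 200L  # one minimal exon + margin
    if (slot < min_need) {
      rlang::abort(paste0("chromosome ", chrom, " too short for requested gene count"))
    }

    is_x <- chrom == "chrX"
    for (g in seq_len(n)) {
      gid <- sprintf("%s_g%03d", chrom, g)
      slot_start <- as.integer((g - 1L) * slot + sample(0:min(100L, slot - min_need), 1L))

      if (identical(chrom, gnas_chrom) && g == n) {
        gl <- gnas_like_structure(slot_start)
        iso_truth <- gl$tx |> dplyr::mutate(gene_id = "gnasl", .before = 1)
        tx_exons[[length(tx_exons) + 1L]] <- gl$exons |>
          dplyr::mutate(gene_id = "gnasl", chrom = chrom, strand = "+")
        gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
          gene_id = "gnasl", chrom = chrom, strand = "+",
          class = "gnas_like", biotype = "coding", is_x_linked = FALSE,
          true_maternal_fraction =
            sum(gl$tx$weight * dplyr::coalesce(gl$tx$maternal_fraction, 0)) /
            sum(gl$tx$weight)
        )
        next
      }

      strand <- sample(c("+", "-"), 1L)
      ex <- draw_gene_structure(slot_start, slot, config$exons_per_gene, chrom)
      tx_exons[[length(tx_exons) + 1L]] <- ex |>
        dplyr::mutate(
          transcript_id = paste0(gid, "_t1"), gene_id = gid,
          chrom = chrom, strand = strand
        )
      cls <- if (is_x) "xci_subject" else {
        sample(names(config$gene_class_fractions), 1L,
               prob = config$gene_class_fractions)
      }
      gene_rows[[length(gene_rows) + 1L]] <- tibble::tibble(
        gene_id = gid, chrom = chrom, strand = strand, class = cls,
        biotype = "coding", is_x_linked = is_x,
        true_maternal_fraction = NA_real_
      )
    }
  }

  if (length(gene_rows) == 0) {
    genes <- tibble::tibble(
      gene_id = character(), chrom = character(), strand = character(),
      class = character(), biotype = character(), is_x_linked = logical(),
      true_maternal_fraction = double()
    )
    tx_exons <- tibble::tibble(
      start = integer(), end = integer(), transcript_id = character(),
      gene_id = character(), chrom = character(), strand = character()
    )
  } else {
    genes <- dplyr::bind_rows(gene_rows)
    tx_exons <- dplyr::bind_rows(tx_exons)
  }

  # X-chromosome roles under the skewed-XCI design
  if (any(genes$is_x_linked) && config$xci_skewed) {
    xg <- genes$gene_id[genes$is_x_linked]
    n_special <- min(length(xg), 1L + config$escape_gene_count)
    special <- sample(xg, n_special)
    if (n_special >= 1L) {
      genes$class[genes$gene_id == special[1]] <- "xist_like"
      genes$biotype[genes$gene_id == special[1]] <- "noncoding"
    }
    if (n_special >= 2L) {
      genes$class[genes$gene_id %in% special[-1]] <- "xci_escape"
    }
  }

  genes <- genes |>
    dplyr::mutate(true_maternal_fraction = dplyr::case_when(
      !is.na(.data$true_maternal_fraction) ~ .data$true_maternal_fraction,
      .data$class == "biallelic" ~ 0.5,
      .data$class == "maternal_imprinted" ~ 1,
      .data$class == "paternal_imprinted" ~ 0,
      .data$class == "maternal_strain_bias" ~ config$strain_bias_fraction,
      .data$class == "paternal_strain_bias" ~ 1 - config$strain_bias_fraction,
      .data$class == "xci_subject" & config$xci_skewed ~ 1,
      .data$class == "xci_subject" ~ 0.5,
      .data$class == "xci_escape" ~ config$escape_maternal_fraction,
      .data$class == "xist_like" ~ 0
    ))

  # antisense partners: a single-exon gene on the opposite strand inside a
  # host intron on the first autosome (stranded counting must separate them)
  if (config$antisense_pair_count > 0 && length(autosomes) > 0 && config$n_genes > 0) {
    host_chrom <- autosomes[1]
    hosts <- tx_exons |>
      dplyr::filter(.data$chrom == host_chrom, .data$gene_id != "gnasl") |>
      dplyr::group_by(.data$gene_id, .data$strand) |>
      dplyr::summarise(
        n_ex = dplyr::n(),
        gap_start = ifelse(dplyr::n() > 1, .data$end[1], NA_integer_),
        gap_end = ifelse(dplyr::n() > 1, .data$start[2], NA_integer_),
        .groups = "drop"
      ) |>
      dplyr::filter(.data$n_ex > 1, .data$gap_end - .data$gap_start >= 800L)
    n_pairs <- min(config$antisense_pair_count, nrow(hosts))
    if (n_pairs > 0) {
      for (k in seq_len(n_pairs)) {
        h <- hosts[k, ]
        gid <- paste0(h$gene_id, "_as")
        mid <- as.integer((h$gap_start + h$gap_end) %/% 2L)
        st <- if (h$strand == "+") "-" else "+"
        tx_exons <- dplyr::bind_rows(tx_exons, tibble::tibble(
          start = mid - 150L, end = mid + 150L,
          transcript_id = paste0(gid, "_t1"), gene_id = gid,
          chrom = host_chrom, strand = st
        ))
        genes <- dplyr::bind_rows(genes, tibble::tibble(
          gene_id = gid, chrom = host_chrom, strand = st,
          class = "biallelic", biotype = "noncoding", is_x_linked = FALSE,
          true_maternal_fraction = 0.5
        ))
      }
    }
  }

  annotation <- if (nrow(tx_exons) > 0) {
    ase_annotation(tx_exons, genes)
  } else {
    empty_annotation()
  }

  variants <- draw_variants(annotation, reference, config$snp_per_exon_rate)

  structure(
    list(
      reference = reference,
      variants = variants,
      annotation = annotation,
      truth = list(
        genes = genes |>
          dplyr::select("gene_id", "chrom", "strand", "class", "biotype",
                        "is_x_linked", "true_maternal_fraction"),
        isoforms = iso_truth
      ),
      config = config
    ),
    class = "sim_genome"
  )
}

empty_annotation <- function() {
  structure(
    list(
      genes = tibble::tibble(
        gene_id = character(), chrom = character(), strand = character(),
        is_x_linked = logical(), biotype = character()
      ),
      gene_exons = tibble::tibble(
        gene_id = character(), chrom = character(), strand = character(),
        start = integer(), end = integer()
      ),
      transcripts = tibble::tibble(
        transcript_id = character(), gene_id = character(), chrom = character(),
        strand = character(), n_exons = integer(), start = integer(),
        end = integer(), first_exon_start = integer(), first_exon_end = integer()
      ),
      tx_exons = tibble::tibble(
        transcript_id = character(), gene_id = character(), chrom = character(),
        strand = character(), start = integer(), end = integer(),
        exon_rank = integer()
      )
    ),
    class = "ase_annotation"
  )
}

draw_variants <- function(annotation, reference, rate) {
  ge <- annotation$gene_exons
  if (nrow(ge) == 0 || rate == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(),
      maternal_base = character(), paternal_base = character()
    ))
  }
  k <- stats::rpois(nrow(ge), rate)
  rows <- purrr::pmap_dfr(
    list(ge$chrom, ge$start, ge$end, k),
    function(chrom, start, end, ki) {
      ki <- min(ki, end - start)
      if (ki == 0) return(NULL)
      tibble::tibble(chrom = chrom, pos = sort(sample(start:(end - 1L), ki)))
    }
  )
  if (nrow(rows) == 0) {
    return(tibble::tibble(
      chrom = character(), pos = integer(),
      maternal_base = character(), paternal_base = character()
    ))
  }
  rows <- dplyr::distinct(rows, .data$chrom, .data$pos) |>
    dplyr::arrange(.data$chrom, .data$pos)
  ref_base <- vapply(seq_len(nrow(rows)), function(i) {
    as.character(Biostrings::subseq(
      reference[[rows$chrom[i]]], rows$pos[i] + 1L, rows$pos[i] + 1L
    ))
  }, character(1))
  alt_base <- vapply(ref_base, function(b) sample(setdiff(BASES, b), 1L), character(1))
  rows |>
    dplyr::mutate(
      pos = as.integer(.data$pos),
      maternal_base = ref_base, paternal_base = unname(alt_base)
    )
}

# spliced haplotype sequence of a transcript (reference-forward orientation)
spliced_sequences <- function(exons, chrom_seq, variants) {
  exons <- dplyr::arrange(exons, .data$start)
  mat <- paste0(
    vapply(seq_len(nrow(exons)), function(i) {
      as.character(Biostrings::subseq(chrom_seq, exons$start[i] + 1L, exons$end[i]))
    }, character(1)),
    collapse = ""
  )
  # map variant reference positions into spliced coordinates
  offs <- cumsum(c(0L, (exons$end - exons$start)[-nrow(exons)]))
  vpos <- integer(0); valt <- character(0)
  if (nrow(variants) > 0) {
    for (i in seq_len(nrow(exons))) {
      inx <- variants$pos >= exons$start[i] & variants$pos < exons$end[i]
      if (any(inx)) {
        vpos <- c(vpos, offs[i] + variants$pos[inx] - exons$start[i])
        valt <- c(valt, variants$paternal_base[inx])
      }
    }
  }
  pat <- mat
  if (length(vpos) > 0) {
    pv <- strsplit(pat, "", fixed = TRUE)[[1]]
    pv[vpos + 1L] <- valt
    pat <- paste(pv, collapse = "")
  }
  list(maternal = mat, paternal = pat)
}

inject_errors <- function(seqs, error_rate) {
  if (error_rate == 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, error_rate)
    if (k == 0) return(s)
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    at <- sample.int(n, k)
    v[at] <- vapply(v[at], function(b) sample(setdiff(BASES, b), 1L), character(1))
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate spliced long-read alignments with known allelic origin
#'
#' Draws a negative-binomial read depth per gene, assigns each read to a
#' haplotype according to the gene's (or, at the multi-isoform locus, the
#' transcript's) true maternal fraction, builds full-length spliced
#' alignments (match blocks over exons, skip operations over introns) whose
#' bases carry the originating haplotype's alleles at covered SNVs, then
#' applies uniform per-base substitution errors.
#'
#' @param genome A [sim_genome()].
#' @param config The matching [sim_config()]; defaults to the one stored in
#'   `genome`.
#' @return List with `alignments` (tibble: `read_id`, `chrom`, `strand`,
#'   `pos` 0-based, `cigar`, `seq`, `qual`, `flag`) and `truth` (tibble:
#'   `read_id`, `gene_id`, `transcript_id`, `haplotype` `"M"`/`"P"`).
#' @export
sim_reads <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(config$seed + 1L)

  ann <- genome$annotation
  gtruth <- genome$truth$genes
  iso <- genome$truth$isoforms
  aln <- list(); tru <- list()

  for (gi in seq_len(nrow(gtruth))) {
    g <- gtruth[gi, ]
    depth <- stats::rnbinom(1L, mu = config$depth_mean, size = config$depth_dispersion)
    if (depth == 0) next
    chrom_seq <- genome$reference[[g$chrom]]
    gvars <- dplyr::filter(genome$variants, .data$chrom == g$chrom)

    if (!is.null(iso) && g$gene_id %in% iso$gene_id) {
      itx <- dplyr::filter(iso, .data$gene_id == g$gene_id)
      tx_pick <- sample(itx$transcript_id, depth, replace = TRUE, prob = itx$weight)
      mf <- itx$maternal_fraction[match(tx_pick, itx$transcript_id)]
    } else {
      tx_pick <- rep(paste0(g$gene_id, "_t1"), depth)
      mf <- rep(g$true_maternal_fraction, depth)
    }
    hap <- ifelse(stats::runif(depth) < mf, "M", "P")

    for (tx in unique(tx_pick)) {
      idx <- which(tx_pick == tx)
      exons <- ann$tx_exons |>
        dplyr::filter(.data$transcript_id == tx) |>
        dplyr::arrange(.data$start)
      sp <- spliced_sequences(exons, chrom_seq, gvars)
      widths <- exons$end - exons$start
      gaps <- if (nrow(exons) > 1) exons$start[-1] - exons$end[-nrow(exons)] else integer(0)
      cig <- paste0(widths, "M")
      if (length(gaps) > 0) {
        cig <- c(rbind(cig[-length(cig)], paste0(gaps, "N")), cig[length(cig)])
      }
      cigar <- paste(cig, collapse = "")
      seqs <- ifelse(hap[idx] == "M", sp$maternal, sp$paternal)
      seqs <- inject_errors(seqs, config$base_error_rate)
      tx_strand <- exons$strand[1]
      tx_flag <- if (tx_strand == "-") 16L else 0L
      rid <- sprintf("%s_r%05d", g$gene_id, idx)
      aln[[length(aln) + 1L]] <- tibble::tibble(
        read_id = rid, chrom = g$chrom, strand = tx_strand,
        pos = exons$start[1], cigar = cigar, seq = seqs,
        qual = strrep("I", nchar(seqs[1])),
        flag = tx_flag
      )
      tru[[length(tru) + 1L]] <- tibble::tibble(
        read_id = rid, gene_id = g$gene_id, transcript_id = tx,
        haplotype = hap[idx]
      )
    }
  }

  alignments <- if (length(aln) > 0) {
    dplyr::bind_rows(aln) |> dplyr::arrange(.data$chrom, .data$pos, .data$read_id)
  } else {
    tibble::tibble(
      read_id = character(), chrom = character(), strand = character(),
      pos = integer(), cigar = character(), seq = character(),
      qual = character(), flag = integer()
    )
  }
  truth <- if (length(tru) > 0) dplyr::bind_rows(tru) else {
    tibble::tibble(
      read_id = character(), gene_id = character(),
      transcript_id = character(), haplotype = character()
    )
  }
  list(alignments = alignments, truth = truth)
}

#' Resample an allelic count table from simulated truth
#'
#' Emulates an independently sequenced dataset of the same biological
#' sample (for example a short-read experiment processed by an external
#' allelic pipeline): per-gene depth is drawn anew from a negative binomial
#' and maternal counts binomially from the gene's true maternal fraction.
#' Useful as the second table in concordance analyses.
#'
#' @param genome A [sim_genome()].
#' @param depth_mean,depth_dispersion Negative-binomial depth parameters.
#' @param seed Integer seed.
#' @return Tibble with columns `gene_id`, `chrom`, `strand`, `biotype`,
#'   `is_x_linked`, `maternal`, `paternal`, `untagged`, `snp_overlap_reads`.
#' @export
sim_count_table <- function(genome, depth_mean = 500, depth_dispersion = 8,
                            seed = genome$config$seed + 2L) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(seed)
  gt <- genome$truth$genes
  n <- stats::rnbinom(nrow(gt), mu = depth_mean, size = depth_dispersion)
  m <- stats::rbinom(nrow(gt), n, gt$true_maternal_fraction)
  tibble::tibble(
    gene_id = gt$gene_id, chrom = gt$chrom, strand = gt$strand,
    biotype = gt$biotype, is_x_linked = gt$is_x_linked,
    maternal = m, paternal = n - m, untagged = 0L,
    snp_overlap_reads = n
  )
}

#' Write the simulated dataset to standard formats
#'
#' Writes the reference FASTA, phased-SNV VCF (one sample, `0|1` with the
#' maternal allele as REF), annotation GTF, coordinate-sorted SAM and the
#' read/gene truth TSVs. All files round-trip through the package's readers.
#'
#' @param genome A [sim_genome()].
#' @param reads Result of [sim_reads()].
#' @param outdir Output directory (created if needed).
#' @return Tibble with columns `kind` and `path`.
#' @export
write_fixtures <- function(genome, reads, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(paste0("cannot create output directory: ", outdir))
  }
  ref_lengths <- stats::setNames(
    Biostrings::width(genome$reference), names(genome$reference)
  )
  paths <- tibble::tibble(
    kind = c("fasta", "vcf", "gtf", "sam", "truth", "gene_truth"),
    path = file.path(outdir, c(
      "reference.fa", "variants.vcf", "annotation.gtf",
      "alignments.sam", "read_truth.tsv", "gene_truth.tsv"
    ))
  )
  Biostrings::writeXStringSet(genome$reference, paths$path[1])
  write_vcf(genome$variants, paths$path[2], ref_lengths)
  write_annotation_gtf(genome$annotation, paths$path[3])
  write_sam(reads$alignments, paths$path[4], ref_lengths)
  readr::write_tsv(reads$truth, paths$path[5])
  readr::write_tsv(genome$truth$genes, paths$path[6])
  paths
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
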