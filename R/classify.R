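#' Allelic ratio: maternal over tagged total
#'
#' `maternal / (maternal + paternal)`, so 1 is fully maternal and 0 fully
#' paternal. Undefined (NA) when no tagged reads exist; vectorised.
#'
#' @param maternal,paternal Non-negative counts.
#' @return Numeric vector in `[0, 1]` with NA where the total is zero.
#' @export
allelic_ratio <- function(maternal, paternal) {
  stopifnot(all(maternal >= 0, na.rm = TRUE), all(paternal >= 0, na.rm = TRUE))
  total <- maternal + paternal
  ifelse(total > 0, maternal / total, NA_real_)
}

#' Classification thresholds
#'
#' Defaults follow the hard-cutoff scheme used for F1-hybrid allelic calls:
#' a gene is informative with at least `min_informative_reads` reads
#' overlapping an SNV (10 for long reads; use 20 for short-read tables);
#' ratios at or above `high_cut` (0.7) are maternal, at or below `low_cut`
#' (0.3) paternal, anything strictly between is biallelic. Under skewed XCI
#' with the maternal X active, X genes above `xci_subject_ratio` (0.9) are
#' subject to inactivation; escape candidates additionally need
#' `min_inactive_reads` reads from the inactive allele.
#'
#' @param min_informative_reads Minimum SNV-overlapping reads per feature.
#' @param low_cut,high_cut Ratio cutoffs; boundary values are
#'   allele-specific (`<=` / `>=`).
#' @param xci_subject_ratio Ratio above which an X gene is called subject
#'   to XCI.
#' @param min_inactive_reads Minimum inactive-X reads for an escape call.
#' @return List of class `ase_thresholds`.
#' @export
ase_thresholds <- function(min_informative_reads = 10L,
                           low_cut = 0.3,
                           high_cut = 0.7,
                           xci_subject_ratio = 0.9,
                           min_inactive_reads = 2L) {
  stopifnot(
    min_informative_reads >= 1, min_inactive_reads >= 1,
    low_cut >= 0, high_cut <= 1, low_cut < high_cut,
    xci_subject_ratio > 0, xci_subject_ratio <= 1
  )
  structure(
    list(
      min_informative_reads = as.integer(min_informative_reads),
      low_cut = low_cut, high_cut = high_cut,
      xci_subject_ratio = xci_subject_ratio,
      min_inactive_reads = as.integer(min_inactive_reads)
    ),
    class = "ase_thresholds"
  )
}

#' Classify features as maternal, paternal or biallelic
#'
#' Adds the allelic ratio and the hard-cutoff category to an allelic count
#' table. A feature is informative when its `snp_overlap_reads` (falling
#' back to `maternal + paternal` with a message when that column is absent)
#' reaches the threshold; informative features with ratio `>= high_cut` are
#' `MATERNAL`, `<= low_cut` `PATERNAL`, otherwise `BIALLELIC`. Features
#' failing the filter — including those with an undefined ratio — are
#' `NOT_INFORMATIVE`.
#'
#' @param counts Count tibble with `maternal`, `paternal` (and ideally
#'   `snp_overlap_reads`) columns, e.g. from [count_alleles()].
#' @param thresholds An [ase_thresholds()].
#' @return The input tibble with `ratio`, `informative` and `category`
#'   appended, classed `ase_calls`; the thresholds ride along as an
#'   attribute. [generics::glance()] summarises it.
#' @export
classify_alleles <- function(counts, thresholds = ase_thresholds()) {
  stopifnot(inherits(thresholds, "ase_thresholds"))
  counts <- tibble::as_tibble(counts)
  if (!all(c("maternal", "paternal") %in% names(counts))) {
    rlang::abort("counts must have maternal and paternal columns")
  }
  evidence <- if ("snp_overlap_reads" %in% names(counts)) {
    counts$snp_overlap_reads
  } else {
    rlang::inform("no snp_overlap_reads column; using maternal + paternal as evidence")
    counts$maternal + counts$paternal
  }
  out <- counts |>
    dplyr::mutate(
      ratio = allelic_ratio(.data$maternal, .data$paternal),
      informative = evidence >= thresholds$min_informative_reads &
        !is.na(.data$ratio),
      category = dplyr::case_when(
        !.data$informative ~ "NOT_INFORMATIVE",
        .data$ratio >= thresholds$high_cut ~ "MATERNAL",
        .data$ratio <= thresholds$low_cut ~ "PATERNAL",
        TRUE ~ "BIALLELIC"
      )
    )
  attr(out, "thresholds") <- thresholds
  class(out) <- c("ase_calls", class(out))
  out
}

#' @method glance ase_calls
#' @export
glance.ase_calls <- function(x, ...) {
  inf <- dplyr::filter(x, .data$informative)
  out <- tibble::tibble(
    n_features = nrow(x),
    n_informative = nrow(inf),
    n_maternal = sum(inf$category == "MATERNAL"),
    n_paternal = sum(inf$category == "PATERNAL"),
    n_biallelic = sum(inf$category == "BIALLELIC"),
    n_not_informative = sum(x$category == "NOT_INFORMATIVE")
  )
  if ("is_x_linked" %in% names(x)) {
    out$n_informative_autosomal <- sum(!inf$is_x_linked)
    out$n_informative_x <- sum(inf$is_x_linked)
  }
  if ("biotype" %in% names(x)) {
    out$n_informative_coding <- sum(inf$biotype == "coding")
    out$n_informative_noncoding <- sum(inf$biotype != "coding")
  }
  out
}

#' @method tidy ase_calls
#' @export
tidy.ase_calls <- function(x, ...) {
  cols <- intersect(
    c("gene_id", "transcript_id", "feature_id", "chrom", "maternal", "paternal",
      "snp_overlap_reads", "ratio", "informative", "category", "xci_flag"),
    names(x)
  )
  tibble::as_tibble(x)[, cols]
}

#' Flag X-inactivation escape candidates under skewed XCI
#'
#' In a cross where one X is forced active (here the maternal), expression
#' from the other X is diagnostic of escape from inactivation. Informative
#' X-linked genes are flagged: ratio above `xci_subject_ratio` → `SUBJECT`;
#' ratio at or below `low_cut` (inactive-X-only expression, the Xist
#' pattern) → `INACTIVE_X_EXPRESSED`; otherwise `ESCAPE_CANDIDATE` when at
#' least `min_inactive_reads` reads come from the inactive allele, else NA
#' (no confident call). With `active_allele = "paternal"` the rules mirror.
#'
#' @param calls An `ase_calls` table containing X-linked features.
#' @param active_allele `"maternal"` or `"paternal"`; which X the design
#'   keeps active. Must be stated explicitly — it is a property of the
#'   cross, not of the data.
#' @param x_chrom X chromosome name (used when `is_x_linked` is absent).
#' @param thresholds An [ase_thresholds()]; defaults to the ones stored in
#'   `calls`.
#' @return The X-linked informative rows with an `xci_flag` column.
#' @export
detect_escape <- function(calls, active_allele, x_chrom = "chrX",
                          thresholds = attr(calls, "thresholds") %||% ase_thresholds()) {
  if (missing(active_allele) ||
      !active_allele %in% c("maternal", "paternal")) {
    rlang::abort("active_allele must be \"maternal\" or \"paternal\" (the XCI design)")
  }
  x_rows <- if ("is_x_linked" %in% names(calls)) {
    calls$is_x_linked
  } else if ("chrom" %in% names(calls)) {
    calls$chrom == x_chrom
  } else {
    rlang::abort("calls need an is_x_linked or chrom column")
  }
  x <- dplyr::filter(tibble::as_tibble(calls), x_rows, .data$informative)
  active_ratio <- if (active_allele == "maternal") x$ratio else 1 - x$ratio
  inactive_reads <- if (active_allele == "maternal") x$paternal else x$maternal
  x |>
    dplyr::mutate(
      xci_flag = dplyr::case_when(
        active_ratio > thresholds$xci_subject_ratio ~ "SUBJECT",
        active_ratio <= thresholds$low_cut ~ "INACTIVE_X_EXPRESSED",
        inactive_reads >= thresholds$min_inactive_reads ~ "ESCAPE_CANDIDATE",
        TRUE ~ NA_character_
      )
    )
}
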