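#' Join two allelic call tables on shared informative features
#'
#' Inner join on the feature id restricted to features informative in both
#' tables; ratios, counts and categories from each side are kept with `_a`
#' and `_b` suffixes.
#'
#' @param calls_a,calls_b `ase_calls` tables (or any tibble with the call
#'   schema) over the same feature namespace.
#' @param by Feature id column (default `"gene_id"`).
#' @return Joined tibble; empty (with a warning) when no informative
#'   feature is shared.
#' @export
join_calls <- function(calls_a, calls_b, by = "gene_id") {
  keep <- function(x) {
    x <- tibble::as_tibble(x)
    cols <- intersect(
      c(by, "maternal", "paternal", "snp_overlap_reads", "ratio",
        "informative", "category"),
      names(x)
    )
    dplyr::filter(x[, cols], .data$informative)
  }
  joined <- dplyr::inner_join(
    keep(calls_a), keep(calls_b), by = by, suffix = c("_a", "_b")
  )
  if (nrow(joined) == 0) {
    rlang::warn("no shared informative features between the two call tables")
  }
  joined
}

#' Pearson correlation of two allelic-ratio vectors
#'
#' Sample Pearson r with a two-sided p-value from the t transform on n - 2
#' degrees of freedom (via [stats::cor.test()]). Zero variance on either
#' side yields NA with a warning rather than an error.
#'
#' @param x,y Numeric vectors of equal length, at least 3, no NAs.
#' @return One-row tibble: `r`, `p`, `n`.
#' @export
ase_pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3 || anyNA(x) || anyNA(y)) {
    rlang::abort("ase_pearson needs >= 3 complete pairs")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::warn("zero variance: Pearson r undefined")
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = length(x)))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Direction agreement between two call tables
#'
#' Among features allele-specific (`MATERNAL` or `PATERNAL`) in both
#' tables, counts those called in the same parental direction; also reports
#' category agreement over the whole join.
#'
#' @param joined Output of [join_calls()].
#' @return One-row tibble: `n_joined`, `n_category_agree`,
#'   `n_allele_specific_both`, `n_direction_agree`, `n_direction_disagree`,
#'   `pct_direction_agree` (NA when no shared allele-specific features).
#' @export
direction_agreement <- function(joined) {
  spec <- c("MATERNAL", "PATERNAL")
  both <- joined$category_a %in% spec & joined$category_b %in% spec
  agree <- joined$category_a[both] == joined$category_b[both]
  tibble::tibble(
    n_joined = nrow(joined),
    n_category_agree = sum(joined$category_a == joined$category_b),
    n_allele_specific_both = sum(both),
    n_direction_agree = sum(agree),
    n_direction_disagree = sum(!agree),
    pct_direction_agree = ifelse(sum(both) > 0, 100 * mean(agree), NA_real_)
  )
}

venn_counts <- function(joined, which_cat) {
  in_a <- joined$category_a %in% which_cat
  in_b <- joined$category_b %in% which_cat
  tibble::tibble(
    a_only = sum(in_a & !in_b),
    b_only = sum(!in_a & in_b),
    both = sum(in_a & in_b)
  )
}

#' Concordance report between two allelic call tables
#'
#' Assembles the cross-platform comparison: the informative-in-both join,
#' overlap (Venn) counts for biallelic and allele-specific categories,
#' direction agreement among shared allele-specific features, and Pearson
#' correlation of the allelic ratios — overall and, when a feature subset
#' is given (e.g. known imprinted genes), over that subset.
#'
#' @inheritParams join_calls
#' @param subset Optional character vector of feature ids for a subset
#'   correlation.
#' @return Object of class `ase_concordance`: list with `joined`, `venn`
#'   (per-category overlap tibble), `direction`, `pearson`,
#'   `pearson_subset` and `n_shared_informative`. [generics::tidy()]
#'   returns the joined table, [generics::glance()] a one-row summary.
#' @export
concordance_report <- function(calls_a, calls_b, by = "gene_id", subset = NULL) {
  joined <- join_calls(calls_a, calls_b, by = by)
  venn <- dplyr::bind_rows(
    biallelic = venn_counts(joined, "BIALLELIC"),
    allele_specific = venn_counts(joined, c("MATERNAL", "PATERNAL")),
    .id = "set"
  )
  direction <- direction_agreement(joined)
  pearson <- if (nrow(joined) >= 3) {
    ase_pearson(joined$ratio_a, joined$ratio_b)
  } else {
    tibble::tibble(r = NA_real_, p = NA_real_, n = nrow(joined))
  }
  pearson_subset <- NULL
  if (!is.null(subset)) {
    sub <- joined[joined[[by]] %in% subset, ]
    pearson_subset <- if (nrow(sub) >= 3) {
      ase_pearson(sub$ratio_a, sub$ratio_b)
    } else {
      tibble::tibble(r = NA_real_, p = NA_real_, n = nrow(sub))
    }
  }
  structure(
    list(
      joined = joined, venn = venn, direction = direction,
      pearson = pearson, pearson_subset = pearson_subset,
      n_shared_informative = nrow(joined), by = by
    ),
    class = "ase_concordance"
  )
}

#' @export
print.ase_concordance <- function(x, ...) {
  cat("<ase_concordance> ", x$n_shared_informative,
      " shared informative features\n", sep = "")
  cat("  r = ", format(x$pearson$r, digits = 4),
      " (p = ", format(x$pearson$p, digits = 3), ")\n", sep = "")
  if (!is.null(x$pearson_subset)) {
    cat("  subset r = ", format(x$pearson_subset$r, digits = 4),
        " (n = ", x$pearson_subset$n, ")\n", sep = "")
  }
  cat("  direction agreement: ", x$direction$n_direction_agree, "/",
      x$direction$n_allele_specific_both, "\n", sep = "")
  invisible(x)
}

#' @method tidy ase_concordance
#' @export
tidy.ase_concordance <- function(x, ...) x$joined

#' @method glance ase_concordance
#' @export
glance.ase_concordance <- function(x, ...) {
  out <- tibble::tibble(
    n_shared_informative = x$n_shared_informative,
    biallelic_both = x$venn$both[x$venn$set == "biallelic"],
    allele_specific_both = x$venn$both[x$venn$set == "allele_specific"],
    n_direction_agree = x$direction$n_direction_agree,
    pct_direction_agree = x$direction$pct_direction_agree,
    pearson_r = x$pearson$r,
    pearson_p = x$pearson$p
  )
  if (!is.null(x$pearson_subset)) {
    out$subset_r <- x$pearson_subset$r
    out$subset_n <- x$pearson_subset$n
  }
  out
}

#' Write a concordance report to disk
#'
#' @param report An [concordance_report()] result.
#' @param dir Output directory.
#' @return Paths of the JSON summary and joined TSV, invisibly.
#' @export
write_concordance <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "concordance.json")
  tsv_path <- file.path(dir, "concordance_joined.tsv")
  jsonlite::write_json(
    list(
      summary = as.list(glance(report)),
      venn = report$venn,
      direction = as.list(report$direction)
    ),
    json_path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  readr::write_tsv(report$joined, tsv_path)
  invisible(c(json = json_path, tsv = tsv_path))
}
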