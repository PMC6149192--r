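#' Filter somatic variant records
#'
#' Retains a record iff `coverage >= min_coverage`, `vaf >= min_vaf`, and
#' its population minor allele frequency is missing or
#' `<= max_maf` (variants above 1% population frequency are treated as
#' germline polymorphisms). Boundary semantics are literal: coverage
#' exactly 25 and VAF exactly 5% are retained; MAF strictly above 1% is
#' removed. The removal report counts each rule independently, so a record
#' failing two rules contributes to both counts.
#'
#' @param variants Tibble with `coverage`, `vaf`, `population_maf` columns
#'   (other columns carried through).
#' @param min_coverage Minimum read coverage (default 25).
#' @param min_vaf Minimum variant allele frequency (default 0.05).
#' @param max_maf Maximum population MAF (default 0.01).
#' @return A list with `retained` (tibble) and `removals` (tibble `rule`,
#'   `n_failed`).
#' @export
#' @examples
#' v <- tibble::tibble(coverage = c(24, 25), vaf = c(0.5, 0.05),
#'                     population_maf = NA_real_)
#' filter_variants(v)$retained
filter_variants <- function(variants, min_coverage = 25, min_vaf = 0.05,
                            max_maf = 0.01) {
  fail_cov <- variants$coverage < min_coverage
  fail_vaf <- variants$vaf < min_vaf
  fail_maf <- !is.na(variants$population_maf) &
    variants$population_maf > max_maf
  keep <- !(fail_cov | fail_vaf | fail_maf)
  list(
    retained = variants[keep, , drop = FALSE],
    removals = tibble::tibble(
      rule = c("coverage", "vaf", "maf"),
      n_failed = c(sum(fail_cov), sum(fail_vaf), sum(fail_maf))
    )
  )
}

#' Tally the 12-class substitution spectrum
#'
#' Counts each ordered ref->alt substitution class and expresses it as a
#' percentage of the total. Classes are not collapsed to the pyrimidine
#' strand: C>T and G>A are reported separately, as is conventional when
#' transition percentages are quoted per strand. With zero records, counts
#' are 0 and percentages are `NA` (undefined, not 0).
#'
#' @param variants Tibble with `ref_base` and `alt_base` single-base
#'   columns.
#' @return Tibble with `class`, `count`, `percentage` (12 rows, fixed
#'   class order).
#' @export
substitution_spectrum <- function(variants) {
  cls <- substitution_classes()
  if (nrow(variants) == 0) {
    return(tibble::tibble(class = cls, count = rep(0L, 12),
                          percentage = rep(NA_real_, 12)))
  }
  key <- paste0(variants$ref_base, ">", variants$alt_base)
  bad <- !key %in% cls
  if (any(bad)) {
    stop("non-SNV or malformed substitution: ",
         paste(unique(key[bad]), collapse = ", "), call. = FALSE)
  }
  count <- as.integer(table(factor(key, levels = cls)))
  total <- sum(count)
  tibble::tibble(
    class = cls,
    count = count,
    percentage = if (total > 0) 100 * count / total else rep(NA_real_, 12)
  )
}

#' Per-sample variant counts
#'
#' @param variants Tibble with a `sample_id` column.
#' @return Tibble with `sample_id`, `n`, sorted by sample.
#' @export
per_sample_counts <- function(variants) {
  if (nrow(variants) == 0) {
    return(tibble::tibble(sample_id = character(0), n = integer(0)))
  }
  dplyr::arrange(dplyr::count(variants, sample_id), sample_id)
}
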