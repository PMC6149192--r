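#' Filter amplicons by coverage percentile and coefficient of variation
#'
#' Applies the two stated amplicon-panel quality rules: amplicons whose
#' mean count across the control samples is at or below the empirical 5th
#' percentile of all detectable amplicons' means are removed, and so are
#' amplicons whose coefficient of variation (sample standard deviation /
#' mean, across control samples) is at or above `cv_threshold`.
#' "Detectable" means a nonzero mean count. The percentile uses the default
#' linear-interpolation definition of [stats::quantile()]; ties at the
#' threshold are removed. The filter is idempotent only up to the
#' re-estimated percentile; callers apply it once.
#'
#' @param amplicons Tibble with `amplicon_id`, `gene_id`, `pool` and one
#'   numeric column per sample.
#' @param control_cols Character names of the control-sample columns used
#'   for both rules; defaults to every numeric column.
#' @param percentile Lower percentile cut, in percent (default 5).
#' @param cv_threshold Removal threshold on CV (default 0.3).
#' @return A list with `retained` (tibble) and `removed` (tibble
#'   `amplicon_id`, `reason`; reasons `undetectable`, `low_coverage`,
#'   `high_cv`).
#' @export
filter_amplicons <- function(amplicons, control_cols = NULL,
                             percentile = 5, cv_threshold = 0.3) {
  if (is.null(control_cols)) {
    control_cols <- names(amplicons)[vapply(amplicons, is.numeric, TRUE)]
    control_cols <- setdiff(control_cols, "pool")
  }
  mat <- as.matrix(amplicons[control_cols])
  m <- rowMeans(mat)
  if (!any(m > 0)) stop("no detectable amplicon in the panel", call. = FALSE)
  detectable <- m > 0
  cut <- stats::quantile(m[detectable], percentile / 100, names = FALSE)
  cv <- apply(mat, 1, stats::sd) / m
  cv[!detectable] <- Inf
  reason <- dplyr::case_when(
    !detectable ~ "undetectable",
    m <= cut ~ "low_coverage",
    cv >= cv_threshold ~ "high_cv",
    TRUE ~ NA_character_
  )
  keep <- is.na(reason)
  if (!any(keep)) stop("all amplicons removed by the filters", call. = FALSE)
  list(
    retained = amplicons[keep, , drop = FALSE],
    removed = tibble::tibble(
      amplicon_id = amplicons$amplicon_id[!keep],
      reason = reason[!keep]
    )
  )
}

#' Normalize amplicon counts for primer-pool design bias
#'
#' Within each sample, scales every pool's counts so that all pool medians
#' are equal (relative values within a pool are preserved). This removes
#' the count offset induced by amplifying different amplicon subsets in
#' different primer pools. Two target conventions are offered:
#' `"global_median"` (default) scales each pool's median to the sample's
#' overall median, keeping counts in familiar units; `"relative"` divides
#' each pool by its own median (pool medians become 1), which makes the
#' output invariant to a global scaling of the sample's library and is the
#' convention under which downstream gene copy numbers are depth-free.
#'
#' @param amplicons Tibble as in [filter_amplicons()].
#' @param sample_cols Character names of the sample columns to normalize;
#'   defaults to every numeric column except `pool`.
#' @param target `"global_median"` or `"relative"`.
#' @return The tibble with pool-scaled counts.
#' @export
pool_normalize <- function(amplicons, sample_cols = NULL,
                           target = c("global_median", "relative")) {
  target <- match.arg(target)
  if (is.null(sample_cols)) {
    sample_cols <- names(amplicons)[vapply(amplicons, is.numeric, TRUE)]
    sample_cols <- setdiff(sample_cols, "pool")
  }
  pools <- unique(amplicons$pool)
  for (p in pools) {
    if (!any(amplicons$pool == p)) stop("empty pool: ", p, call. = FALSE)
  }
  out <- amplicons
  for (s in sample_cols) {
    tgt <- if (target == "global_median") stats::median(out[[s]]) else 1
    for (p in pools) {
      idx <- out$pool == p
      pool_med <- stats::median(out[[s]][idx])
      if (pool_med > 0) {
        out[[s]][idx] <- out[[s]][idx] * tgt / pool_med
      }
    }
  }
  out
}

#' Gene-level copy number from an amplicon panel
#'
#' For each gene, the copy number is twice the median over the gene's
#' amplicons of the tumor/normal count ratio, where the normal value is
#' the mean count across control samples. The median-of-ratios aggregation
#' is robust to single-amplicon outliers; amplicons whose normal mean is
#' zero are skipped, and genes left without usable amplicons are omitted
#' with a message. Filtering ([filter_amplicons()]) and pool normalization
#' ([pool_normalize()]) are assumed already applied.
#'
#' @param amplicons Tibble with `amplicon_id`, `gene_id`, `pool`, a tumor
#'   column and control columns.
#' @param tumor_col Name of the tumor count column.
#' @param control_cols Names of the control count columns.
#' @return Copy-number profile tibble: `gene_id`, `baseline` (2), `cn`,
#'   `n_amplicons`.
#' @export
panel_copy_number <- function(amplicons, tumor_col, control_cols) {
  normal_mean <- rowMeans(as.matrix(amplicons[control_cols]))
  usable <- normal_mean > 0
  if (!any(usable)) stop("no amplicon shared with a usable control mean", call. = FALSE)
  dropped_genes <- setdiff(amplicons$gene_id, amplicons$gene_id[usable])
  if (length(dropped_genes)) {
    message(length(dropped_genes),
            " gene(s) omitted (no amplicon with nonzero control mean): ",
            paste(dropped_genes, collapse = ", "))
  }
  df <- tibble::tibble(
    gene_id = amplicons$gene_id[usable],
    ratio = amplicons[[tumor_col]][usable] / normal_mean[usable]
  )
  out <- dplyr::summarise(
    dplyr::group_by(df, gene_id),
    baseline = 2,
    cn = 2 * stats::median(ratio),
    n_amplicons = dplyr::n(),
    .groups = "drop"
  )
  out
}
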