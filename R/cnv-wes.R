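#' Per-gene read density
#'
#' Read density is the per-gene read count divided by the gene's total exon
#' length in bases; it is the unit in which copy number is normalized
#' against the panel of normals.
#'
#' @param counts Tibble with `gene_id` and one or more numeric count
#'   columns.
#' @param gene_models Gene models from [as_gene_models()] (exon tibbles are
#'   collapsed automatically).
#' @return The input tibble with every count column replaced by its
#'   density.
#' @export
#' @examples
#' gm <- tibble::tibble(gene_id = "g1", chromosome = "autosome",
#'                      start = 0L, end = 2000L)
#' read_density(tibble::tibble(gene_id = "g1", tumor = 600), gm)
read_density <- function(counts, gene_models) {
  gm <- as_gene_models(gene_models)
  missing <- setdiff(counts$gene_id, gm$gene_id)
  if (length(missing)) {
    stop("no gene model for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  len <- gm$exon_length[match(counts$gene_id, gm$gene_id)]
  dplyr::mutate(counts,
                dplyr::across(dplyr::where(is.numeric), ~ .x / len))
}

#' Panel-of-normals baseline density
#'
#' Arithmetic mean of per-gene read densities across the normal
#' white-blood-cell panel; this average is the diploid reference against
#' which tumor densities are scaled. Genes whose mean density is zero are
#' flagged unusable (they cannot normalize anything) rather than imputed.
#'
#' @param normal_counts Tibble with `gene_id` and one column per normal
#'   sample.
#' @param gene_models Gene models.
#' @return Tibble with `gene_id`, `baseline_density`, `usable`.
#' @export
panel_baseline <- function(normal_counts, gene_models) {
  if (ncol(normal_counts) < 2) {
    stop("panel must contain at least one normal sample", call. = FALSE)
  }
  dens <- read_density(normal_counts, gene_models)
  mat <- as.matrix(dens[setdiff(names(dens), "gene_id")])
  tibble::tibble(
    gene_id = dens$gene_id,
    baseline_density = rowMeans(mat),
    usable = rowMeans(mat) > 0
  )
}

#' Per-gene copy number from read densities
#'
#' Estimates copy number as
#' `cn(g) = ploidy(g) * tumor_density(g) / baseline_density(g)`, where the
#' baseline ploidy is 2 for autosomal genes and 1 for genes on the X or Y
#' chromosome (male samples). Before the ratio is formed, every sample's
#' density vector (tumor and each normal) is divided by that sample's
#' genome-wide mean density (total reads / total exon length), so the
#' profile is invariant to sequencing depth: multiplying all counts of a
#' sample by a constant changes nothing. Genes with an unusable (zero)
#' baseline are omitted with a message. Only male samples are supported: a
#' female mode would need a different sex-chromosome baseline and is
#' rejected explicitly.
#'
#' @param tumor_counts Tibble with `gene_id` and a single `tumor` count
#'   column (the first numeric column is used).
#' @param normal_counts Panel counts, as in [panel_baseline()].
#' @param gene_models Gene models.
#' @param sex Must be `"male"`.
#' @return A copy-number profile: tibble with `gene_id`, `chromosome`,
#'   `baseline` (ploidy), `cn`.
#' @export
to_copy_number <- function(tumor_counts, normal_counts, gene_models,
                           sex = "male") {
  if (!identical(sex, "male")) {
    stop("only male samples are supported (sex-chromosome baseline 1)",
         call. = FALSE)
  }
  gm <- as_gene_models(gene_models)
  # library normalization: densities in units of the sample's mean density
  norm_density <- function(counts) {
    dens <- read_density(counts, gene_models)
    len <- gm$exon_length[match(counts$gene_id, gm$gene_id)]
    for (s in setdiff(names(dens), "gene_id")) {
      lib_density <- sum(counts[[s]]) / sum(len)
      if (lib_density > 0) dens[[s]] <- dens[[s]] / lib_density
    }
    dens
  }
  tum <- norm_density(tumor_counts)
  tum_col <- setdiff(names(tum), "gene_id")[1]
  norm_dens <- norm_density(normal_counts)
  mat <- as.matrix(norm_dens[setdiff(names(norm_dens), "gene_id")])
  base <- tibble::tibble(
    gene_id = norm_dens$gene_id,
    baseline_density = rowMeans(mat),
    usable = rowMeans(mat) > 0
  )
  df <- dplyr::inner_join(tum, base, by = "gene_id")
  dropped <- df$gene_id[!df$usable]
  if (length(dropped)) {
    message(length(dropped), " gene(s) dropped for zero baseline density: ",
            paste(utils::head(dropped, 5), collapse = ", "),
            if (length(dropped) > 5) ", ...")
    df <- df[df$usable, , drop = FALSE]
  }
  idx <- match(df$gene_id, gm$gene_id)
  ploidy <- ifelse(gm$is_sex_chromosome[idx], 1, 2)
  tibble::tibble(
    gene_id = df$gene_id,
    chromosome = gm$chromosome[idx],
    baseline = ploidy,
    cn = ploidy * df[[tum_col]] / df$baseline_density
  )
}

#' Call per-gene copy-number gains and losses
#'
#' Thresholds are expressed on the autosomal (diploid) scale and scaled by
#' `baseline / 2` per gene, so a gene on chrX (baseline 1) is called with
#' thresholds half those of an autosomal gene. Boundaries are closed: a
#' copy number exactly at a threshold is called gain (or loss).
#'
#' @param profile Copy-number profile from [to_copy_number()].
#' @param gain_threshold,loss_threshold Autosomal-scale thresholds
#'   (defaults 3 and 1: one copy gained or lost at diploid baseline).
#' @return The profile with an added `call` column
#'   (`"gain"`, `"neutral"`, `"loss"`).
#' @export
call_gain_loss <- function(profile, gain_threshold = 3, loss_threshold = 1) {
  if (loss_threshold >= gain_threshold) {
    stop("`loss_threshold` must be below `gain_threshold`", call. = FALSE)
  }
  scale <- profile$baseline / 2
  dplyr::mutate(profile, call = dplyr::case_when(
    cn >= gain_threshold * scale ~ "gain",
    cn <= loss_threshold * scale ~ "loss",
    TRUE ~ "neutral"
  ))
}

#' Concordance between two copy-number profiles
#'
#' Pearson correlation of `log2(cn + pseudocount)` over the genes shared by
#' the two profiles. The pseudocount keeps homozygous deletions (cn = 0)
#' finite on the log scale.
#'
#' @param profile_a,profile_b Copy-number profiles (tibbles with `gene_id`
#'   and `cn`).
#' @param pseudocount Added to cn before log2 (default 0.01).
#' @param sample_a,sample_b Optional identifiers carried into the result.
#' @return One-row tibble with `sample_a`, `sample_b`, `n_genes`,
#'   `pearson_r`.
#' @export
cn_correlation <- function(profile_a, profile_b, pseudocount = 0.01,
                           sample_a = "a", sample_b = "b") {
  shared <- dplyr::inner_join(
    profile_a[, c("gene_id", "cn")], profile_b[, c("gene_id", "cn")],
    by = "gene_id", suffix = c("_a", "_b")
  )
  if (nrow(shared) < 3) {
    stop("need at least 3 shared genes, got ", nrow(shared), call. = FALSE)
  }
  la <- log2(shared$cn_a + pseudocount)
  lb <- log2(shared$cn_b + pseudocount)
  if (stats::sd(la) == 0 || stats::sd(lb) == 0) {
    stop("correlation undefined: zero variance in a profile", call. = FALSE)
  }
  tibble::tibble(
    sample_a = sample_a, sample_b = sample_b,
    n_genes = nrow(shared),
    pearson_r = stats::cor(la, lb)
  )
}
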