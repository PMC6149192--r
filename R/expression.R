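#' RPKM expression values
#'
#' Reads per kilobase of exon per million mapped reads:
#' `rpkm(g, s) = counts(g, s) * 1e9 / (library_size(s) * length(g))`,
#' with the library size taken as the column sum of the count matrix.
#'
#' @param counts Tibble with `gene_id` and one numeric column per sample.
#' @param gene_lengths Tibble with `gene_id` and `length` (bases), or a
#'   gene-model table with `exon_length`.
#' @return Tibble of the same shape with RPKM values.
#' @export
#' @examples
#' counts <- tibble::tibble(gene_id = "g", s1 = 10)
#' # a 1 kb gene carrying all 10 reads of a 10-read library
#' rpkm(counts, tibble::tibble(gene_id = "g", length = 1000)) # huge RPKM
rpkm <- function(counts, gene_lengths) {
  len_col <- if ("length" %in% names(gene_lengths)) "length" else "exon_length"
  len <- gene_lengths[[len_col]][match(counts$gene_id, gene_lengths$gene_id)]
  if (anyNA(len)) {
    stop("missing gene length for: ",
         paste(counts$gene_id[is.na(len)], collapse = ", "), call. = FALSE)
  }
  if (any(len <= 0)) stop("gene lengths must be positive", call. = FALSE)
  out <- counts
  for (s in setdiff(names(counts), "gene_id")) {
    lib <- sum(counts[[s]])
    if (lib == 0) stop("zero library size in sample ", s, call. = FALSE)
    out[[s]] <- counts[[s]] * 1e9 / (lib * len)
  }
  out
}

#' Quantifiable genes
#'
#' A gene is quantifiable when its total read count across all samples of
#' the comparison is at least `min_reads` (default 10).
#'
#' @param counts Count tibble (`gene_id` + sample columns).
#' @param min_reads Minimum total reads (default 10).
#' @return Character vector of quantifiable gene ids.
#' @export
quantifiable_genes <- function(counts, min_reads = 10) {
  if (nrow(counts) == 0) return(character(0))
  total <- rowSums(as.matrix(counts[setdiff(names(counts), "gene_id")]))
  counts$gene_id[total >= min_reads]
}

#' Call differentially expressed genes
#'
#' Applies the quantifiability filter, computes the treated/control fold
#' change of mean RPKM (with a pseudocount of one read added to every cell
#' before normalization, so zero counts cannot produce infinite ratios),
#' and tests each gene for a count difference. With a single sample per
#' condition the test is the exact binomial test of the gene's treated
#' count against the library-size split of the pooled count; with
#' replicates it is Welch's t-test on `log2(RPKM + 1)`. A gene is called
#' differentially expressed iff its fold change is at least `fc_threshold`
#' (or at most its reciprocal) and its p-value is below `alpha`. No
#' multiple-testing correction is applied by default; `fdr = TRUE`
#' switches the alpha comparison to Benjamini-Hochberg adjusted p-values.
#'
#' @param treated,control Count tibbles (`gene_id` + replicate columns).
#' @param gene_lengths Tibble with `gene_id` and `length`.
#' @param fc_threshold Fold-change threshold (default 2).
#' @param alpha Significance level (default 0.05).
#' @param min_reads Quantifiability threshold on total reads across both
#'   conditions (default 10).
#' @param fdr Use BH-adjusted p-values for the significance rule.
#' @return Tibble with `gene_id`, `fold_change`, `p_value`, `is_de`.
#' @export
call_deg <- function(treated, control, gene_lengths, fc_threshold = 2,
                     alpha = 0.05, min_reads = 10, fdr = FALSE) {
  shared <- intersect(treated$gene_id, control$gene_id)
  if (!length(shared)) stop("no overlapping genes", call. = FALSE)
  treated <- treated[match(shared, treated$gene_id), , drop = FALSE]
  control <- control[match(shared, control$gene_id), , drop = FALSE]
  tcols <- setdiff(names(treated), "gene_id")
  ccols <- setdiff(names(control), "gene_id")
  tmat <- as.matrix(treated[tcols])
  cmat <- as.matrix(control[ccols])

  keep <- shared %in% quantifiable_genes(
    dplyr::inner_join(treated, control, by = "gene_id"), min_reads
  )
  tmat <- tmat[keep, , drop = FALSE]
  cmat <- cmat[keep, , drop = FALSE]
  genes <- shared[keep]

  # fold change on mean RPKM with +1 read pseudocount
  t_rpkm <- as.matrix(rpkm(
    tibble::tibble(gene_id = genes, !!!as.data.frame(tmat + 1)), gene_lengths
  )[-1])
  c_rpkm <- as.matrix(rpkm(
    tibble::tibble(gene_id = genes, !!!as.data.frame(cmat + 1)), gene_lengths
  )[-1])
  fc <- rowMeans(t_rpkm) / rowMeans(c_rpkm)

  if (length(tcols) == 1 && length(ccols) == 1) {
    nt <- sum(tmat)
    nc <- sum(cmat)
    p <- vapply(seq_along(genes), function(i) {
      tot <- tmat[i, 1] + cmat[i, 1]
      if (tot == 0) return(1)
      stats::binom.test(tmat[i, 1], tot, p = nt / (nt + nc))$p.value
    }, numeric(1))
  } else {
    lt <- log2(t_rpkm + 1)
    lc <- log2(c_rpkm + 1)
    p <- vapply(seq_along(genes), function(i) {
      a <- lt[i, ]
      b <- lc[i, ]
      if (stats::sd(c(a, b)) == 0) return(1)
      tryCatch(stats::t.test(a, b)$p.value, error = function(e) 1)
    }, numeric(1))
  }
  p_rule <- if (fdr) stats::p.adjust(p, "BH") else p
  tibble::tibble(
    gene_id = genes,
    fold_change = unname(fc),
    p_value = unname(p),
    is_de = (fc >= fc_threshold | fc <= 1 / fc_threshold) & p_rule < alpha
  )
}
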