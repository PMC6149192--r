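#' Simulate a plasma cfDNA cohort tied to EBV DNA load
#'
#' EBV DNA loads are drawn log-uniformly on `load_range`; the true
#' CCND1/CDKN2A ratio follows the linear model
#' `ratio = plasma_slope * log10(load) + plasma_intercept + N(0, plasma_noise_sd)`,
#' floored at 0.01 so that the linear model cannot produce non-positive
#' ratios at low loads. Gene-level copy numbers are chosen consistent with
#' the ratio: CDKN2A is drawn from \{2, 1, 0.05\} with one-copy (and, rarely,
#' homozygous) loss probability increasing in load, CCND1 is set to
#' `ratio * CDKN2A`, and RAD52 stays near the diploid 2 with small noise.
#'
#' @param config A [sim_config()] (plasma coefficients and noise live there).
#' @param n_patients Cohort size.
#' @param load_range Length-2 positive vector of EBV DNA copies/ml.
#' @return A tibble with `patient_id`, `ebv_load`, `cn_ccnd1`, `cn_cdkn2a`,
#'   `cn_rad52`, `true_ratio`.
#' @export
#' @examples
#' cohort <- sim_plasma_cohort(sim_config(seed = 7), n_patients = 22)
#' head(cohort)
sim_plasma_cohort <- function(config, n_patients = 22L,
                              load_range = c(5e3, 1e6)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(load_range <= 0)) {
    stop("`load_range` must contain positive loads only", call. = FALSE)
  }
  withr::with_seed(sub_seed(config, 71L), {
    lx <- stats::runif(n_patients, log10(load_range[1]), log10(load_range[2]))
    load <- 10^lx
    ratio <- config$plasma_slope * lx + config$plasma_intercept +
      stats::rnorm(n_patients, 0, config$plasma_noise_sd)
    ratio <- pmax(ratio, 0.01)
    # loss probability rises from 0 at the low end of the range to ~0.75
    p_loss <- 0.75 * (lx - log10(load_range[1])) /
      max(log10(load_range[2]) - log10(load_range[1]), 1e-9)
    u <- stats::runif(n_patients)
    cdkn2a <- ifelse(u < p_loss * 0.1, 0.05, ifelse(u < p_loss, 1, 2))
    tibble::tibble(
      patient_id = sprintf("patient_%03d", seq_len(n_patients)),
      ebv_load = load,
      cn_ccnd1 = ratio * cdkn2a,
      cn_cdkn2a = cdkn2a,
      cn_rad52 = pmax(stats::rnorm(n_patients, 2, 0.1), 0.2),
      true_ratio = ratio
    )
  })
}

#' Simulate qPCR cycle-threshold measurements from true copy numbers
#'
#' Inverts the delta-delta-Ct quantification model of
#' [qpcr_copy_number()]: with amplification factor `1 + qpcr_efficiency`
#' per cycle, the Ct of a target with copy number `cn` is placed
#' `log(cn / 2, base = 1 + efficiency)` cycles below a fixed baseline, so
#' that at zero noise the estimator recovers `cn` exactly. The control
#' target and the calibrator (healthy PBMC, diploid everywhere) sit at the
#' baseline Ct. A true copy number of 0 is emitted as a non-detect
#' (`NA` Ct).
#'
#' @param config A [sim_config()] (`qpcr_efficiency` lives there).
#' @param truth_cn Tibble with `sample_id`, `target`, `cn` true copy
#'   numbers. The control target need not be listed; it is assumed diploid.
#' @param control_target Reference gene measured in every sample.
#' @param n_replicates Technical replicates per target.
#' @param ct_noise_sd Standard deviation of Normal noise added per
#'   replicate Ct (0 gives exact round trips).
#' @param baseline_ct Ct of a diploid target in the calibrator.
#' @return A list with `measurements` and `calibrator`, both tibbles with
#'   `sample_id`, `target`, `replicate`, `ct`.
#' @export
sim_qpcr <- function(config, truth_cn, control_target = "RAD52",
                     n_replicates = 2L, ct_noise_sd = 0,
                     baseline_ct = 25) {
  stopifnot(inherits(config, "sim_config"))
  stopifnot(all(c("sample_id", "target", "cn") %in% names(truth_cn)))
  if (any(truth_cn$cn < 0)) stop("true copy numbers must be >= 0", call. = FALSE)
  amp <- 1 + config$qpcr_efficiency
  ct_for <- function(cn) {
    ifelse(cn <= 0, NA_real_, baseline_ct - log(cn / 2, base = amp))
  }
  withr::with_seed(sub_seed(config, 83L), {
    samples <- unique(truth_cn$sample_id)
    targets <- union(unique(truth_cn$target), control_target)
    grid <- tidyr::expand_grid(
      sample_id = samples, target = targets,
      replicate = seq_len(n_replicates)
    )
    grid <- dplyr::left_join(grid, truth_cn, by = c("sample_id", "target"))
    grid$cn[is.na(grid$cn) & grid$target == control_target] <- 2
    if (anyNA(grid$cn)) {
      stop("missing true copy number for a non-control target", call. = FALSE)
    }
    grid$ct <- ct_for(grid$cn) +
      ifelse(is.na(ct_for(grid$cn)), 0,
             stats::rnorm(nrow(grid), 0, ct_noise_sd))
    calibrator <- tidyr::expand_grid(
      sample_id = "PBMC_calibrator", target = targets,
      replicate = seq_len(n_replicates)
    )
    calibrator$ct <- baseline_ct +
      stats::rnorm(nrow(calibrator), 0, ct_noise_sd)
    list(
      measurements = grid[, c("sample_id", "target", "replicate", "ct")],
      calibrator = calibrator
    )
  })
}

#' Simulate a two-condition RNA count matrix with planted fold changes
#'
#' `n_de` genes receive mean expression `fold_change` times higher in the
#' treated condition; all other genes have equal means in both conditions.
#' Counts are Poisson around a log-normal baseline mean.
#'
#' @param config A [sim_config()].
#' @param n_genes Number of genes (defaults to `config$n_genes`).
#' @param n_de Number of truly differential genes.
#' @param fold_change True treated/control mean ratio for planted genes
#'   (must be positive).
#' @param n_reps Replicates per condition.
#' @param base_mean Median baseline mean count.
#' @return A list with `treated` and `control` count tibbles
#'   (`gene_id` + replicate columns), `gene_lengths` (tibble `gene_id`,
#'   `length`), and `labels` (tibble `gene_id`, `is_de`).
#' @export
sim_expression <- function(config, n_genes = config$n_genes, n_de = 50L,
                           fold_change = 4, n_reps = 3L, base_mean = 100) {
  stopifnot(inherits(config, "sim_config"))
  if (fold_change <= 0) stop("`fold_change` must be positive", call. = FALSE)
  if (n_de > n_genes) stop("`n_de` cannot exceed `n_genes`", call. = FALSE)
  withr::with_seed(sub_seed(config, 97L), {
    gene_id <- sprintf("gene_%04d", seq_len(n_genes))
    mu <- stats::rlnorm(n_genes, meanlog = log(base_mean), sdlog = 1)
    is_de <- seq_len(n_genes) <= n_de
    is_de <- sample(is_de) # scatter DE genes through the matrix
    draw_cond <- function(means, prefix) {
      out <- tibble::tibble(gene_id = gene_id)
      for (r in seq_len(n_reps)) {
        out[[paste0(prefix, r)]] <- stats::rpois(n_genes, means)
      }
      out
    }
    list(
      treated = draw_cond(mu * ifelse(is_de, fold_change, 1), "treated_"),
      control = draw_cond(mu, "control_"),
      gene_lengths = tibble::tibble(
        gene_id = gene_id,
        length = sample(500:3000, n_genes, replace = TRUE)
      ),
      labels = tibble::tibble(gene_id = gene_id, is_de = is_de)
    )
  })
}
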