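#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data layer into a single validated
#' object. All generators draw their randomness from `seed`, with a fixed
#' per-generator offset, so a given configuration always produces
#' byte-identical output.
#'
#' @param seed Integer seed for all downstream randomness.
#' @param n_genes Number of genes in the simulated exome.
#' @param depth Mean reads per kilobase of exon per sample at diploid copy
#'   number (the sequencing depth of the coverage simulator).
#' @param contamination Proportion of mouse-origin reads in a xenograft
#'   read set, in `[0, 1]`.
#' @param divergence Per-base substitution rate between the synthetic human
#'   and mouse references, in `[0, 1]`.
#' @param genome_length Total reference length in bases, split across an
#'   autosomal chromosome and chrX.
#' @param read_length Simulated read length in bases.
#' @param planted_cnv Named numeric vector mapping gene ids to true copy
#'   numbers (non-negative); genes not named are left at baseline.
#' @param spectrum Named probability vector over the 12 ordered
#'   substitution classes (see [substitution_classes()]); must sum to 1.
#' @param plasma_slope,plasma_intercept Coefficients of the true linear
#'   model of the CCND1/CDKN2A ratio on log10 EBV DNA load
#'   (defaults 11.11 and -36.93).
#' @param plasma_noise_sd Standard deviation of the Normal residual added
#'   to the plasma ratio.
#' @param qpcr_efficiency Amplification efficiency in `(0, 1]`; 1 means
#'   perfect doubling per cycle.
#' @param n_normals Number of normal white-blood-cell samples in the
#'   copy-number reference panel.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50)
#' cfg$depth
sim_config <- function(seed = 1L,
                       n_genes = 200L,
                       depth = 100,
                       contamination = 0.2,
                       divergence = 0.1,
                       genome_length = 20000L,
                       read_length = 100L,
                       planted_cnv = NULL,
                       spectrum = uniform_spectrum(),
                       plasma_slope = 11.11,
                       plasma_intercept = -36.93,
                       plasma_noise_sd = 2,
                       qpcr_efficiency = 1,
                       n_normals = 5L) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (n_genes < 1) stop("`n_genes` must be at least 1", call. = FALSE)
  if (genome_length < 1) stop("zero-length genome requested", call. = FALSE)
  if (depth <= 0) stop("`depth` must be positive", call. = FALSE)
  if (contamination < 0 || contamination > 1) {
    stop("`contamination` must lie in [0, 1]", call. = FALSE)
  }
  if (divergence < 0 || divergence > 1) {
    stop("`divergence` must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(planted_cnv)) {
    if (is.null(names(planted_cnv)) || any(!nzchar(names(planted_cnv)))) {
      stop("`planted_cnv` must be a named vector of gene ids", call. = FALSE)
    }
    if (any(planted_cnv < 0)) {
      stop("planted copy numbers must be non-negative", call. = FALSE)
    }
  }
  spectrum <- validate_spectrum(spectrum)
  if (qpcr_efficiency <= 0 || qpcr_efficiency > 1) {
    stop("`qpcr_efficiency` must lie in (0, 1]", call. = FALSE)
  }
  if (plasma_noise_sd < 0) stop("`plasma_noise_sd` must be >= 0", call. = FALSE)
  if (n_normals < 1) stop("`n_normals` must be at least 1", call. = FALSE)

  structure(
    list(
      seed = as.integer(seed) %% .Machine$integer.max,
      n_genes = as.integer(n_genes),
      depth = depth,
      contamination = contamination,
      divergence = divergence,
      genome_length = as.integer(genome_length),
      read_length = as.integer(read_length),
      planted_cnv = planted_cnv,
      spectrum = spectrum,
      plasma_slope = plasma_slope,
      plasma_intercept = plasma_intercept,
      plasma_noise_sd = plasma_noise_sd,
      qpcr_efficiency = qpcr_efficiency,
      n_normals = as.integer(n_normals)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  seed:", x$seed, " genes:", x$n_genes, " depth:", x$depth, "\n")
  cat("  contamination:", x$contamination, " divergence:", x$divergence, "\n")
  cat("  plasma model: ratio =", x$plasma_slope, "* log10(load) +",
      x$plasma_intercept, " (sd", x$plasma_noise_sd, ")\n")
  invisible(x)
}

#' The 12 ordered substitution classes
#'
#' Ordered ref->alt single-nucleotide substitution classes, without
#' pyrimidine-strand collapsing: C>T and G>A are distinct classes, matching
#' how transition percentages are conventionally reported for tumor panels.
#'
#' @return Character vector of length 12, e.g. `"C>T"`.
#' @export
substitution_classes <- function() {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (r in bases) for (a in setdiff(bases, r)) out <- c(out, paste0(r, ">", a))
  out
}

#' Uniform substitution spectrum
#'
#' @return Named probability vector assigning 1/12 to each class.
#' @export
uniform_spectrum <- function() {
  cls <- substitution_classes()
  stats::setNames(rep(1 / 12, 12), cls)
}

validate_spectrum <- function(spectrum) {
  cls <- substitution_classes()
  if (is.null(names(spectrum))) stop("spectrum must be named by class", call. = FALSE)
  if (!all(names(spectrum) %in% cls)) {
    stop("unknown substitution class: ",
         paste(setdiff(names(spectrum), cls), collapse = ", "), call. = FALSE)
  }
  full <- stats::setNames(rep(0, 12), cls)
  full[names(spectrum)] <- spectrum
  if (any(full < 0)) stop("spectrum probabilities must be >= 0", call. = FALSE)
  if (abs(sum(full) - 1) > 1e-8) {
    stop("spectrum must sum to 1 (got ", format(sum(full)), ")", call. = FALSE)
  }
  full
}

# Deterministic sub-stream: every generator perturbs the master seed by a
# fixed offset so individual outputs are reproducible in isolation.
sub_seed <- function(config, offset) {
  (config$seed + offset) %% .Machine$integer.max
}
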