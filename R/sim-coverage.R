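#' Simulate per-gene exome read counts with planted copy-number truth
#'
#' Inverts the read-density copy-number model: the expected read count of
#' gene *g* in the tumor sample is
#' `depth * exon_length(g)/1000 * CN(g)/baseline(g)`, where the baseline
#' ploidy is 2 on autosomes and 1 on chrX (male samples). Normal panel
#' samples are drawn at baseline copy number. Counts are Poisson by default;
#' a negative-binomial option adds extra-Poisson dispersion.
#'
#' @param config A [sim_config()]; `config$planted_cnv` names the genes with
#'   non-baseline true copy number.
#' @param gene_models Gene models as returned by [as_gene_models()] (or the
#'   exon tibble from [sim_gene_models()], which is collapsed automatically).
#' @param dispersion Negative-binomial size parameter; `Inf` (default) gives
#'   Poisson counts.
#' @return A list with `counts`, a tibble `gene_id`, `tumor`,
#'   `normal_1..n_normals`, and `truth`, a tibble `gene_id`, `true_cn`,
#'   `baseline`.
#' @export
sim_coverage <- function(config, gene_models, dispersion = Inf) {
  stopifnot(inherits(config, "sim_config"))
  gm <- as_gene_models(gene_models)
  planted <- config$planted_cnv
  if (!is.null(planted)) {
    unknown <- setdiff(names(planted), gm$gene_id)
    if (length(unknown)) {
      stop("planted copy number for unknown gene(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  baseline <- ifelse(gm$is_sex_chromosome, 1, 2)
  true_cn <- baseline
  if (!is.null(planted)) {
    idx <- match(names(planted), gm$gene_id)
    true_cn[idx] <- unname(planted)
  }
  mu_unit <- config$depth * gm$exon_length / 1000
  draw <- function(mu) {
    if (is.finite(dispersion)) {
      stats::rnbinom(length(mu), size = dispersion, mu = mu)
    } else {
      stats::rpois(length(mu), mu)
    }
  }
  withr::with_seed(sub_seed(config, 47L), {
    counts <- tibble::tibble(
      gene_id = gm$gene_id,
      tumor = draw(mu_unit * true_cn / baseline)
    )
    for (j in seq_len(config$n_normals)) {
      counts[[paste0("normal_", j)]] <- draw(mu_unit)
    }
    list(
      counts = counts,
      truth = tibble::tibble(gene_id = gm$gene_id,
                             true_cn = true_cn, baseline = baseline)
    )
  })
}

#' Simulate a somatic variant table with a planted substitution spectrum
#'
#' Draws substitution classes from `config$spectrum` and populates the
#' coverage, variant allele frequency (VAF) and population minor allele
#' frequency (MAF) fields so that a configurable fraction of records fails
#' each retention rule of [filter_variants()]. The rule each record was
#' built to fail is recorded in `planted_fail` (`"none"` for records built
#' to pass all rules), giving exact bookkeeping for filter tests.
#'
#' @param config A [sim_config()].
#' @param n_per_sample Named integer vector: records per sample.
#' @param fail_fraction Named fractions (`coverage`, `vaf`, `maf`) of
#'   records planted to fail each rule; must sum to at most 1.
#' @return A tibble of variant records with columns `sample_id`,
#'   `chromosome`, `position`, `ref_base`, `alt_base`, `coverage`, `vaf`,
#'   `population_maf`, `consequence`, `planted_fail`.
#' @export
sim_variant_table <- function(config, n_per_sample,
                              fail_fraction = c(coverage = 0, vaf = 0, maf = 0)) {
  stopifnot(inherits(config, "sim_config"))
  if (any(n_per_sample < 0)) stop("negative variant counts requested", call. = FALSE)
  ff <- c(coverage = 0, vaf = 0, maf = 0)
  ff[names(fail_fraction)] <- fail_fraction
  if (sum(ff) > 1) stop("fail fractions must sum to at most 1", call. = FALSE)
  if (is.null(names(n_per_sample))) {
    names(n_per_sample) <- sprintf("sample_%d", seq_along(n_per_sample))
  }
  cls <- substitution_classes()
  total <- sum(n_per_sample)
  empty <- tibble::tibble(
    sample_id = character(0), chromosome = character(0), position = integer(0),
    ref_base = character(0), alt_base = character(0), coverage = integer(0),
    vaf = numeric(0), population_maf = numeric(0), consequence = character(0),
    planted_fail = character(0)
  )
  if (total == 0) return(empty)
  withr::with_seed(sub_seed(config, 59L), {
    sample_id <- rep(names(n_per_sample), times = n_per_sample)
    classes <- sample(cls, total, replace = TRUE, prob = config$spectrum)
    n_cov <- round(total * ff[["coverage"]])
    n_vaf <- round(total * ff[["vaf"]])
    n_maf <- round(total * ff[["maf"]])
    planted <- rep("none", total)
    fail_idx <- sample.int(total, n_cov + n_vaf + n_maf)
    planted[fail_idx] <- rep(c("coverage", "vaf", "maf"),
                             times = c(n_cov, n_vaf, n_maf))
    coverage <- sample(25:400, total, replace = TRUE)
    coverage[planted == "coverage"] <- sample(1:24, n_cov, replace = TRUE)
    vaf <- stats::runif(total, 0.05, 0.9)
    vaf[planted == "vaf"] <- stats::runif(n_vaf, 0.001, 0.0499)
    maf <- rep(NA_real_, total)
    known <- stats::runif(total) < 0.3 # minority of passing records have a known, benign MAF
    maf[known] <- stats::runif(sum(known), 0, 0.01)
    maf[planted == "maf"] <- stats::runif(n_maf, 0.0101, 0.5)
    tibble::tibble(
      sample_id = sample_id,
      chromosome = sample(c("autosome", "chrX"), total, replace = TRUE,
                          prob = c(0.9, 0.1)),
      position = sample.int(1e6, total, replace = TRUE),
      ref_base = substr(classes, 1, 1),
      alt_base = substr(classes, 3, 3),
      coverage = coverage,
      vaf = vaf,
      population_maf = maf,
      consequence = sample(c("missense", "splice_site"), total,
                           replace = TRUE, prob = c(0.9, 0.1)),
      planted_fail = planted
    )
  })
}
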