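#' Run the full synthetic-to-result pipeline
#'
#' Executes every stage in dependency order — simulate references, reads
#' and tables; deconvolve the read set; estimate copy number against the
#' normal panel and call gains/losses; filter variants and tally the
#' substitution spectrum; quantify plasma copy numbers, fit the
#' ratio-vs-load regression and classify candidates; call differentially
#' expressed genes — writing each stage's output under `outdir` and
#' returning a machine-readable run manifest. Rerunning with the same
#' configuration reproduces every output file byte-identically.
#'
#' @param config A [sim_config()], or a path to a YAML file whose keys are
#'   `sim_config()` arguments.
#' @param outdir Output directory (created if missing).
#' @param n_reads Reads to simulate for the deconvolution stage.
#' @param cutoff Plasma ratio cutoff for candidate classification.
#' @return A list with `manifest` (tibble: stage, status, outputs) and the
#'   in-memory stage results (`partition`, `cnv_profile`, `spectrum`,
#'   `plasma_fit`, `calls`, `deg`).
#' @export
run_pipeline <- function(config, outdir = tempfile("pdxscreen_run_"),
                         n_reads = 2000L, cutoff = 4) {
  if (is.character(config)) {
    spec <- yaml::read_yaml(config)
    config <- do.call(sim_config, spec)
  }
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, outputs) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, status = "completed",
      outputs = paste(basename(outputs), collapse = ";")
    )
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # --- simulate ---
  refs <- run_stage("simulate", sim_reference_pair(config))
  write_fasta(refs$human, file.path(outdir, "human.fa"))
  write_fasta(refs$mouse, file.path(outdir, "mouse.fa"))
  reads <- sim_reads(config, refs, n_reads)
  write_fastq(reads, file.path(outdir, "reads.fastq"))
  exons <- sim_gene_models(config)
  write_gene_bed(exons, file.path(outdir, "genes.bed"))
  gm <- as_gene_models(exons)
  cov <- sim_coverage(config, gm)
  write_counts_tsv(cov$counts, file.path(outdir, "gene_counts.tsv"))
  note("simulate", c("human.fa", "mouse.fa", "reads.fastq", "genes.bed",
                     "gene_counts.tsv"))

  # --- xenofilter ---
  part <- run_stage("xenofilter",
                    partition_reads(reads, refs$human, refs$mouse))
  write_fastq(part$human, file.path(outdir, "reads.human.fastq"))
  jsonlite::write_json(part$summary, file.path(outdir, "xenofilter.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  note("xenofilter", c("reads.human.fastq", "xenofilter.json"))

  # --- cnv ---
  profile <- run_stage("cnv", call_gain_loss(to_copy_number(
    cov$counts[c("gene_id", "tumor")],
    cov$counts[c("gene_id", grep("^normal_", names(cov$counts), value = TRUE))],
    gm
  )))
  readr::write_tsv(profile, file.path(outdir, "cnv_profile.tsv"))
  note("cnv", "cnv_profile.tsv")

  # --- variants ---
  variants <- run_stage("variants", sim_variant_table(
    config, c(sample_1 = 60L, sample_2 = 60L),
    fail_fraction = c(coverage = 0.1, vaf = 0.1, maf = 0.1)
  ))
  kept <- filter_variants(variants)
  spectrum <- substitution_spectrum(kept$retained)
  readr::write_tsv(spectrum, file.path(outdir, "spectrum.tsv"))
  note("variants", "spectrum.tsv")

  # --- plasma ---
  cohort <- run_stage("plasma", sim_plasma_cohort(config))
  cohort$ratio <- cnv_ratio(cohort$cn_ccnd1, cohort$cn_cdkn2a)$ratio
  fit <- fit_load_regression(cohort)
  calls <- classify_candidate(cohort, cutoff = cutoff)
  readr::write_csv(calls, file.path(outdir, "plasma_calls.csv"))
  jsonlite::write_json(glance(fit), file.path(outdir, "plasma_fit.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  note("plasma", c("plasma_calls.csv", "plasma_fit.json"))

  # --- expression ---
  expr_sim <- run_stage("expression",
                        sim_expression(config, n_genes = 500L, n_de = 25L))
  deg <- call_deg(expr_sim$treated, expr_sim$control, expr_sim$gene_lengths)
  readr::write_tsv(deg, file.path(outdir, "deg.tsv"))
  note("expression", "deg.tsv")

  manifest <- dplyr::bind_rows(manifest)
  manifest$seed <- config$seed
  readr::write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  list(
    manifest = manifest, outdir = outdir,
    partition = part, cnv_profile = profile, spectrum = spectrum,
    plasma_fit = fit, calls = calls, deg = deg
  )
}
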