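mk_ct <- function(sample_id, targets, cts, reps = 1) {
  tidyr::expand_grid(sample_id = sample_id,
                     target = targets, replicate = seq_len(reps)) |>
    dplyr::mutate(ct = rep(cts, each = reps))
}

test_that("delta-delta-Ct quantification follows the doubling model", {
  targets <- c("CCND1", "CDKN2A", "RAD52")
  cal <- mk_ct("PBMC", targets, c(25, 25, 25), reps = 2)
  # sample identical to calibrator -> CN 2 everywhere
  same <- qpcr_copy_number(mk_ct("s", targets, c(25, 25, 25), reps = 2), cal)
  expect_equal(same$cn, rep(2, 3))
  # target one cycle below calibrator, control equal -> CN 4
  one_lower <- qpcr_copy_number(mk_ct("s", targets, c(24, 25, 25)), cal)
  expect_equal(one_lower$cn[one_lower$target == "CCND1"], 4)
  # non-detect target -> CN 0, flagged
  nd <- qpcr_copy_number(mk_ct("s", targets, c(NA, 25, 25)), cal)
  expect_identical(nd$cn[nd$target == "CCND1"], 0)
  expect_true(nd$non_detect[nd$target == "CCND1"])
  # discordant replicates flagged
  disc <- qpcr_copy_number(
    tibble::tibble(sample_id = "s", target = rep(targets, each = 2),
                   replicate = rep(1:2, 3),
                   ct = c(24, 25, 25, 25, 25, 25)), cal
  )
  expect_true(disc$discordant_replicates[disc$target == "CCND1"])
  # errors: missing control, calibrator non-detect
  expect_error(
    qpcr_copy_number(mk_ct("s", c("CCND1", "CDKN2A"), c(25, 25)), cal),
    "control target"
  )
  expect_error(
    qpcr_copy_number(mk_ct("s", targets, c(25, 25, 25)),
                     mk_ct("PBMC", targets, c(NA, 25, 25))),
    "calibrator"
  )
})

test_that("zero-noise qPCR round trip is exact at CN 22", {
  cfg <- sim_config(seed = 107)
  truth <- tibble::tibble(sample_id = "hi_load", target = "CCND1", cn = 22)
  q <- sim_qpcr(cfg, truth, ct_noise_sd = 0)
  est <- qpcr_copy_number(q$measurements, q$calibrator)
  expect_equal(est$cn[est$target == "CCND1"], 22, tolerance = 1e-12)
  # reduced efficiency round-trips too when both sides agree on it
  cfg2 <- sim_config(seed = 107, qpcr_efficiency = 0.9)
  q2 <- sim_qpcr(cfg2, truth, ct_noise_sd = 0)
  est2 <- qpcr_copy_number(q2$measurements, q2$calibrator, efficiency = 0.9)
  expect_equal(est2$cn[est2$target == "CCND1"], 22, tolerance = 1e-10)
})

test_that("cnv_ratio floors the denominator and flags it", {
  expect_equal(cnv_ratio(2, 2)$ratio, 1)
  expect_equal(cnv_ratio(8, 2)$ratio, 4)
  res <- cnv_ratio(2, 0, epsilon = 0.05)
  expect_equal(res$ratio, 40)
  expect_true(res$denominator_floored)
  expect_false(cnv_ratio(8, 2)$denominator_floored)
  expect_error(cnv_ratio(-1, 2), "non-negative")
})

test_that("regression on exact points returns the generating line", {
  d <- tibble::tibble(
    ebv_load = c(1e4, 1e5, 1e6),
    ratio = 11.11 * c(4, 5, 6) - 36.93
  )
  fit <- fit_load_regression(d)
  expect_equal(fit$slope, 11.11, tolerance = 1e-9)
  expect_equal(fit$intercept, -36.93, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-12)
  # constant ratio: slope 0, r reported as 0 by convention
  flat <- tibble::tibble(ebv_load = c(1e4, 1e5, 1e6), ratio = 2)
  ffit <- fit_load_regression(flat)
  expect_equal(ffit$slope, 0, tolerance = 1e-12)
  expect_equal(ffit$pearson_r, 0)
  # degenerate inputs
  expect_error(fit_load_regression(d[1:2, ]), "at least 3")
  expect_error(
    fit_load_regression(tibble::tibble(ebv_load = rep(1e4, 5), ratio = 1:5)),
    "slope undefined"
  )
  expect_warning(
    fit_load_regression(dplyr::bind_rows(d, tibble::tibble(ebv_load = 0,
                                                           ratio = 1))),
    "excluded"
  )
})

test_that("tidy and glance expose the fit in broom shape", {
  fit <- fit_load_regression(synthetic_plasma_cohort())
  td <- tidy(fit)
  expect_identical(td$term, c("intercept", "log10_load"))
  expect_equal(td$estimate, c(fit$intercept, fit$slope))
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$r.squared, fit$pearson_r^2, tolerance = 1e-12)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("predicted ratio reproduces the worked example at 5000 copies/ml", {
  fit <- list(slope = 11.11, intercept = -36.93)
  expect_equal(ratio_at_load(fit, 5000), 4.17, tolerance = 0.005)
  expect_equal(round(ratio_at_load(fit, 5000)), 4)
  expect_equal(ratio_at_load(fit, 1e5), 18.62, tolerance = 1e-9)
  expect_error(ratio_at_load(fit, 0), "positive")
  # strictly increasing in load for positive slope
  loads <- c(5e3, 1e4, 1e5, 1e6)
  expect_true(all(diff(ratio_at_load(fit, loads)) > 0))
  # slope 0: constant prediction
  expect_equal(ratio_at_load(list(slope = 0, intercept = 7), loads),
               rep(7, 4))
})

test_that("noise-free self-fit recovers the generating coefficients", {
  cfg <- sim_config(seed = 109, plasma_noise_sd = 0)
  cohort <- sim_plasma_cohort(cfg, n_patients = 50, load_range = c(5e3, 1e6))
  cohort$ratio <- cnv_ratio(cohort$cn_ccnd1, cohort$cn_cdkn2a)$ratio
  fit <- fit_load_regression(cohort)
  expect_equal(fit$slope, 11.11, tolerance = 1e-9)
  expect_equal(fit$intercept, -36.93, tolerance = 1e-9)
  expect_equal(fit$pearson_r, 1, tolerance = 1e-9)
})

test_that("slope is recovered across seeded noisy cohorts", {
  slopes <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = 1000 + s, plasma_noise_sd = 2)
    cohort <- sim_plasma_cohort(cfg, n_patients = 22,
                                load_range = c(5e3, 1e6))
    cohort$ratio <- cnv_ratio(cohort$cn_ccnd1, cohort$cn_cdkn2a)$ratio
    fit_load_regression(cohort)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 11.11) / 11.11, 0.10)
  # single-cohort sampling check: recovered slope within 2 OLS SEs
  cfg <- sim_config(seed = 113, plasma_noise_sd = 2)
  cohort <- sim_plasma_cohort(cfg, n_patients = 200,
                              load_range = c(5e3, 1e6))
  cohort$ratio <- cnv_ratio(cohort$cn_ccnd1, cohort$cn_cdkn2a)$ratio
  fit <- fit_load_regression(cohort)
  se <- tidy(fit)$std.error[2]
  expect_lt(abs(fit$slope - 11.11), 2 * se)
})

test_that("gene-load correlations behave at the extremes", {
  d <- tibble::tibble(
    ebv_load = 10^seq(3.7, 6, length.out = 10),
    cn_ccnd1 = seq(2, 20, length.out = 10),
    cn_cdkn2a = rep(2, 10)
  )
  expect_equal(gene_load_correlation(d, "CCND1"), 1, tolerance = 1e-12)
  expect_error(gene_load_correlation(d, "CDKN2A"), "zero variance")
  expect_error(gene_load_correlation(d, "RAD52"), "no column")
  # independence: |r| small at n = 200
  set.seed(127)
  big <- tibble::tibble(
    ebv_load = 10^runif(200, 3.7, 6),
    cn_ccnd1 = rnorm(200, 10, 2)
  )
  expect_lt(abs(gene_load_correlation(big, "CCND1")), 0.15)
})

test_that("candidate classification is strict at the cutoff", {
  d <- tibble::tibble(patient_id = c("a", "b", "c"),
                      ratio = c(1, 4, 4.17))
  calls <- classify_candidate(d, cutoff = 4)
  expect_identical(calls$candidate, c(FALSE, FALSE, TRUE))
  expect_true(all(calls$candidate == (calls$ratio > calls$cutoff)))
})

test_that("qPCR and read-density copy numbers of one truth concord", {
  # the two quantification routes measure the same planted truth and must
  # agree (analogue of the cross-method validation r = 0.89-0.95)
  cfg <- sim_config(seed = 131, n_genes = 60, depth = 150, n_normals = 4)
  gm <- as_gene_models(sim_gene_models(cfg))
  auto <- gm$gene_id[!gm$is_sex_chromosome][1:12]
  truth <- stats::setNames(rep(c(0.5, 1, 2, 3, 4, 6), 2), auto)
  cfg <- sim_config(seed = 131, n_genes = 60, depth = 150, n_normals = 4,
                    planted_cnv = truth)
  cov <- sim_coverage(cfg, gm)
  wes <- to_copy_number(cov$counts[c("gene_id", "tumor")],
                        cov$counts[c("gene_id", paste0("normal_", 1:4))], gm)
  q <- sim_qpcr(cfg, tibble::tibble(sample_id = "pdx", target = auto,
                                    cn = unname(truth)),
                ct_noise_sd = 0.1)
  qcn <- qpcr_copy_number(q$measurements, q$calibrator,
                          control_target = "RAD52")
  merged <- dplyr::inner_join(
    wes[wes$gene_id %in% auto, c("gene_id", "cn")],
    qcn[, c("target", "cn")], by = c(gene_id = "target")
  )
  expect_gte(stats::cor(merged$cn.x, merged$cn.y), 0.89)
})
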