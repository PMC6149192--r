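test_that("percentile rule removes the expected amplicons", {
  # 20 amplicons with distinct means: exactly one falls at or below the
  # 5th percentile (linear-interpolation definition)
  amps <- tibble::tibble(
    amplicon_id = sprintf("a%02d", 1:20),
    gene_id = "G", pool = 1L,
    c1 = as.numeric(10 * (1:20)), c2 = as.numeric(10 * (1:20))
  )
  res <- filter_amplicons(amps)
  expect_identical(res$removed$amplicon_id, "a01")
  expect_identical(res$removed$reason, "low_coverage")
  # oracle: brute-force percentile on the 20 means
  means <- rowMeans(cbind(amps$c1, amps$c2))
  cut <- sort(means)[1] + 0.95 * (sort(means)[2] - sort(means)[1])
  expect_identical(sum(means <= cut), 1L)
})

test_that("CV rule uses the sample standard deviation", {
  amps <- tibble::tibble(
    amplicon_id = c("flat", "noisy", paste0("f", 1:20)),
    gene_id = "G", pool = 1L,
    c1 = c(110, 150, 100 + 1:20), c2 = c(110, 250, 100 + 1:20)
  )
  res <- filter_amplicons(amps, cv_threshold = 0.3)
  # (150, 250): mean 200, sample sd ~70.7 -> CV ~0.354 >= 0.3 -> removed
  expect_true("noisy" %in% res$removed$amplicon_id)
  expect_identical(res$removed$reason[res$removed$amplicon_id == "noisy"],
                   "high_cv")
  # identical counts: CV exactly 0, never CV-removed
  expect_false("flat" %in%
                 res$removed$amplicon_id[res$removed$reason == "high_cv"])
  # brute-force oracle for the CV convention on the stated pair (10, 30)
  expect_equal(sd(c(10, 30)) / mean(c(10, 30)), sqrt(2) / 2,
               tolerance = 1e-12)
  expect_gte(sqrt(2) / 2, 0.3) # so such an amplicon is always removed
})

test_that("raising the CV threshold never removes more amplicons", {
  set.seed(83)
  amps <- tibble::tibble(
    amplicon_id = sprintf("a%03d", 1:100),
    gene_id = rep(c("A", "B"), 50), pool = rep(1:2, each = 50),
    c1 = rpois(100, 100), c2 = rpois(100, 100), c3 = rpois(100, 100)
  )
  n_removed <- vapply(c(0.1, 0.2, 0.3, 0.5, 1), function(cv) {
    nrow(filter_amplicons(amps, cv_threshold = cv)$removed)
  }, numeric(1))
  expect_true(all(diff(n_removed) <= 0))
  # the CV rule reaches a fixpoint after one pass: re-filtering the
  # survivors never removes anything else for high CV (the percentile rule
  # is a single-pass cut by construction and is re-estimated each run)
  once <- filter_amplicons(amps, cv_threshold = 0.3)
  twice <- filter_amplicons(once$retained, cv_threshold = 0.3)
  expect_false(any(twice$removed$reason == "high_cv"))
  expect_error(
    filter_amplicons(dplyr::mutate(amps, c1 = 0, c2 = 0, c3 = 0)),
    "detectable"
  )
})

test_that("pool normalization equalizes pool medians within a sample", {
  # pool medians 100 and 200, global median 100: pool-2 counts halved
  amps <- tibble::tibble(
    amplicon_id = sprintf("a%d", 1:7),
    gene_id = "G",
    pool = c(rep(1L, 5), 2L, 2L),
    s1 = c(90, 100, 100, 100, 110, 195, 205)
  )
  norm <- pool_normalize(amps)
  expect_equal(median(norm$s1[norm$pool == 1]),
               median(norm$s1[norm$pool == 2]))
  expect_equal(norm$s1[norm$pool == 2] / amps$s1[amps$pool == 2],
               rep(0.5, 2))
  expect_equal(norm$s1[1:5], amps$s1[1:5]) # pool 1 already at the target
  # single pool with the global-median target: unchanged
  one <- pool_normalize(dplyr::mutate(amps, pool = 1L))
  expect_equal(one$s1, amps$s1)
  # relative convention: every pool median becomes 1
  rel <- pool_normalize(amps, target = "relative")
  expect_equal(median(rel$s1[rel$pool == 1]), 1)
  expect_equal(median(rel$s1[rel$pool == 2]), 1)
  # amplicon order is irrelevant
  perm <- sample(7)
  norm_p <- pool_normalize(amps[perm, ])
  expect_equal(norm_p$s1, norm$s1[perm])
})

test_that("relative pool normalization makes gene CN depth-free", {
  set.seed(91)
  amps <- tibble::tibble(
    amplicon_id = sprintf("a%02d", 1:40),
    gene_id = rep(c("A", "B"), each = 20),
    pool = rep(1:2, 20),
    tumor = rpois(40, 300),
    n1 = rpois(40, 100), n2 = rpois(40, 100)
  )
  cn1 <- panel_copy_number(pool_normalize(amps, target = "relative"),
                           "tumor", c("n1", "n2"))
  scaled <- dplyr::mutate(amps, tumor = tumor * 7)
  cn7 <- panel_copy_number(pool_normalize(scaled, target = "relative"),
                           "tumor", c("n1", "n2"))
  expect_equal(cn7$cn, cn1$cn, tolerance = 1e-12)
})

test_that("gene copy number is twice the median amplicon ratio", {
  amps <- tibble::tibble(
    amplicon_id = sprintf("a%d", 1:4),
    gene_id = c("G", "G", "G", "H"), pool = 1L,
    tumor = c(140, 150, 160, 100),
    n1 = c(100, 100, 100, 100), n2 = c(100, 100, 100, 100)
  )
  prof <- panel_copy_number(amps, "tumor", c("n1", "n2"))
  expect_equal(prof$cn[prof$gene_id == "G"], 3) # median(1.4,1.5,1.6)*2
  expect_equal(prof$cn[prof$gene_id == "H"], 2)
  # median oracle on a <= 10 element instance
  expect_equal(median(c(1.4, 1.5, 1.6)), 1.5, tolerance = 1e-12)
  # tumor identical to normals -> cn 2 everywhere
  same <- panel_copy_number(
    dplyr::mutate(amps, tumor = n1), "tumor", c("n1", "n2")
  )
  expect_true(all(same$cn == 2))
})

test_that("planted panel copy number is recovered from noisy amplicons", {
  set.seed(89)
  n_amp <- 8
  truth_cn <- 4
  amps <- tibble::tibble(
    amplicon_id = sprintf("a%d", 1:n_amp),
    gene_id = "CCND1", pool = rep(1:2, each = n_amp / 2),
    tumor = rpois(n_amp, 200 * truth_cn / 2),
    n1 = rpois(n_amp, 200), n2 = rpois(n_amp, 200), n3 = rpois(n_amp, 200)
  )
  prof <- panel_copy_number(amps, "tumor", c("n1", "n2", "n3"))
  expect_lt(abs(prof$cn - truth_cn), 0.5)
})

test_that("panel-based and read-density profiles of one truth agree", {
  # 40 genes / 400 amplicons, planted gains and losses; the two
  # independent quantifications of the same truth must concord (r > 0.9)
  set.seed(97)
  n_genes <- 40
  genes <- sprintf("g%02d", 1:n_genes)
  true_cn <- rep(2, n_genes)
  true_cn[1:4] <- c(6, 6, 0, 1)
  # amplicon panel: 10 amplicons per gene
  amp <- tibble::tibble(
    amplicon_id = sprintf("a%03d", 1:(10 * n_genes)),
    gene_id = rep(genes, each = 10),
    pool = rep(1:4, length.out = 10 * n_genes)
  )
  cn_amp <- rep(true_cn, each = 10)
  amp$tumor <- rpois(nrow(amp), 150 * cn_amp / 2)
  for (j in 1:3) amp[[paste0("n", j)]] <- rpois(nrow(amp), 150)
  panel_prof <- panel_copy_number(
    pool_normalize(filter_amplicons(amp, c("n1", "n2", "n3"))$retained),
    "tumor", c("n1", "n2", "n3")
  )
  # read-density route on the same truth
  gm <- tibble::tibble(gene_id = genes, chromosome = "autosome",
                       start = 0L, end = 1500L)
  counts <- tibble::tibble(
    gene_id = genes,
    tumor = rpois(n_genes, 150 * true_cn / 2 * 1.5),
    nn1 = rpois(n_genes, 225), nn2 = rpois(n_genes, 225)
  )
  wes_prof <- to_copy_number(counts[c("gene_id", "tumor")],
                             counts[c("gene_id", "nn1", "nn2")], gm)
  conc <- cn_correlation(panel_prof, wes_prof)
  expect_gt(conc$pearson_r, 0.9)
})
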