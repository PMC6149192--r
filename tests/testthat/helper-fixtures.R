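# Shared fixture builders; everything is generated in code at test time.

tiny_gene_models <- function() {
  tibble::tibble(
    gene_id = c("g_auto", "g_auto", "g_x"),
    chromosome = c("autosome", "autosome", "chrX"),
    start = c(0L, 3000L, 0L),
    end = c(1000L, 4000L, 2000L)
  )
}

# amplicon panel with per-amplicon Poisson-ish deterministic counts
tiny_amplicons <- function() {
  tibble::tibble(
    amplicon_id = sprintf("amp_%02d", 1:6),
    gene_id = rep(c("A", "B"), each = 3),
    pool = rep(c(1L, 2L), 3),
    ctrl_1 = c(100, 110, 90, 200, 210, 190),
    ctrl_2 = c(102, 108, 92, 198, 214, 186)
  )
}

# textbook Pearson correlation, kept independent of stats::cor
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - sum(x) / n) * (y - sum(y) / n)) /
    sqrt(sum((x - sum(x) / n)^2) * sum((y - sum(y) / n)^2))
}
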