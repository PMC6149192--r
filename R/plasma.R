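#' Copy numbers from qPCR cycle thresholds (delta-delta-Ct)
#'
#' Quantifies each target relative to a reference gene (`control_target`,
#' RAD52 by default) and a healthy-PBMC calibrator assumed diploid:
#' replicate Ct values are averaged, then
#' `dCt = Ct(target) - Ct(control)` per sample,
#' `ddCt = dCt(sample) - dCt(calibrator)`, and
#' `CN = 2 * (1 + efficiency)^(-ddCt)` (perfect doubling,
#' `efficiency = 1`, gives the familiar `2 * 2^-ddCt`). A non-detected
#' target (`NA` Ct) is reported as copy number 0 with a flag; replicates
#' more than `replicate_tolerance` cycles apart are flagged as discordant
#' but still averaged.
#'
#' @param measurements Tibble with `sample_id`, `target`, `replicate`,
#'   `ct` for the samples to quantify.
#' @param calibrator Same columns for the calibrator (all targets must be
#'   detected).
#' @param control_target Reference gene name (default `"RAD52"`).
#' @param efficiency Amplification efficiency in `(0, 1]`.
#' @param replicate_tolerance Max allowed replicate Ct spread before the
#'   `discordant_replicates` flag is set (default 0.5 cycles).
#' @return Tibble with `sample_id`, `target`, `cn`, `non_detect`,
#'   `discordant_replicates`.
#' @export
qpcr_copy_number <- function(measurements, calibrator,
                             control_target = "RAD52", efficiency = 1,
                             replicate_tolerance = 0.5) {
  if (efficiency <= 0 || efficiency > 1) {
    stop("`efficiency` must lie in (0, 1]", call. = FALSE)
  }
  amp <- 1 + efficiency
  summarize_ct <- function(df) {
    dplyr::summarise(
      dplyr::group_by(df, sample_id, target),
      spread = if (all(is.na(ct))) 0 else diff(range(ct, na.rm = TRUE)),
      ct = mean(ct), # NA propagates: any non-detect replicate -> non-detect
      .groups = "drop"
    )
  }
  samp <- summarize_ct(measurements)
  cal <- summarize_ct(calibrator)
  if (anyNA(cal$ct)) stop("calibrator has a non-detected target", call. = FALSE)
  cal_dct <- cal$ct - cal$ct[match(control_target, cal$target)]
  names(cal_dct) <- cal$target
  if (!control_target %in% samp$target) {
    stop("control target '", control_target, "' missing from measurements",
         call. = FALSE)
  }
  out <- dplyr::group_modify(
    dplyr::group_by(samp, sample_id),
    function(df, key) {
      ctrl_ct <- df$ct[match(control_target, df$target)]
      if (is.na(ctrl_ct)) {
        stop("control target not detected in sample ", key$sample_id,
             call. = FALSE)
      }
      if (anyNA(match(df$target, names(cal_dct)))) {
        stop("calibrator is missing a measured target", call. = FALSE)
      }
      ddct <- (df$ct - ctrl_ct) - cal_dct[df$target]
      tibble::tibble(
        target = df$target,
        cn = ifelse(is.na(df$ct), 0, 2 * amp^(-ddct)),
        non_detect = is.na(df$ct),
        discordant_replicates = df$spread > replicate_tolerance
      )
    }
  )
  dplyr::ungroup(out)
}

#' CCND1/CDKN2A copy-number ratio
#'
#' `ratio = cn_ccnd1 / max(cn_cdkn2a, epsilon)`. The epsilon floor keeps
#' the ratio finite for samples with homozygous CDKN2A deletion while
#' preserving its "very large" semantics; floored denominators are
#' flagged.
#'
#' @param cn_ccnd1,cn_cdkn2a Non-negative copy numbers (vectorized).
#' @param epsilon Denominator floor (default 0.05).
#' @return Tibble with `ratio` and `denominator_floored`.
#' @export
#' @examples
#' cnv_ratio(8, 2)     # ratio 4
#' cnv_ratio(2, 0)     # floored: ratio 40
cnv_ratio <- function(cn_ccnd1, cn_cdkn2a, epsilon = 0.05) {
  if (any(cn_ccnd1 < 0) || any(cn_cdkn2a < 0)) {
    stop("copy numbers must be non-negative", call. = FALSE)
  }
  floored <- cn_cdkn2a < epsilon
  tibble::tibble(
    ratio = cn_ccnd1 / pmax(cn_cdkn2a, epsilon),
    denominator_floored = floored
  )
}

#' Fit the ratio vs log10 EBV-load regression
#'
#' Ordinary least squares of the CCND1/CDKN2A ratio on log10 EBV DNA load
#' (copies/ml), with the Pearson correlation of the same pairs. Samples
#' with non-positive load are excluded with a warning (log10 undefined).
#'
#' @param samples Tibble containing the load and ratio columns.
#' @param load_col,ratio_col Column names (defaults `"ebv_load"`,
#'   `"ratio"`).
#' @return An object of class `plasma_fit`: list with `slope`,
#'   `intercept`, `pearson_r`, `n`, `model` (the underlying `lm`), `data`.
#' @export
#' @examples
#' d <- tibble::tibble(ebv_load = c(1e4, 1e5, 1e6),
#'                     ratio = 11.11 * c(4, 5, 6) - 36.93)
#' fit <- fit_load_regression(d)
#' fit$slope
fit_load_regression <- function(samples, load_col = "ebv_load",
                                ratio_col = "ratio") {
  load <- samples[[load_col]]
  ratio <- samples[[ratio_col]]
  bad <- !is.finite(load) | load <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with non-positive load excluded")
    load <- load[!bad]
    ratio <- ratio[!bad]
  }
  if (length(load) < 3) stop("need at least 3 samples", call. = FALSE)
  x <- log10(load)
  if (stats::sd(x) == 0) {
    stop("all loads equal: slope undefined", call. = FALSE)
  }
  model <- stats::lm(ratio ~ x)
  r <- if (stats::sd(ratio) == 0) 0 else stats::cor(x, ratio)
  structure(
    list(
      slope = unname(stats::coef(model)[2]),
      intercept = unname(stats::coef(model)[1]),
      pearson_r = r,
      n = length(x),
      model = model,
      data = tibble::tibble(log10_load = x, ratio = ratio)
    ),
    class = "plasma_fit"
  )
}

#' @export
print.plasma_fit <- function(x, ...) {
  cat("<plasma_fit> ratio =", format(x$slope, digits = 4),
      "* log10(load) +", format(x$intercept, digits = 4), "\n")
  cat("  Pearson r =", format(x$pearson_r, digits = 3), " n =", x$n, "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a plasma ratio regression
#'
#' @param x A `plasma_fit`.
#' @param ... Unused.
#' @return Tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`).
#' @method tidy plasma_fit
#' @export
tidy.plasma_fit <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("intercept", "log10_load"),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' One-row summary of a plasma ratio regression
#'
#' @param x A `plasma_fit`.
#' @param ... Unused.
#' @return Tibble with `slope`, `intercept`, `pearson_r`, `r.squared`, `n`.
#' @method glance plasma_fit
#' @export
glance.plasma_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    pearson_r = x$pearson_r,
    r.squared = summary(x$model)$r.squared,
    n = x$n
  )
}

#' Predicted ratio at a given EBV DNA load
#'
#' @param fit A `plasma_fit` (or any list with `slope` and `intercept`).
#' @param load EBV DNA copies/ml (positive; vectorized).
#' @return Predicted CCND1/CDKN2A ratio(s).
#' @export
#' @examples
#' fit <- list(slope = 11.11, intercept = -36.93)
#' ratio_at_load(fit, 5000) # ~4.17
ratio_at_load <- function(fit, load) {
  if (any(load <= 0)) stop("`load` must be positive", call. = FALSE)
  fit$slope * log10(load) + fit$intercept
}

#' Correlation of one gene's copy number with log10 EBV load
#'
#' @param samples Plasma cohort tibble with `ebv_load` and a `cn_<gene>`
#'   column.
#' @param gene Target name, e.g. `"CDKN2A"` (matched case-insensitively to
#'   the `cn_` column).
#' @return Pearson correlation coefficient.
#' @export
gene_load_correlation <- function(samples, gene) {
  col <- paste0("cn_", tolower(gene))
  if (!col %in% names(samples)) {
    stop("no column '", col, "' in samples", call. = FALSE)
  }
  if (nrow(samples) < 3) stop("need at least 3 samples", call. = FALSE)
  cn <- samples[[col]]
  x <- log10(samples$ebv_load)
  if (stats::sd(cn) == 0 || stats::sd(x) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(cn, x)
}

#' Classify CDK4/6-inhibitor candidates from the plasma ratio
#'
#' A patient is a candidate iff the CCND1/CDKN2A ratio strictly exceeds
#' the cutoff (default 4, the ratio corresponding to an EBV DNA load of
#' about 5000 copies/ml under the fitted regression). The boundary is
#' exclusive: a ratio exactly at the cutoff is not a candidate.
#'
#' @param samples Tibble with a `ratio` column (e.g. a plasma cohort after
#'   [cnv_ratio()]).
#' @param cutoff Ratio cutoff (default 4).
#' @return The tibble with added `cutoff` and `candidate` columns.
#' @export
classify_candidate <- function(samples, cutoff = 4) {
  dplyr::mutate(samples, cutoff = cutoff, candidate = ratio > cutoff)
}
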