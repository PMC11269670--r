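one_tailed_p <- function(x, mu0) {
  n <- length(x)
  s <- stats::sd(x)
  if (s == 0) {
    # zero-variance convention: certain if strictly above, else p = 1
    return(if (mean(x) > mu0) 0 else 1)
  }
  stats::pt((mean(x) - mu0) / (s / sqrt(n)), df = n - 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment with a rejection set
#'
#' Standard step-up false-discovery-rate control: adjusted p-values from
#' [stats::p.adjust()] with `method = "BH"`, plus the rejection decision at
#' the requested FDR.
#'
#' @param pvals Raw p-values in `[0, 1]`.
#' @param fdr Target false discovery rate (default 0.05).
#' @return A tibble with `p`, `p_adj`, `reject`.
#' @export
bh_adjust <- function(pvals, fdr = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  tibble::tibble(p = pvals, p_adj = adj, reject = adj < fdr)
}

#' Per-part burden estimates and significance tests
#'
#' Burden is the percentage reduction in normalized growth rate,
#' `100 * (1 - normalized rate)`, summarised per part across all replicate
#' measurements and plates. For each threshold (percent), a one-sample
#' one-tailed t-test of "mean burden > threshold" is computed; the p-values
#' against zero burden are Benjamini-Hochberg adjusted across parts. The
#' 95% confidence half-width comes from the t distribution. Parts with a
#' single measurement are flagged untestable (`NA` p-values).
#'
#' @param normalized A tibble with one row per measurement, containing the
#'   part identifier and a normalized growth-rate column.
#' @param part_col Name of the part identifier column (default `"strain"`).
#' @param rate_col Name of the normalized growth-rate column
#'   (default `"normalized_r_max"`).
#' @param thresholds Burden thresholds, in percent (default
#'   `c(0, 10, 20, 30, 45)`; 45% is the model's constructability bound).
#' @param fdr FDR for the adjusted test against zero burden (default 0.05).
#' @return A tibble, one row per part: `part`, `n`, `burden_pct`, `sem`,
#'   `ci95`, one `p_vs_<threshold>` column per threshold, `p_bh_0`,
#'   `significant` (BH-adjusted p vs 0 below `fdr`), `untestable`.
#' @export
burden_summary <- function(normalized, part_col = "strain",
                           rate_col = "normalized_r_max",
                           thresholds = c(0, 10, 20, 30, 45), fdr = 0.05) {
  stopifnot(part_col %in% names(normalized), rate_col %in% names(normalized))
  res <- normalized |>
    dplyr::filter(is.finite(.data[[rate_col]])) |>
    dplyr::group_by(part = .data[[part_col]]) |>
    dplyr::summarise(
      n = dplyr::n(),
      burden_pct = mean(100 * (1 - .data[[rate_col]])),
      sem = stats::sd(100 * (1 - .data[[rate_col]])) / sqrt(dplyr::n()),
      values = list(100 * (1 - .data[[rate_col]])),
      .groups = "drop")
  res$ci95 <- ifelse(res$n >= 2,
                     stats::qt(0.975, res$n - 1) * res$sem, NA_real_)
  for (thr in thresholds) {
    res[[paste0("p_vs_", thr)]] <- purrr::map2_dbl(
      res$values, res$n,
      function(v, n) if (n >= 2) one_tailed_p(v, thr) else NA_real_)
  }
  res$untestable <- res$n < 2
  testable <- !res$untestable
  res$p_bh_0 <- NA_real_
  res$p_bh_0[testable] <- stats::p.adjust(res$p_vs_0[testable], method = "BH")
  res$significant <- !is.na(res$p_bh_0) & res$p_bh_0 < fdr
  dplyr::select(res, -"values")
}

#' Trend of growth-rate SEM with burden
#'
#' When mutant takeover is already underway in some replicate cultures,
#' high-burden parts show more variable measured growth rates. This tests
#' for that signature: ordinary least-squares regression of each part's
#' standard error of the mean growth rate on its mean burden, with a
#' two-tailed t-test for a non-zero slope.
#'
#' @param burden A burden tibble from [burden_summary()] (needs `burden_pct`
#'   and `sem` with at least 3 parts).
#' @return A one-row tibble: `slope` (SEM percentage points per burden
#'   percentage point), `std_error`, `statistic`, `p_value`, `n_parts`.
#' @export
sem_burden_trend <- function(burden) {
  dat <- dplyr::filter(burden, is.finite(.data$sem), is.finite(.data$burden_pct))
  if (nrow(dat) < 3) stop("need at least 3 parts", call. = FALSE)
  fit <- stats::lm(sem ~ burden_pct, data = dat)
  sm <- summary(fit)$coefficients
  tibble::tibble(slope = sm["burden_pct", "Estimate"],
                 std_error = sm["burden_pct", "Std. Error"],
                 statistic = sm["burden_pct", "t value"],
                 p_value = sm["burden_pct", "Pr(>|t|)"],
                 n_parts = nrow(dat))
}

#' Plot per-part burden estimates
#'
#' Parts ordered by mean burden with 95% confidence bars, coloured by
#' whether the burden is significantly greater than zero after FDR
#' correction.
#'
#' @param burden A burden tibble from [burden_summary()].
#' @return A ggplot.
#' @export
plot_burden <- function(burden) {
  dat <- dplyr::arrange(burden, .data$burden_pct) |>
    dplyr::mutate(part = factor(.data$part, levels = .data$part))
  ggplot2::ggplot(dat, ggplot2::aes(.data$part, .data$burden_pct,
                                    colour = .data$significant)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$burden_pct - .data$ci95,
      ymax = .data$burden_pct + .data$ci95), size = 0.2) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#e08214",
                                            `FALSE` = "grey50")) +
    ggplot2::labs(x = NULL, y = "burden (% growth-rate reduction)",
                  colour = "BH-significant") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}
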