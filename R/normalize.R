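#' Gaussian kernel density estimate by exact summation
#'
#' Evaluates the mean of Gaussian kernels (sd = `bandwidth`) centred at the
#' observed values on a grid. Computed by direct summation rather than
#' binned FFT so the curve is exact at every grid point; the vectors
#' involved here (dozens of rate estimates per plate) make this cheap.
#'
#' @param values Numeric observations (at least one).
#' @param bandwidth Kernel standard deviation (> 0).
#' @param grid Evaluation points; by default `n_grid` points spanning
#'   `range(values)` padded by `pad` bandwidths on each side.
#' @param n_grid Number of grid points (default 2048).
#' @param pad Padding in bandwidth units (default 4).
#' @return A tibble with columns `x` and `density`.
#' @export
kde_density <- function(values, bandwidth, grid = NULL, n_grid = 2048,
                        pad = 4) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no finite values", call. = FALSE)
  stopifnot(bandwidth > 0)
  if (is.null(grid)) {
    grid <- seq(min(values) - pad * bandwidth,
                max(values) + pad * bandwidth, length.out = n_grid)
  }
  dens <- vapply(grid, function(g) mean(stats::dnorm(g, values, bandwidth)),
                 numeric(1))
  tibble::tibble(x = grid, density = dens)
}

#' Per-plate no-burden reference rate from density peaks
#'
#' Most strains on a plate are expected to carry negligible burden, so the
#' mode of the plate's rate distribution estimates the plate's no-burden
#' rate. To be robust to multimodal distributions, all strict local maxima
#' of the Gaussian KDE are found on a dense grid, and among peaks at least
#' `min_height_frac` (default 50%) as high as the highest peak, the one at
#' the largest rate value is returned.
#'
#' @inheritParams kde_density
#' @param min_height_frac Minimum height of an admissible peak relative to
#'   the highest peak (default 0.5).
#' @return The no-burden reference rate (a single number).
#' @export
no_burden_reference <- function(values, bandwidth, n_grid = 2048, pad = 4,
                                min_height_frac = 0.5) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    stop("need at least 3 values to locate a density peak", call. = FALSE)
  }
  kd <- kde_density(values, bandwidth, n_grid = n_grid, pad = pad)
  y <- kd$density
  n <- length(y)
  is_peak <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] > y[3:n],
               FALSE)
  if (!any(is_peak)) {  # monotone density edge case: take the global max
    return(kd$x[which.max(y)])
  }
  px <- kd$x[is_peak]; py <- y[is_peak]
  keep <- py >= min_height_frac * max(py)
  max(px[keep])
}

#' Normalize rate estimates within a plate
#'
#' Divides every measurement of the chosen metric by the plate's no-burden
#' reference, which is estimated by [no_burden_reference()] from the
#' replicate-level values of non-control strains only (controls are
#' burdensome by design and would distort the reference, but their values
#' are normalized too).
#'
#' @param fits A fits tibble (one plate) from [fit_plate()].
#' @param metric `"growth_rate"` (column `r_max`) or `"production_rate"`.
#' @param bandwidth KDE bandwidth on the raw rate scale. Defaults:
#'   growth 0.014/60 per minute (the published per-hour bandwidth 0.014
#'   expressed in this package's per-minute rate units) and 300
#'   fluorescence units for production rates (instrument-scale dependent).
#' @param value_col Column holding the metric; default `r_max` for growth
#'   and the first `p_max_*` column for production.
#' @return The fits tibble with a `normalized_<col>` column added and the
#'   reference stored in attribute `"no_burden_value"`.
#' @export
normalize_plate <- function(fits, metric = c("growth_rate", "production_rate"),
                            bandwidth = NULL, value_col = NULL) {
  metric <- match.arg(metric)
  if (is.null(value_col)) {
    value_col <- if (metric == "growth_rate") "r_max" else {
      cand <- grep("^p_max_", names(fits), value = TRUE)
      if (!length(cand)) stop("no p_max_* column found", call. = FALSE)
      cand[1]
    }
  }
  if (is.null(bandwidth)) {
    bandwidth <- if (metric == "growth_rate") 0.014 / 60 else 300
  }
  vals <- fits[[value_col]][fits$role == "test"]
  vals <- vals[is.finite(vals)]
  if (length(vals) < 3) {
    stop("plate ", fits$plate[1], ": fewer than 3 non-control ", metric,
         " measurements", call. = FALSE)
  }
  ref <- no_burden_reference(vals, bandwidth)
  out <- fits
  out[[paste0("normalized_", value_col)]] <- fits[[value_col]] / ref
  attr(out, "no_burden_value") <- ref
  out
}

#' Normalize growth and production rates across plates
#'
#' Applies [normalize_plate()] per plate for the growth rate and every
#' fluorescence production-rate column, binding the plates back together
#' and recording each plate's reference values.
#'
#' @param fits A fits tibble covering one or more plates.
#' @param bandwidth_growth,bandwidth_prod KDE bandwidths (see
#'   [normalize_plate()]).
#' @return The fits tibble with `normalized_r_max` and
#'   `normalized_p_max_<channel>` columns; per-plate reference values are
#'   in attribute `"references"` (a tibble).
#' @export
normalize_rates <- function(fits, bandwidth_growth = 0.014 / 60,
                            bandwidth_prod = 300) {
  p_cols <- grep("^p_max_", names(fits), value = TRUE)
  refs <- list()
  out <- fits |>
    dplyr::group_split(.data$plate) |>
    purrr::map(function(pf) {
      pf2 <- normalize_plate(pf, "growth_rate", bandwidth_growth)
      ref_row <- tibble::tibble(plate = pf$plate[1],
                                ref_r_max = attr(pf2, "no_burden_value"))
      for (pc in p_cols) {
        pf2 <- normalize_plate(pf2, "production_rate", bandwidth_prod,
                               value_col = pc)
        ref_row[[paste0("ref_", pc)]] <- attr(pf2, "no_burden_value")
      }
      refs[[length(refs) + 1]] <<- ref_row
      pf2
    }) |>
    dplyr::bind_rows()
  attr(out, "references") <- dplyr::bind_rows(refs)
  out
}

#' Plot a plate's rate distribution and no-burden reference
#'
#' Shows the Gaussian KDE of the non-control rate estimates, its local
#' peaks, and the selected no-burden reference value.
#'
#' @inheritParams normalize_plate
#' @return A ggplot.
#' @export
plot_plate_normalization <- function(fits,
                                     metric = c("growth_rate",
                                                "production_rate"),
                                     bandwidth = NULL, value_col = NULL) {
  metric <- match.arg(metric)
  if (is.null(value_col)) {
    value_col <- if (metric == "growth_rate") "r_max" else
      grep("^p_max_", names(fits), value = TRUE)[1]
  }
  if (is.null(bandwidth)) {
    bandwidth <- if (metric == "growth_rate") 0.014 / 60 else 300
  }
  vals <- fits[[value_col]][fits$role == "test"]
  vals <- vals[is.finite(vals)]
  kd <- kde_density(vals, bandwidth)
  ref <- no_burden_reference(vals, bandwidth)
  ggplot2::ggplot(kd, ggplot2::aes(.data$x, .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_rug(data = tibble::tibble(x = vals, density = 0),
                      sides = "b", alpha = 0.5) +
    ggplot2::geom_vline(xintercept = ref, colour = "#b2182b",
                        linetype = "dashed") +
    ggplot2::labs(x = value_col, y = "density",
                  subtitle = paste("no-burden reference =", signif(ref, 4)))
}
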