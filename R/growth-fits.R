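## Single-window exponential fit C(t) = C0 * exp(r * t), t relative to the
## window start. Initialised from a log-linear regression, refined by
## Levenberg-Marquardt NLS on the raw scale.
fit_exp_window <- function(tt, yy, r_upper = 1) {
  ok <- is.finite(yy) & yy > 0
  if (sum(ok) < 3) return(NULL)
  cf <- stats::lm.fit(cbind(1, tt[ok]), log(yy[ok]))$coefficients
  start <- list(C0 = exp(cf[[1]]), r = min(max(cf[[2]], -0.9), r_upper))
  fit <- tryCatch(
    minpack.lm::nlsLM(yy ~ C0 * exp(r * tt),
                      data = data.frame(tt = tt, yy = yy),
                      start = start,
                      lower = c(C0 = 1e-12, r = -1),
                      upper = c(C0 = Inf, r = r_upper),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 60, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  co <- stats::coef(fit)
  res <- yy - co[["C0"]] * exp(co[["r"]] * tt)
  ss_tot <- sum((yy - mean(yy))^2)
  list(C0 = co[["C0"]], r = co[["r"]],
       r2 = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 1)
}

## Fluorescence fit with (C0, r) frozen from the window's OD fit:
## F(t) = F0 + C0 (p / r) (exp(r t) - 1), which is linear in (F0, p).
## In the r -> 0 limit the regressor degenerates to C0 * t.
fit_prod_window <- function(tt, ff, C0, r) {
  ok <- is.finite(ff)
  if (sum(ok) < 2) return(NULL)
  g <- if (abs(r) > 1e-8) C0 / r * expm1(r * tt) else C0 * tt
  cf <- stats::lm.fit(cbind(1, g[ok]), ff[ok])$coefficients
  list(F0 = cf[[1]], p = cf[[2]])
}

#' Fit the maximum specific growth rate of one well
#'
#' Slides a window of `window_pts` consecutive measurements along the
#' background-corrected OD series; for every window whose first point
#' exceeds `od_min`, fits the exponential model `C(t) = C0 * exp(r t)` by
#' nonlinear least squares, and reports the largest fitted rate as the
#' well's maximum specific growth rate. Windows with non-positive fitted
#' rates are skipped for the maximum (their count is reported).
#'
#' @param times Measurement times in minutes (uniformly spaced).
#' @param od Background-corrected OD values, same length as `times`.
#' @param window_pts Number of consecutive points per window (default 9;
#'   at the standard 10-minute sampling this is the assay's standard
#'   fitting window).
#' @param od_min OD that the first point of a window must exceed for the
#'   window to be eligible (default 0.03).
#' @param r_upper Upper bound on the fitted rate, per minute (default 1).
#' @return A one-row tibble: `r_max`, `C0`, `window_index` (index of the
#'   winning window's first point), `window_start` (its time), `r2` of the
#'   winning fit, `status` (`ok`, `no_growth`, or `fit_failed`),
#'   `n_windows` eligible and `n_nonpos` skipped for a non-positive rate.
#' @examples
#' t <- seq(0, 360, 10)
#' fit_max_growth_rate(t, 0.01 * exp(0.02 * t))
#' @export
fit_max_growth_rate <- function(times, od, window_pts = 9, od_min = 0.03,
                                r_upper = 1) {
  stopifnot(window_pts >= 3, length(times) == length(od))
  scan <- scan_windows(times, od, window_pts, od_min, r_upper)
  scan$summary
}

scan_windows <- function(times, od, window_pts, od_min, r_upper) {
  n <- length(times)
  starts <- which(od > od_min)
  starts <- starts[starts <= n - window_pts + 1]
  fits <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    i <- starts[j]
    idx <- i:(i + window_pts - 1)
    f <- fit_exp_window(times[idx] - times[i], od[idx], r_upper)
    if (!is.null(f)) fits[[j]] <- c(index = i, start = times[i],
                                    C0 = f$C0, r = f$r, r2 = f$r2)
  }
  fits <- fits[!vapply(fits, is.null, logical(1))]
  empty <- tibble::tibble(r_max = NA_real_, C0 = NA_real_,
                          window_index = NA_integer_, window_start = NA_real_,
                          r2 = NA_real_, status = NA_character_,
                          n_windows = length(starts), n_nonpos = 0L)
  if (length(starts) == 0) {
    return(list(summary = dplyr::mutate(empty, status = "no_growth"),
                windows = NULL))
  }
  if (length(fits) == 0) {
    return(list(summary = dplyr::mutate(empty, status = "fit_failed"),
                windows = NULL))
  }
  w <- tibble::as_tibble(do.call(rbind, fits))
  pos <- w[w$r > 0, ]
  if (nrow(pos) == 0) {
    return(list(summary = dplyr::mutate(empty, status = "fit_failed",
                                        n_nonpos = nrow(w)),
                windows = w))
  }
  best <- pos[which.max(pos$r), ]
  list(summary = tibble::tibble(
    r_max = best$r, C0 = best$C0,
    window_index = as.integer(best$index), window_start = best$start,
    r2 = best$r2, status = "ok",
    n_windows = length(starts), n_nonpos = nrow(w) - nrow(pos)),
    windows = w)
}

#' Fit the maximum fluorescent-protein production rate of one well
#'
#' For each eligible OD window (same windows as [fit_max_growth_rate()]),
#' fits `F(t) = F0 + C0 (p / r)(exp(r t) - 1)` — the integral of
#' `dF/dt = p C(t)` — with `C0` and `r` frozen to that window's OD fit,
#' and reports the largest fitted production rate `p` across windows.
#'
#' @inheritParams fit_max_growth_rate
#' @param fluor Background-corrected fluorescence values for one channel.
#' @return A one-row tibble: `p_max`, `F0` (fitted initial fluorescence at
#'   the winning window's start), `window_index`, `status`.
#' @export
fit_max_production_rate <- function(times, od, fluor, window_pts = 9,
                                    od_min = 0.03, r_upper = 1) {
  stopifnot(length(times) == length(od), length(times) == length(fluor))
  scan <- scan_windows(times, od, window_pts, od_min, r_upper)
  production_from_scan(times, fluor, scan, window_pts)
}

production_from_scan <- function(times, fluor, scan, window_pts) {
  empty <- tibble::tibble(p_max = NA_real_, F0 = NA_real_,
                          window_index = NA_integer_, status = "no_growth")
  if (is.null(scan$windows)) {
    empty$status <- scan$summary$status
    return(empty)
  }
  w <- scan$windows[scan$windows$r > 0, ]
  if (nrow(w) == 0) return(dplyr::mutate(empty, status = "fit_failed"))
  best_p <- -Inf; best <- NULL
  for (j in seq_len(nrow(w))) {
    i <- w$index[j]
    idx <- i:(i + window_pts - 1)
    pf <- fit_prod_window(times[idx] - times[i], fluor[idx], w$C0[j], w$r[j])
    if (!is.null(pf) && pf$p > best_p) {
      best_p <- pf$p
      best <- tibble::tibble(p_max = pf$p, F0 = pf$F0,
                             window_index = as.integer(i), status = "ok")
    }
  }
  if (is.null(best)) dplyr::mutate(empty, status = "fit_failed") else best
}

#' Fit growth and production rates for every well of a plate
#'
#' Convenience pipeline step: optionally applies [subtract_blanks()] and
#' [align_baselines()], then fits each non-blank well's maximum growth rate
#' on the density channel and its maximum production rate on every
#' fluorescence channel. Wells named in `exclude` (by well or strain id)
#' are dropped explicitly, never silently. Winning fits with
#' `r2 < qc_r2` are flagged in `flag_low_r2` for manual review.
#'
#' @param plate A plate tibble from [read_plate()] / [join_plate()].
#' @param window_pts,od_min,r_upper See [fit_max_growth_rate()].
#' @param od_channel Density channel name; by default `"OD600"` if present,
#'   otherwise `"OD660"` (the alternative used when red fluorophores
#'   interfere with 600 nm absorbance).
#' @param correct If `TRUE` (default), blank-subtract and baseline-align
#'   before fitting.
#' @param exclude Character vector of well or strain ids to drop.
#' @param qc_r2 R-squared threshold below which a winning growth fit is
#'   flagged (default 0.95).
#' @return A fits tibble, one row per well: `plate`, `well`, `strain`,
#'   `role`, `replicate`, `r_max`, `C0`, `window_start`, `r2`, `status`,
#'   `flag_low_r2`, and `p_max_<channel>` / `F0_<channel>` per fluorescence
#'   channel.
#' @examples
#' gen <- generate_plate(synth_config(n_test = 4), seed = 1)
#' plate <- join_plate(gen$run, gen$layout, "P1")
#' fit_plate(plate)
#' @export
fit_plate <- function(plate, window_pts = 9, od_min = 0.03, r_upper = 1,
                      od_channel = NULL, correct = TRUE, exclude = NULL,
                      qc_r2 = 0.95) {
  if (correct) {
    plate <- align_baselines(subtract_blanks(plate))
  }
  channels <- unique(plate$channel)
  if (is.null(od_channel)) {
    od_channel <- if ("OD600" %in% channels) "OD600" else
      if ("OD660" %in% channels) "OD660" else
        stop("no OD600/OD660 channel found; give `od_channel`", call. = FALSE)
  }
  if (!od_channel %in% channels) {
    stop("density channel ", od_channel, " absent from plate", call. = FALSE)
  }
  fl_channels <- setdiff(channels, c("OD600", "OD660"))
  wells <- plate |>
    dplyr::filter(.data$role != "blank",
                  !.data$well %in% exclude, !.data$strain %in% exclude) |>
    dplyr::distinct(.data$plate, .data$well, .data$strain, .data$role,
                    .data$replicate)
  wide <- plate |>
    tidyr::pivot_wider(id_cols = c("plate", "well", "time_min"),
                       names_from = "channel", values_from = "value")
  fits <- purrr::pmap(wells, function(plate, well, strain, role, replicate) {
    dat <- wide[wide$well == well & wide$plate == plate, ]
    dat <- dat[order(dat$time_min), ]
    scan <- scan_windows(dat$time_min, dat[[od_channel]], window_pts,
                         od_min, r_upper)
    row <- scan$summary
    for (ch in fl_channels) {
      pr <- production_from_scan(dat$time_min, dat[[ch]], scan, window_pts)
      row[[paste0("p_max_", ch)]] <- pr$p_max
      row[[paste0("F0_", ch)]] <- pr$F0
    }
    row
  })
  dplyr::bind_cols(wells, dplyr::bind_rows(fits)) |>
    dplyr::mutate(flag_low_r2 = !is.na(.data$r2) & .data$r2 < qc_r2)
}

#' Plot fitted growth curves for selected wells
#'
#' Overlays the corrected OD series with the exponential fit of the winning
#' window for each requested well.
#'
#' @param plate A corrected plate tibble (what the fits were computed on).
#' @param fits The fits tibble from [fit_plate()].
#' @param wells Wells to show (default: the first 6 fitted wells).
#' @param od_channel Density channel name (default `"OD600"`).
#' @return A ggplot.
#' @export
plot_growth_fits <- function(plate, fits, wells = NULL, od_channel = "OD600") {
  fits <- dplyr::filter(fits, .data$status == "ok")
  if (is.null(wells)) wells <- utils::head(fits$well, 6)
  fits <- dplyr::filter(fits, .data$well %in% wells)
  od <- plate |>
    dplyr::filter(.data$channel == od_channel, .data$well %in% wells)
  curves <- fits |>
    dplyr::rowwise() |>
    dplyr::reframe(well = .data$well, time_min = seq(
      .data$window_start, .data$window_start + 80, length.out = 40),
      value = .data$C0 * exp(.data$r_max * (.data$time_min - .data$window_start)))
  ggplot2::ggplot(od, ggplot2::aes(.data$time_min, .data$value)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_line(data = curves, colour = "#b2182b") +
    ggplot2::facet_wrap(~well, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = od_channel)
}
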