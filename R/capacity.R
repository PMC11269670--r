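#' Deming regression through a fixed anchor
#'
#' Fits the linear trade-off between normalized growth rate and normalized
#' gene-expression (GFP) capacity from control strains, acknowledging
#' measurement error on both axes. The line is constrained to pass through
#' the no-burden anchor (normalized production 1, normalized growth 1), so
#' only the slope is estimated: it minimizes the Deming objective
#' `sum((v - m u)^2) / (lambda + m^2)` in anchor-centred coordinates
#' `u = x - x0`, `v = y - y0`, where `lambda` is the ratio of error
#' variances (y over x). The minimizer has a closed form via the second
#' moments about the anchor.
#'
#' @param data Data frame of control points.
#' @param x,y Names of the x (normalized production rate) and y (normalized
#'   growth rate) columns.
#' @param anchor Fixed point the line must pass through (default `c(1, 1)`).
#' @param lambda Error-variance ratio (default 1: orthogonal regression on
#'   the normalized axes).
#' @return An object of class `capacity_line` with elements `slope`,
#'   `anchor`, `lambda`, `n`, `points`, `objective`.
#' @examples
#' pts <- tibble::tibble(gfp = c(0.5, 0.7, 0.9), growth = c(0.55, 0.72, 0.91))
#' fit_anchored_deming(pts, x = "gfp", y = "growth")
#' @export
fit_anchored_deming <- function(data, x = "normalized_p_max_GFP",
                                y = "normalized_r_max",
                                anchor = c(1, 1), lambda = 1) {
  stopifnot(x %in% names(data), y %in% names(data), lambda > 0,
            length(anchor) == 2)
  u <- data[[x]] - anchor[1]
  v <- data[[y]] - anchor[2]
  ok <- is.finite(u) & is.finite(v)
  u <- u[ok]; v <- v[ok]
  if (length(u) < 2) stop("need at least 2 points", call. = FALSE)
  suu <- sum(u^2); svv <- sum(v^2); suv <- sum(u * v)
  if (suu + svv == 0) {
    stop("all points coincide with the anchor; slope undefined", call. = FALSE)
  }
  obj <- function(m) sum((v - m * u)^2) / (lambda + m^2)
  if (suv == 0) {
    slope <- if (svv >= lambda * suu) Inf else 0
    if (!is.finite(slope)) {
      stop("points are vertical about the anchor; slope unbounded",
           call. = FALSE)
    }
  } else {
    disc <- sqrt((svv - lambda * suu)^2 + 4 * lambda * suv^2)
    roots <- ((svv - lambda * suu) + c(-1, 1) * disc) / (2 * suv)
    slope <- roots[which.min(vapply(roots, obj, numeric(1)))]
  }
  structure(list(slope = slope, anchor = anchor, lambda = lambda,
                 n = length(u), objective = obj(slope),
                 points = tibble::tibble(x = u + anchor[1],
                                         y = v + anchor[2])),
            class = "capacity_line")
}

#' @export
print.capacity_line <- function(x, ...) {
  cat("<capacity_line> slope =", signif(x$slope, 5), "through (",
      x$anchor[1], ",", x$anchor[2], "), lambda =", x$lambda,
      ",", x$n, "control points\n")
  invisible(x)
}

#' @rdname fit_anchored_deming
#' @param object,... For the `predict`, `tidy` and `glance` methods.
#' @param newdata Numeric vector of normalized production-rate values at
#'   which to predict the normalized growth rate.
#' @export
predict.capacity_line <- function(object, newdata, ...) {
  object$anchor[2] + object$slope * (newdata - object$anchor[1])
}

#' @rdname fit_anchored_deming
#' @method tidy capacity_line
#' @export
tidy.capacity_line <- function(x, ...) {
  tibble::tibble(term = "slope", estimate = x$slope)
}

#' @rdname fit_anchored_deming
#' @method glance capacity_line
#' @export
glance.capacity_line <- function(x, ...) {
  tibble::tibble(n = x$n, lambda = x$lambda, objective = x$objective,
                 anchor_x = x$anchor[1], anchor_y = x$anchor[2])
}

#' Exclude parts whose products interfere with GFP fluorescence
#'
#' Parts expressing GFP itself, YFP (overlapping emission), or the amilCP
#' blue chromoprotein (absorbs at the monitored emission wavelength) cannot
#' be assessed with the GFP capacity monitor and are excluded. Annotations
#' are tag lists (separated by `;`, `,` or whitespace); parts with missing
#' annotations are conservatively excluded with a warning.
#'
#' @param annotations Data frame with a part identifier column and a
#'   fluorophore-tag column.
#' @param part_col,fluor_col Column names (defaults `"part"`,
#'   `"fluorophores"`).
#' @param exclude_tags Tags triggering exclusion (default GFP, YFP, amilCP).
#' @return A tibble: `part`, `excluded`, `reason` (`NA` when included).
#' @export
interference_filter <- function(annotations, part_col = "part",
                                fluor_col = "fluorophores",
                                exclude_tags = c("GFP", "YFP", "amilCP")) {
  stopifnot(part_col %in% names(annotations),
            fluor_col %in% names(annotations))
  tags <- strsplit(ifelse(is.na(annotations[[fluor_col]]), NA_character_,
                          annotations[[fluor_col]]), "[;,[:space:]]+")
  res <- purrr::map(tags, function(tg) {
    if (length(tg) == 1 && is.na(tg)) {
      return(list(excluded = TRUE, reason = "missing annotation"))
    }
    hit <- intersect(toupper(tg), toupper(exclude_tags))
    if (length(hit)) {
      list(excluded = TRUE,
           reason = paste("interferes with GFP readout:",
                          paste(hit, collapse = ", ")))
    } else list(excluded = FALSE, reason = NA_character_)
  })
  if (any(vapply(res, function(r) identical(r$reason, "missing annotation"),
                 logical(1)))) {
    warning("parts with missing fluorophore annotation were excluded",
            call. = FALSE)
  }
  tibble::tibble(part = annotations[[part_col]],
                 excluded = vapply(res, `[[`, logical(1), "excluded"),
                 reason = vapply(res, `[[`, character(1), "reason"))
}

## Maximum-likelihood location-scale t fit. Small samples (n < 30, i.e.
## every replicate set this assay produces) use a fixed df = n - 1, which
## keeps the derived location test calibrated; larger samples fit df
## freely, floored at 3 so the fitted distribution keeps a finite variance.
fit_t_ml <- function(x, df = NULL, df_floor = 3) {
  n <- length(x)
  if (n < 3) stop("need at least 3 measurements for a t fit", call. = FALSE)
  m0 <- stats::median(x)
  s0 <- max(stats::mad(x), stats::sd(x) / 2, 1e-8)
  nll <- function(m, ls, df) {
    s <- exp(ls)
    -sum(stats::dt((x - m) / s, df, log = TRUE) - ls)
  }
  if (is.null(df) && n >= 30) {
    op <- stats::optim(c(m0, log(s0), log(10)), function(p) {
      nll(p[1], p[2], df_floor + exp(p[3]) - 1)
    }, method = "Nelder-Mead", control = list(maxit = 500))
    list(m = op$par[1], s = exp(op$par[2]),
         df = max(df_floor, df_floor + exp(op$par[3]) - 1))
  } else {
    if (is.null(df)) df <- max(n - 1, 2)
    op <- stats::optim(c(m0, log(s0)), function(p) nll(p[1], p[2], df),
                       method = "Nelder-Mead", control = list(maxit = 500))
    list(m = op$par[1], s = exp(op$par[2]), df = df)
  }
}

rt_ls <- function(n, fit) fit$m + fit$s * stats::rt(n, fit$df)

#' Test a part for burden beyond its gene-expression footprint
#'
#' The capacity line predicts how much growth-rate reduction a part's GFP
#' (gene-expression) footprint accounts for. This test asks whether the
#' part's growth rate is lower than that prediction — burden from sources
#' other than competing for expression resources. Location-scale t
#' distributions are fitted by maximum likelihood to the part's normalized
#' growth-rate and GFP-production measurements; treating the two as
#' independent, Monte Carlo draws from the fitted 2-D distribution give the
#' probability mass on the null-consistent side of the line (growth at or
#' above the line's prediction). That mass is the default one-tailed
#' p-value: about 0.5 for a part sitting on the line, small for a part
#' clearly below it. `halve_above = TRUE` instead reports half the mass on
#' the other-burden side, a compatibility convention.
#'
#' The burden decomposition is `b = 100 (1 - mean growth)`, expression-
#' predicted burden `b_GE = 100 (1 - line(mean GFP))`, other burden
#' `b_O = b - b_GE`; the interval on `b_O / b` is a parametric bootstrap
#' from the fitted t distributions (not truncated, so ratios above 1 are
#' possible when GFP production exceeds the no-burden level).
#'
#' @param growth Normalized growth-rate measurements for the part (>= 3).
#' @param gfp Normalized GFP production-rate measurements (>= 3).
#' @param line A [fit_anchored_deming()] capacity line.
#' @param n_mc Monte Carlo draws for the p-value (default 1e5).
#' @param seed Optional integer seed.
#' @param halve_above Use the halved-mass compatibility convention.
#' @param n_boot Parametric bootstrap replicates for the interval
#'   (default 1000).
#' @param conf Interval coverage (default 0.95).
#' @return A one-row tibble: `n`, `b`, `b_ge`, `b_o`, `frac_other`,
#'   `frac_lo`, `frac_hi`, `p`.
#' @export
other_burden_test <- function(growth, gfp, line, n_mc = 1e5, seed = NULL,
                              halve_above = FALSE, n_boot = 1000,
                              conf = 0.95) {
  if (length(growth) < 3 || length(gfp) < 3) {
    stop("need at least 3 measurements on each axis for the ML t fit",
         call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  tg <- fit_t_ml(growth)
  tf <- fit_t_ml(gfp)
  # The p-value concerns the part's location, so the 2-D distribution is
  # the sampling distribution of the mean: the fitted t rescaled to a
  # standard error (with the ML small-sample scale correction) and n - 1
  # degrees of freedom, which reduces to an exact t-test for Gaussian data.
  ng <- length(growth); nf <- length(gfp)
  se_g <- list(m = tg$m, s = tg$s * sqrt(ng / (ng - 1)) / sqrt(ng),
               df = ng - 1)
  se_f <- list(m = tf$m, s = tf$s * sqrt(nf / (nf - 1)) / sqrt(nf),
               df = nf - 1)
  xs <- rt_ls(n_mc, se_f)
  ys <- rt_ls(n_mc, se_g)
  null_mass <- mean(ys >= predict(line, xs))
  p <- if (halve_above) (1 - null_mass) / 2 else null_mass
  b <- 100 * (1 - mean(growth))
  b_ge <- 100 * (1 - predict(line, mean(gfp)))
  b_o <- b - b_ge
  frac <- vapply(seq_len(n_boot), function(k) {
    gb <- mean(rt_ls(ng, tg))
    fb <- mean(rt_ls(nf, tf))
    bb <- 100 * (1 - gb)
    (bb - 100 * (1 - predict(line, fb))) / bb
  }, numeric(1))
  qs <- stats::quantile(frac, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE, na.rm = TRUE)
  tibble::tibble(n = ng, b = b, b_ge = b_ge, b_o = b_o,
                 frac_other = b_o / b, frac_lo = qs[1], frac_hi = qs[2],
                 p = p)
}

#' Classify burden into expression and other sources across a cohort
#'
#' Applies the eligibility rules — burden significantly greater than zero
#' after FDR correction, mean burden above `min_burden` percent, and no
#' fluorescence interference — then runs [other_burden_test()] on each
#' eligible part and Benjamini-Hochberg-adjusts the resulting p-values
#' across the eligible set.
#'
#' @param normalized Measurement-level tibble with part, normalized growth
#'   and normalized GFP production columns.
#' @param burden Part-level burden tibble from [burden_summary()].
#' @param annotations Fluorophore annotations (see [interference_filter()]).
#' @param line A [fit_anchored_deming()] capacity line.
#' @param fdr FDR for the other-burden decision (default 0.05).
#' @param min_burden Minimum mean burden (percent) for eligibility
#'   (default 10).
#' @param part_col,rate_col,gfp_col Column names in `normalized`.
#' @inheritParams other_burden_test
#' @return A tibble with one row per eligible part: the
#'   [other_burden_test()] columns plus `part`, `p_bh`, and
#'   `other_burden_significant`. Excluded/ineligible parts are recorded in
#'   attribute `"excluded"`.
#' @export
classify_burden_sources <- function(normalized, burden, annotations, line,
                                    fdr = 0.05, min_burden = 10,
                                    part_col = "strain",
                                    rate_col = "normalized_r_max",
                                    gfp_col = "normalized_p_max_GFP",
                                    n_mc = 1e5, seed = NULL,
                                    halve_above = FALSE, n_boot = 1000) {
  filt <- interference_filter(annotations)
  status <- burden |>
    dplyr::left_join(filt, by = "part") |>
    dplyr::mutate(
      excluded = dplyr::coalesce(.data$excluded, TRUE),
      reason = dplyr::case_when(
        .data$excluded ~ dplyr::coalesce(.data$reason, "missing annotation"),
        !.data$significant ~ "burden not significant",
        .data$burden_pct <= min_burden ~ "mean burden below threshold",
        TRUE ~ NA_character_))
  eligible <- dplyr::filter(status, is.na(.data$reason))
  dropped <- dplyr::filter(status, !is.na(.data$reason)) |>
    dplyr::select("part", "reason")
  if (nrow(eligible) == 0) {
    out <- tibble::tibble(part = character())
    attr(out, "excluded") <- dropped
    message("no parts eligible for the other-burden test")
    return(out)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  part_seeds <- sample.int(2^31 - 1, nrow(eligible))
  rows <- purrr::map2(eligible$part, part_seeds, function(pt, sd) {
    meas <- normalized[normalized[[part_col]] == pt, ]
    other_burden_test(meas[[rate_col]], meas[[gfp_col]], line,
                      n_mc = n_mc, seed = sd, halve_above = halve_above,
                      n_boot = n_boot)
  })
  out <- dplyr::bind_cols(tibble::tibble(part = eligible$part),
                          dplyr::bind_rows(rows))
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out$other_burden_significant <- out$p_bh < fdr
  attr(out, "excluded") <- dropped
  out
}

#' Plot parts against the capacity line
#'
#' Scatter of per-part mean normalized GFP production against mean
#' normalized growth rate, with the anchored Deming line; parts with
#' significant other burden are highlighted if a classification table is
#' supplied.
#'
#' @param normalized Measurement-level tibble (see
#'   [classify_burden_sources()]).
#' @param line A `capacity_line`.
#' @param classified Optional output of [classify_burden_sources()].
#' @inheritParams classify_burden_sources
#' @return A ggplot.
#' @export
plot_capacity <- function(normalized, line, classified = NULL,
                          part_col = "strain",
                          rate_col = "normalized_r_max",
                          gfp_col = "normalized_p_max_GFP") {
  means <- normalized |>
    dplyr::group_by(part = .data[[part_col]]) |>
    dplyr::summarise(gfp = mean(.data[[gfp_col]], na.rm = TRUE),
                     growth = mean(.data[[rate_col]], na.rm = TRUE),
                     .groups = "drop")
  if (!is.null(classified) && nrow(classified)) {
    means <- dplyr::left_join(
      means, dplyr::select(classified, "part",
                           other = "other_burden_significant"),
      by = "part")
  } else {
    means$other <- NA
  }
  rng <- range(c(means$gfp, line$anchor[1]))
  seg <- tibble::tibble(gfp = rng, growth = predict(line, rng))
  ggplot2::ggplot(means, ggplot2::aes(.data$gfp, .data$growth)) +
    ggplot2::geom_line(data = seg, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$other)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "#2166ac"),
                                 na.value = "grey60") +
    ggplot2::labs(x = "normalized GFP production rate",
                  y = "normalized growth rate",
                  colour = "other burden")
}
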