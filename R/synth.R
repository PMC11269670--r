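#' Configuration for the synthetic plate generator
#'
#' Defaults emulate the standard burden-assay design: a 96-well plate with
#' 23 test strains and 5 control strains in triplicate plus 12 media
#' blanks, OD600 and GFP read every 10 minutes for 6 hours. Growth curves
#' have an exactly exponential early phase that relaxes smoothly into
#' saturation at the carrying OD (the fitting procedure only ever uses the
#' exponential windows; the saturating family is a free modelling choice),
#' fluorescence accumulates as the integral of `p * C(t)`, each well
#' carries an additive baseline offset, and each plate a multiplicative
#' rate effect.
#'
#' Test-strain burdens are drawn from a mixture — a point mass at zero, a
#' low-burden shoulder below 10%, and a piecewise-uniform tail — with
#' nothing above 45%, the constructability bound above which the failure
#' model predicts takeover before a culture can even be grown. The default
#' weights reproduce the composition of the large common-garden survey
#' this assay design comes from: roughly 60% of parts without measurable
#' burden, about 11% above 10%, 6% above 20%, 2% above 30%. Control
#' burdens are five fixed levels, mirroring a graded series of
#' expression-burden control plasmids.
#'
#' @param n_test,n_controls,n_reps,n_blanks Plate design (defaults 23, 5,
#'   3, 12; must fit a 96-well plate).
#' @param interval_min,duration_min Sampling interval and run length in
#'   minutes (defaults 10 and 360).
#' @param r0 True no-burden maximum specific growth rate, per minute
#'   (default 0.021, a ~33-minute doubling time).
#' @param C0,K Initial and carrying OD of the logistic growth curve
#'   (defaults 0.005 and 1.0).
#' @param p0 True no-burden GFP production rate, fluorescence units per OD
#'   per minute (default 3000; arbitrary instrument scale).
#' @param burden_mix Mixture weights and shapes for test-strain burdens:
#'   `w0` (no burden), `w_shoulder`/`shoulder_mean`/`shoulder_sd`
#'   (half-normal shoulder, truncated below `tail_breaks[1]`), and
#'   `tail_weights` over the piecewise-uniform intervals delimited by
#'   `tail_breaks`; all weights must sum to 1.
#' @param control_burdens True burdens of the five control strains.
#' @param line_slope True slope of the growth-vs-expression capacity line
#'   on normalized axes (default 1: pure expression burden lies on the
#'   identity line through the no-burden anchor).
#' @param od_noise_sd,fluor_noise_sd Additive Gaussian measurement noise
#'   (defaults 0.003 OD, 30 fluorescence units).
#' @param baseline_od,baseline_fluor Mean media background levels.
#' @param baseline_offset_sd,baseline_offset_fluor_sd Per-well additive
#'   baseline offsets (sd; defaults 0.01 OD, 10 units).
#' @param plate_effect_range Range of the per-plate multiplicative rate
#'   effect (default `c(0.85, 1.15)`).
#' @param takeover_mu Failure mutation rate per division used for
#'   mutant-takeover wells (0, the default, disables takeover).
#' @param takeover_pre_doublings Doublings of seeded stochastic preculture
#'   growth before the well is observed (default 23: the expansion of a
#'   single founding cell into a colony; deeper histories drive burdensome
#'   strains to complete takeover before the well is ever read).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_test = 23, n_controls = 5, n_reps = 3,
                         n_blanks = 12, interval_min = 10,
                         duration_min = 360, r0 = 0.021, C0 = 0.005, K = 1,
                         p0 = 3000,
                         burden_mix = list(w0 = 0.60, w_shoulder = 0.287,
                                           shoulder_mean = 0.04,
                                           shoulder_sd = 0.03,
                                           tail_breaks = c(0.10, 0.20,
                                                           0.30, 0.45),
                                           tail_weights = c(0.050, 0.043,
                                                            0.020)),
                         control_burdens = c(0.05, 0.10, 0.15, 0.22, 0.30),
                         line_slope = 1, od_noise_sd = 0.003,
                         fluor_noise_sd = 30, baseline_od = 0.04,
                         baseline_fluor = 100, baseline_offset_sd = 0.01,
                         baseline_offset_fluor_sd = 10,
                         plate_effect_range = c(0.85, 1.15),
                         takeover_mu = 0, takeover_pre_doublings = 23) {
  n_wells <- (n_test + n_controls) * n_reps + n_blanks
  if (n_wells > 96) {
    stop("configuration needs ", n_wells, " wells; a plate has 96",
         call. = FALSE)
  }
  stopifnot(r0 > 0, C0 > 0, K > C0, p0 > 0, interval_min > 0,
            duration_min >= 360 || duration_min >= 6 * interval_min)
  w <- c(burden_mix$w0, burden_mix$w_shoulder, burden_mix$tail_weights)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-8) {
    stop("burden mixture weights must be non-negative and sum to 1",
         call. = FALSE)
  }
  if (length(burden_mix$tail_breaks) != length(burden_mix$tail_weights) + 1) {
    stop("`tail_breaks` must have one more element than `tail_weights`",
         call. = FALSE)
  }
  if (length(control_burdens) != n_controls) {
    stop("`control_burdens` must have length n_controls", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_config")
}

draw_burdens <- function(n, mix) {
  n_tail <- length(mix$tail_weights)
  comp <- sample.int(2 + n_tail, n, replace = TRUE,
                     prob = c(mix$w0, mix$w_shoulder, mix$tail_weights))
  b <- numeric(n)
  sh <- comp == 2
  b[sh] <- pmin(abs(stats::rnorm(sum(sh), mix$shoulder_mean,
                                 mix$shoulder_sd)),
                mix$tail_breaks[1] - 1e-6)
  for (k in seq_len(n_tail)) {
    tl <- comp == 2 + k
    b[tl] <- stats::runif(sum(tl), mix$tail_breaks[k],
                          mix$tail_breaks[k + 1])
  }
  b
}

## Saturating transform applied to the ideal (unbounded) cell density: the
## curve is exactly exponential below `sat_frac * K` and relaxes smoothly
## (continuous value and slope) to the carrying capacity K above it, so the
## exponential-phase windows the fitting procedure uses really are
## exponential.
saturate_od <- function(density, K, sat_frac = 0.3) {
  xc <- sat_frac * K
  ifelse(density <= xc, density,
         K - (K - xc) * exp(-(density - xc) / (K - xc)))
}

## One well's noiseless OD core and cumulative GFP signal on a time grid.
## Fluorescence accumulates as the integral of p * C(t), evaluated by
## trapezoidal integration on a 1-minute internal grid; with takeover the
## engineered/failed mixture from a seeded stochastic run drives both.
well_core <- function(times, b, b_other, plate_effect, cfg, takeover = FALSE,
                      mu = 0, seed = NULL) {
  r_fail <- cfg$r0 * plate_effect          # failed (no-burden) rate, per min
  r_eng <- r_fail * (1 - b)
  b_ge <- b - b_other
  p_eng <- cfg$p0 * plate_effect * (1 - b_ge / cfg$line_slope)
  fine <- seq(0, max(times), by = 1)
  if (!takeover || mu <= 0 || b <= 0) {
    od_f <- saturate_od(cfg$C0 * exp(r_eng * fine), cfg$K)
    integrand <- p_eng * od_f
    gfp_f <- c(0, cumsum((integrand[-1] + integrand[-length(integrand)]) / 2 *
                           diff(fine)))
    idx <- match(times, fine)
    return(list(od = od_f[idx], gfp = gfp_f[idx],
                mutant_fraction = rep(0, length(times))))
  }
  d_well <- log2(cfg$K / cfg$C0) + 4
  traj <- simulate_stochastic(failure_params(b, mu),
                              d_max = cfg$takeover_pre_doublings + d_well,
                              seed = seed, method = "hybrid")
  tau <- traj$time
  d <- traj$doublings
  tau0 <- stats::approx(d, tau, xout = cfg$takeover_pre_doublings,
                        ties = "ordered")$y
  tau_f <- pmin(tau0 + r_fail * fine, max(tau))
  log_tot <- stats::approx(tau, log(traj$E + traj$F), xout = tau_f,
                           rule = 2, ties = "ordered")$y
  frac <- stats::approx(tau, traj$failed_fraction, xout = tau_f,
                        rule = 2, ties = "ordered")$y
  fg <- exp(log_tot - log_tot[1])
  od_f <- saturate_od(cfg$C0 * fg, cfg$K)
  p_mix <- p_eng * (1 - frac) + cfg$p0 * plate_effect * frac
  integrand <- p_mix * od_f
  gfp_f <- c(0, cumsum((integrand[-1] + integrand[-length(integrand)]) / 2 *
                         diff(fine)))
  idx <- match(times, fine)
  list(od = od_f[idx], gfp = gfp_f[idx], mutant_fraction = frac[idx])
}

plate_well_ids <- function() {
  paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
}

#' Generate one synthetic burden-assay plate
#'
#' Emulates a 96-well plate run with known ground truth: per-strain true
#' burdens (drawn from the configured mixture or supplied), a per-plate
#' multiplicative rate effect, per-well baseline offsets, additive Gaussian
#' measurement noise, and — when `config$takeover_mu > 0` — wells whose
#' apparent growth rate drifts upward as burden-free mutants take over,
#' driven by the stochastic failure model.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @param plate_id Plate identifier (default `"P1"`).
#' @param burdens Optional vector of true test-strain burdens (length
#'   `n_test`); drawn from the mixture when `NULL`.
#' @param b_other Optional vector of true other-burden components (extra
#'   growth-rate reduction at unchanged GFP footprint), recycled to
#'   `n_test`; default 0.
#' @param part_names Optional test strain names (default
#'   `part_01...`).
#' @return A list with `run` (long tibble: `well`, `time_min`, `channel`,
#'   `value`), `layout` (`well`, `strain`, `role`, `replicate`), and
#'   `truth` (per strain: true burden, other burden, realized rates, plate
#'   effect, takeover flag; per-well mean mutant fraction for takeover
#'   wells).
#' @examples
#' gen <- generate_plate(synth_config(n_test = 4), seed = 42)
#' head(gen$truth)
#' @export
generate_plate <- function(config = synth_config(), seed = NULL,
                           plate_id = "P1", burdens = NULL, b_other = NULL,
                           part_names = NULL) {
  cfg <- config
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(part_names)) {
    part_names <- sprintf("part_%02d", seq_len(cfg$n_test))
  }
  stopifnot(length(part_names) == cfg$n_test)
  if (is.null(burdens)) burdens <- draw_burdens(cfg$n_test, cfg$burden_mix)
  stopifnot(length(burdens) == cfg$n_test)
  if (is.null(b_other)) b_other <- 0
  b_other <- rep_len(b_other, cfg$n_test)
  controls <- sprintf("BFP%d", seq_len(cfg$n_controls))
  plate_effect <- stats::runif(1, cfg$plate_effect_range[1],
                               cfg$plate_effect_range[2])
  times <- seq(0, cfg$duration_min, by = cfg$interval_min)

  strains <- tibble::tibble(
    strain = c(part_names, controls),
    role = rep(c("test", "control"), c(cfg$n_test, cfg$n_controls)),
    burden = c(burdens, cfg$control_burdens),
    b_other = c(b_other, rep(0, cfg$n_controls)))
  wells <- tidyr::expand_grid(strains, replicate = seq_len(cfg$n_reps))
  n_used <- nrow(wells) + cfg$n_blanks
  ids <- plate_well_ids()[seq_len(n_used)]
  blank_ids <- utils::tail(ids, cfg$n_blanks)
  wells$well <- utils::head(ids, nrow(wells))

  takeover_on <- cfg$takeover_mu > 0
  well_rows <- purrr::pmap(wells, function(strain, role, burden, b_other,
                                           replicate, well) {
    offs_od <- stats::rnorm(1, 0, cfg$baseline_offset_sd)
    offs_fl <- stats::rnorm(1, 0, cfg$baseline_offset_fluor_sd)
    core <- well_core(times, burden, b_other, plate_effect, cfg,
                      takeover = takeover_on && role == "test",
                      mu = cfg$takeover_mu,
                      seed = sample.int(2^31 - 1, 1))
    od <- cfg$baseline_od + offs_od + core$od +
      stats::rnorm(length(times), 0, cfg$od_noise_sd)
    gfp <- cfg$baseline_fluor + offs_fl + core$gfp +
      stats::rnorm(length(times), 0, cfg$fluor_noise_sd)
    list(run = tibble::tibble(
      well = well,
      time_min = rep(times, 2),
      channel = rep(c("OD600", "GFP"), each = length(times)),
      value = c(od, gfp)),
      mutant_fraction = mean(core$mutant_fraction))
  })
  blank_rows <- purrr::map(blank_ids, function(w) {
    offs_od <- stats::rnorm(1, 0, cfg$baseline_offset_sd)
    offs_fl <- stats::rnorm(1, 0, cfg$baseline_offset_fluor_sd)
    tibble::tibble(
      well = w,
      time_min = rep(times, 2),
      channel = rep(c("OD600", "GFP"), each = length(times)),
      value = c(cfg$baseline_od + offs_od +
                  stats::rnorm(length(times), 0, cfg$od_noise_sd),
                cfg$baseline_fluor + offs_fl +
                  stats::rnorm(length(times), 0, cfg$fluor_noise_sd)))
  })
  run <- dplyr::bind_rows(c(purrr::map(well_rows, "run"), blank_rows))
  layout <- dplyr::bind_rows(
    dplyr::select(wells, "well", "strain", "role", "replicate"),
    tibble::tibble(well = blank_ids, strain = NA_character_, role = "blank",
                   replicate = seq_len(cfg$n_blanks)))
  truth <- wells |>
    dplyr::mutate(
      plate = plate_id,
      plate_effect = plate_effect,
      r_true = cfg$r0 * (1 - .data$burden) * plate_effect,
      p_true = cfg$p0 * plate_effect *
        (1 - (.data$burden - .data$b_other) / cfg$line_slope),
      takeover = takeover_on & .data$role == "test" & .data$burden > 0,
      mutant_fraction = purrr::map_dbl(well_rows, "mutant_fraction")) |>
    dplyr::select("plate", "well", "strain", "role", "replicate", "burden",
                  "b_other", "r_true", "p_true", "plate_effect", "takeover",
                  "mutant_fraction")
  list(run = run, layout = layout, truth = truth)
}

#' Generate a single well undergoing mutant takeover
#'
#' Runs the stochastic failure model through a seeded preculture of
#' `config$takeover_pre_doublings` doublings and converts the resulting
#' engineered/failed mixture into an observed OD and GFP series: the
#' apparent growth rate drifts from `(1 - b) r0` toward `r0` as burden-free
#' mutants take over, and replicate wells (independent seeds) vary with the
#' timing of the first mutants.
#'
#' @param b,mu Burden and failure mutation rate of the strain.
#' @param config A [synth_config()].
#' @param seed Integer seed for this well.
#' @param plate_effect Multiplicative rate effect (default 1).
#' @return A list with `series` (tibble `time_min`, `OD600`, `GFP`,
#'   noise-free `mutant_fraction`) and `truth` (one row: the inputs and the
#'   final mutant fraction).
#' @export
generate_takeover_well <- function(b, mu, config = synth_config(),
                                   seed = NULL, plate_effect = 1) {
  cfg <- config
  params <- failure_params(b, mu)  # validates
  times <- seq(0, cfg$duration_min, by = cfg$interval_min)
  if (!is.null(seed)) set.seed(as.integer(seed))
  core <- well_core(times, b, 0, plate_effect, cfg,
                    takeover = mu > 0 && b > 0, mu = mu,
                    seed = if (is.null(seed)) NULL else
                      sample.int(2^31 - 1, 1))
  od <- cfg$baseline_od + core$od +
    stats::rnorm(length(times), 0, cfg$od_noise_sd)
  gfp <- cfg$baseline_fluor + core$gfp +
    stats::rnorm(length(times), 0, cfg$fluor_noise_sd)
  list(series = tibble::tibble(time_min = times, OD600 = od, GFP = gfp,
                               mutant_fraction = core$mutant_fraction),
       truth = tibble::tibble(b = b, mu = mu, plate_effect = plate_effect,
                              r_true = cfg$r0 * (1 - b) * plate_effect,
                              final_mutant_fraction =
                                core$mutant_fraction[length(times)]))
}

#' Generate a multi-plate synthetic cohort
#'
#' Assigns `n_parts` test parts to plates (`config$n_test` per plate, the
#' last plate padded with blanks), draws true burdens per part, optionally
#' injects other-burden components, and generates every plate with its own
#' plate effect. Supports the null and power simulations used to validate
#' the burden and capacity statistics.
#'
#' @inheritParams generate_plate
#' @param n_parts Number of test parts in the cohort.
#' @param burdens Optional true burdens, recycled to `n_parts`.
#' @param b_other Optional other-burden components, recycled to `n_parts`.
#' @param plates_per_part Number of plates each group of parts is assayed
#'   on (default 1); with triplicate wells, `plates_per_part = 3` gives 9
#'   measurements per part.
#' @return A list with `run`, `layout`, `truth`, all carrying a `plate`
#'   column.
#' @export
generate_cohort <- function(config = synth_config(), n_parts, seed = NULL,
                            burdens = NULL, b_other = NULL,
                            plates_per_part = 1) {
  cfg <- config
  stopifnot(n_parts >= 1, plates_per_part >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(burdens)) burdens <- draw_burdens(n_parts, cfg$burden_mix)
  burdens <- rep_len(burdens, n_parts)
  if (is.null(b_other)) b_other <- 0
  b_other <- rep_len(b_other, n_parts)
  part_names <- sprintf("part_%03d", seq_len(n_parts))
  n_groups <- ceiling(n_parts / cfg$n_test)
  spec <- tidyr::expand_grid(group = seq_len(n_groups),
                             rep_plate = seq_len(plates_per_part))
  plates <- purrr::pmap(spec, function(group, rep_plate) {
    idx <- ((group - 1) * cfg$n_test + 1):min(group * cfg$n_test, n_parts)
    pcfg <- cfg
    n_here <- length(idx)
    if (n_here < cfg$n_test) {  # pad the last plate group with extra blanks
      pcfg$n_test <- n_here
      pcfg$n_blanks <- cfg$n_blanks + (cfg$n_test - n_here) * cfg$n_reps
    }
    pid <- if (plates_per_part == 1) sprintf("P%02d", group) else
      sprintf("P%02d%s", group, letters[rep_plate])
    gen <- generate_plate(pcfg, seed = sample.int(2^31 - 1, 1),
                          plate_id = pid,
                          burdens = burdens[idx], b_other = b_other[idx],
                          part_names = part_names[idx])
    gen$run$plate <- pid
    gen$layout$plate <- pid
    gen
  })
  list(run = dplyr::bind_rows(purrr::map(plates, "run")),
       layout = dplyr::bind_rows(purrr::map(plates, "layout")),
       truth = dplyr::bind_rows(purrr::map(plates, "truth")))
}

#' Generate normalized measurements directly (for statistical validation)
#'
#' Skips the plate level entirely and draws normalized growth-rate and GFP
#' production-rate measurements for a cohort of parts with known burden and
#' other-burden truth: growth centred at `1 - burden`, GFP at
#' `1 - (burden - b_other) / slope`, with independent Gaussian measurement
#' noise. This is the cheap route for null-calibration and power studies of
#' the burden and other-burden tests.
#'
#' @param n_parts Number of parts.
#' @param n_rep Measurements per part.
#' @param burden True burden fraction(s), recycled to `n_parts`.
#' @param b_other True other-burden fraction(s), recycled (default 0).
#' @param sd_growth,sd_gfp Measurement noise on the normalized axes
#'   (defaults 0.02).
#' @param slope True capacity-line slope (default 1).
#' @param seed Integer seed.
#' @return A measurement-level tibble (`strain`, `replicate`,
#'   `normalized_r_max`, `normalized_p_max_GFP`) with the per-part truth in
#'   attribute `"truth"`.
#' @export
generate_normalized_measurements <- function(n_parts, n_rep, burden,
                                             b_other = 0, sd_growth = 0.02,
                                             sd_gfp = 0.02, slope = 1,
                                             seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  burden <- rep_len(burden, n_parts)
  b_other <- rep_len(b_other, n_parts)
  parts <- sprintf("part_%03d", seq_len(n_parts))
  truth <- tibble::tibble(strain = parts, burden = burden, b_other = b_other)
  out <- tidyr::expand_grid(strain = parts, replicate = seq_len(n_rep)) |>
    dplyr::left_join(truth, by = "strain") |>
    dplyr::mutate(
      normalized_r_max = 1 - .data$burden +
        stats::rnorm(dplyr::n(), 0, sd_growth),
      normalized_p_max_GFP = 1 - (.data$burden - .data$b_other) / slope +
        stats::rnorm(dplyr::n(), 0, sd_gfp)) |>
    dplyr::select("strain", "replicate", "normalized_r_max",
                  "normalized_p_max_GFP")
  attr(out, "truth") <- truth
  out
}

#' Write a generated dataset to CSV files
#'
#' @param dataset Output of [generate_plate()] or [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`run.csv`, `layout.csv`,
#'   `truth.csv`).
#' @export
write_synth <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("run.csv", "layout.csv", "truth.csv"))
  readr::write_csv(dataset$run, paths[1])
  readr::write_csv(dataset$layout, paths[2])
  readr::write_csv(dataset$truth, paths[3])
  invisible(paths)
}

#' Fit every plate of a multi-plate run table
#'
#' Splits a cohort-level run/layout pair by its `plate` column, assembles
#' and fits each plate with [fit_plate()], and binds the fits.
#'
#' @param run,layout Cohort tables with a `plate` column (see
#'   [generate_cohort()]).
#' @param ... Passed to [fit_plate()].
#' @return A fits tibble covering all plates.
#' @export
fit_cohort <- function(run, layout, ...) {
  stopifnot("plate" %in% names(run), "plate" %in% names(layout))
  plates <- unique(run$plate)
  purrr::map(plates, function(p) {
    pl <- join_plate(run[run$plate == p, names(run) != "plate"],
                     layout[layout$plate == p, names(layout) != "plate"],
                     plate_id = p)
    fit_plate(pl, ...)
  }) |>
    dplyr::bind_rows()
}
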