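#' Parameters of the two-type evolutionary failure model
#'
#' The model tracks a population of engineered cells `E` carrying a
#' burdensome DNA construct and failed (mutant) cells `F` whose construct is
#' broken and burden-free. Failed cells grow at relative rate 1; engineered
#' cells at `1 - b`. Each division of an engineered cell produces a failed
#' daughter with probability `mu`. Time is measured in e-folding units of
#' failed-cell growth.
#'
#' @param b Burden: fractional reduction in the engineered cells' growth
#'   rate, in `[0, 1)`.
#' @param mu Failure mutation rate per cell division, in `[0, 1)`.
#' @param E0 Initial engineered cell count (default 1).
#' @param F0 Initial failed cell count (default 0).
#' @return An object of class `failure_params`.
#' @examples
#' failure_params(b = 0.3, mu = 1e-6)
#' @export
failure_params <- function(b, mu, E0 = 1, F0 = 0) {
  stopifnot(is.numeric(b), length(b) == 1, is.numeric(mu), length(mu) == 1,
            is.numeric(E0), length(E0) == 1, is.numeric(F0), length(F0) == 1)
  if (is.na(b) || b < 0 || b >= 1) {
    stop("`b` must satisfy 0 <= b < 1, got ", b, call. = FALSE)
  }
  if (is.na(mu) || mu < 0 || mu >= 1) {
    stop("`mu` must satisfy 0 <= mu < 1, got ", mu, call. = FALSE)
  }
  if (E0 < 0 || F0 < 0 || E0 + F0 <= 0) {
    stop("initial counts must be non-negative with E0 + F0 > 0", call. = FALSE)
  }
  structure(list(b = b, mu = mu, E0 = E0, F0 = F0), class = "failure_params")
}

#' @export
print.failure_params <- function(x, ...) {
  cat("<failure_params> b =", x$b, " mu =", format(x$mu), " E0 =", x$E0,
      " F0 =", x$F0, "\n")
  invisible(x)
}

as_failure_params <- function(params) {
  if (inherits(params, "failure_params")) return(params)
  do.call(failure_params, as.list(params))
}

new_burden_traj <- function(times, E, F, params, provenance, seed = NULL) {
  total0 <- params$E0 + params$F0
  tot <- E + F
  if (any(tot <= 0)) stop("total population reached zero", call. = FALSE)
  out <- tibble::tibble(
    time = times,
    E = E,
    F = F,
    doublings = log2(tot / total0),
    failed_fraction = F / tot
  )
  structure(out,
            class = c("burden_traj", class(out)),
            params = params, provenance = provenance, seed = seed)
}

#' Deterministic solution of the failure model
#'
#' Integrates the linear ODE system
#' `dE/dt = (1 - b)(1 - mu) E`,
#' `dF/dt = F + mu (1 - b) E`
#' until the population has undergone `d_max` doublings (measured relative
#' to the founding population), storing the trajectory on a fixed grid of
#' doubling increments so that deterministic and stochastic runs are
#' directly comparable.
#'
#' @param params A [failure_params()] object.
#' @param d_max Number of population doublings to simulate to (> 0).
#' @param step Doubling increment at which the trajectory is stored
#'   (default 0.25).
#' @return A `burden_traj` tibble with columns `time`, `E`, `F`,
#'   `doublings`, `failed_fraction`.
#' @examples
#' traj <- solve_deterministic(failure_params(0.3, 1e-6), d_max = 30)
#' time_to_half_failure(traj)
#' @export
solve_deterministic <- function(params, d_max, step = 0.25) {
  params <- as_failure_params(params)
  if (!is.numeric(d_max) || length(d_max) != 1 || is.na(d_max) || d_max <= 0) {
    stop("`d_max` must be a positive number", call. = FALSE)
  }
  b <- params$b; mu <- params$mu
  # Upper bound on the end time: the slowest subpopulation grows at rate
  # (1 - b)(1 - mu) > 0, the fastest at 1.
  a <- (1 - b) * (1 - mu)
  t_end <- d_max * log(2) / a + 1e-9
  d_grid <- seq(0, d_max, by = step)
  if (d_grid[length(d_grid)] < d_max) d_grid <- c(d_grid, d_max)
  # Integrate in well-conditioned coordinates: log E is linear in t, and
  # G = F e^{-t} stays bounded, so the solver's relative tolerance applies
  # directly to quantities spanning no dynamic range.
  solve_at <- function(times) {
    if (params$E0 == 0) {
      return(list(E = rep(0, length(times)), F = params$F0 * exp(times)))
    }
    rhs <- function(t, y, parms) {
      list(c(a, mu * (1 - b) * exp(y[[1]] - t)))
    }
    # absolute tolerance tied to G's natural scale so tiny mutant inflows
    # (mu ~ 1e-8) are still resolved to ~1e-12 relative accuracy
    g_scale <- max(mu * (1 - b) * params$E0, params$F0, 1e-300)
    sol <- deSolve::lsoda(c(logE = log(params$E0), G = params$F0), times,
                          rhs, parms = NULL, rtol = 1e-12,
                          atol = c(1e-12, g_scale * 1e-12))
    list(E = exp(sol[, "logE"]), F = sol[, "G"] * exp(sol[, "time"]))
  }
  # Dense solve, then invert D(t) (strictly increasing) onto the grid.
  dense_t <- seq(0, t_end, length.out = max(500L, 20L * length(d_grid)))
  dense <- solve_at(dense_t)
  D <- log2((dense$E + dense$F) / (params$E0 + params$F0))
  keep_to <- which(D >= d_max)[1]
  if (is.na(keep_to)) keep_to <- length(D)
  t_at <- stats::approx(D[seq_len(keep_to)], dense_t[seq_len(keep_to)],
                        xout = pmin(pmax(d_grid, D[1]), D[keep_to]),
                        ties = "ordered")$y
  t_at[1] <- 0
  t_at <- unique(t_at)
  sol2 <- solve_at(t_at)
  new_burden_traj(t_at, sol2$E, sol2$F, params,
                  provenance = "deterministic")
}

## Poisson draw that stays stable at the huge counts reached late in a
## culture (populations up to ~2^60 are represented as doubles).
rpois_big <- function(lambda) {
  if (lambda <= 0) return(0)
  if (lambda < 1e9) return(stats::rpois(1L, lambda))
  max(0, round(stats::rnorm(1L, lambda, sqrt(lambda))))
}

rbinom_big <- function(n, p) {
  if (n <= 0 || p <= 0) return(0)
  if (n < 2^31 - 1) return(stats::rbinom(1L, as.integer(n), p))
  rpois_big(n * p)  # p << 1 in every use here
}

## Number of births over one leap of a linear (Yule) birth process with
## `size` founders and survival probability `prob` = exp(-rate * tau):
## exactly negative binomial, approximated by a matched normal when the
## counts overflow integer range.
rnb_big <- function(size, prob) {
  if (size <= 0) return(0)
  mean_b <- size * (1 - prob) / prob
  if (size < 2^31 - 1 && mean_b < 1e9) {
    return(stats::rnbinom(1L, size = size, prob = prob))
  }
  max(0, round(stats::rnorm(1L, mean_b, sqrt(size * (1 - prob) / prob^2))))
}

#' Stochastic simulation of the failure model
#'
#' Simulates the birth-mutation process underlying the deterministic model:
#' an engineered cell divides with propensity `(1 - b) E`, yielding two
#' engineered daughters with probability `1 - mu` or one engineered and one
#' failed daughter with probability `mu`; a failed cell divides with
#' propensity `F` into two failed daughters.
#'
#' Methods: `"exact"` is the Gillespie stochastic simulation algorithm and
#' refuses populations beyond `exact_cap`; `"tau_leap"` advances with
#' Poisson-distributed event counts over small time steps; `"hybrid"`
#' (default) runs exact SSA while the population is below
#' `switch_threshold` — capturing the waiting time for the first mutant and
#' jackpot events — and tau-leaps above it.
#'
#' @inheritParams solve_deterministic
#' @param seed Integer seed; the trajectory is reproducible given
#'   `(params, seed, method)`.
#' @param method One of `"hybrid"`, `"exact"`, `"tau_leap"`.
#' @param switch_threshold Population size at which the hybrid method
#'   switches from exact SSA to tau-leaping.
#' @param tau Tau-leap time step, in failed-cell e-folding units; the
#'   default 0.01 keeps the expected relative population change per leap
#'   around 1%.
#' @param exact_cap Maximum final population size allowed for
#'   `method = "exact"`.
#' @return A `burden_traj` tibble; `E` and `F` are integer-valued counts.
#' @examples
#' simulate_stochastic(failure_params(0.5, 1e-4), d_max = 15, seed = 1)
#' @export
simulate_stochastic <- function(params, d_max, seed = NULL,
                                method = c("hybrid", "exact", "tau_leap"),
                                step = 0.25, switch_threshold = 1e4,
                                tau = 0.01, exact_cap = 1e6) {
  params <- as_failure_params(params)
  method <- match.arg(method)
  if (!is.numeric(d_max) || length(d_max) != 1 || is.na(d_max) || d_max <= 0) {
    stop("`d_max` must be a positive number", call. = FALSE)
  }
  total0 <- params$E0 + params$F0
  final_total <- total0 * 2^d_max
  if (method == "exact" && final_total > exact_cap) {
    stop("exact SSA refused: final population ", format(final_total),
         " exceeds exact_cap = ", format(exact_cap),
         "; use method = \"tau_leap\" or \"hybrid\"", call. = FALSE)
  }
  if (final_total > 2^60) {
    stop("final population exceeds the 2^60 overflow guard", call. = FALSE)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(as.integer(seed))
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  }
  b <- params$b; mu <- params$mu
  E <- params$E0; F <- params$F0
  t <- 0
  ssa_limit <- switch(method, exact = Inf, hybrid = switch_threshold,
                      tau_leap = 0)

  d_grid <- seq(0, d_max, by = step)
  if (d_grid[length(d_grid)] < d_max) d_grid <- c(d_grid, d_max)
  n_rec <- length(d_grid)
  rec_t <- rec_E <- rec_F <- numeric(n_rec)
  rec_i <- 1L
  record <- function() {
    # record current state for every grid point reached
    while (rec_i <= n_rec && log2((E + F) / total0) >= d_grid[rec_i] - 1e-12) {
      rec_t[rec_i] <<- t; rec_E[rec_i] <<- E; rec_F[rec_i] <<- F
      rec_i <<- rec_i + 1L
    }
  }
  record()

  # -- exact SSA phase -------------------------------------------------------
  if (ssa_limit > 0) {
    chunk <- 4096L
    repeat {
      if (E + F >= ssa_limit || rec_i > n_rec) break
      u_evt <- stats::runif(chunk)
      u_mut <- stats::runif(chunk)
      e_dt <- stats::rexp(chunk)
      for (i in seq_len(chunk)) {
        aE <- (1 - b) * E
        rate <- aE + F
        if (rate <= 0) {
          rec_i <- n_rec + 1L  # frozen population (b = 1 impossible; E=F=0)
          break
        }
        t <- t + e_dt[i] / rate
        if (u_evt[i] < aE / rate) {
          if (u_mut[i] < mu) F <- F + 1 else E <- E + 1
        } else {
          F <- F + 1
        }
        record()
        if (E + F >= ssa_limit || rec_i > n_rec) break
      }
    }
  }

  # -- tau-leap phase --------------------------------------------------------
  # Each subpopulation is a linear birth process, so its growth over a leap
  # is sampled exactly (negative binomial / Yule); E-count growth has rate
  # (1 - b)(1 - mu) since mutant divisions leave E unchanged. Mutant
  # arrivals are Poisson-coupled to the number of E divisions; only their
  # within-leap timing is approximated.
  aE <- (1 - b) * (1 - mu)
  pE <- exp(-aE * tau)
  pF <- exp(-tau)
  while (rec_i <= n_rec) {
    nE <- rnb_big(E, pE)
    m <- if (mu > 0) rpois_big(mu / (1 - mu) * nE) else 0
    nF <- rnb_big(F, pF)
    E <- E + nE
    F <- F + nF + m
    t <- t + tau
    record()
  }

  # a single leap can cross several grid points; keep one row per state
  keep <- !duplicated(rec_t)
  new_burden_traj(rec_t[keep], rec_E[keep], rec_F[keep], params,
                  provenance = "stochastic", seed = seed)
}

#' Population doublings of a trajectory
#'
#' `D(t) = log2(E + F)`, by default shifted so the founding population sits
#' at zero doublings (a single founding cell starts at `D = 0`); set
#' `absolute = TRUE` for the unshifted `log2` of the total count.
#'
#' @param traj A `burden_traj` tibble (or any data frame with `E` and `F`
#'   columns).
#' @param absolute If `TRUE`, return `log2(E + F)` without shifting by the
#'   founding population size.
#' @return Numeric vector of doublings, one per stored point.
#' @export
doublings <- function(traj, absolute = FALSE) {
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  tot <- traj$E + traj$F
  if (any(tot <= 0)) stop("E + F must be positive at every point", call. = FALSE)
  if (absolute) return(log2(tot))
  params <- attr(traj, "params")
  total0 <- if (!is.null(params)) params$E0 + params$F0 else tot[1]
  log2(tot / total0)
}

#' Doublings elapsed when the failed fraction first reaches a threshold
#'
#' Linearly interpolates the failed fraction between stored trajectory
#' points so the answer does not depend on the reporting grid.
#'
#' @inheritParams doublings
#' @param threshold Failed-fraction threshold in `(0, 1)` (default 0.5, the
#'   conventional 50%-failure summary).
#' @return Doublings at first crossing, or `NA` if the trajectory never
#'   reaches the threshold.
#' @export
time_to_half_failure <- function(traj, threshold = 0.5) {
  if (nrow(traj) == 0) stop("empty trajectory", call. = FALSE)
  stopifnot(threshold > 0, threshold < 1)
  d <- doublings(traj)
  f <- traj$failed_fraction
  if (f[1] >= threshold) return(d[1])
  idx <- which(f >= threshold)[1]
  if (is.na(idx)) return(NA_real_)
  # linear in failed fraction between the bracketing stored points
  f0 <- f[idx - 1]; f1 <- f[idx]
  d[idx - 1] + (threshold - f0) / (f1 - f0) * (d[idx] - d[idx - 1])
}

#' Ensemble of stochastic runs and the cumulative failure curve
#'
#' Runs `n_runs` independent stochastic simulations (seeds derived from
#' `seed`), records each run's doublings to 50% failure, and returns the
#' empirical cumulative distribution of failure times over doublings.
#'
#' @inheritParams simulate_stochastic
#' @param n_runs Number of independent runs (the study-scale default for
#'   published curves is 10,000; smaller ensembles are fine for exploration).
#' @param threshold Failed-fraction threshold defining failure (default 0.5).
#' @return An object of class `failure_ensemble`: a list with `params`,
#'   `n_runs`, `seed`, `half_failure_doublings` (NA where a run never
#'   failed within `d_max`), and `cdf`, a tibble of `doublings` and
#'   `frac_failed`.
#' @examples
#' ens <- ensemble_failure_curve(failure_params(0.5, 1e-4),
#'                               n_runs = 20, d_max = 34, seed = 1)
#' glance(ens)
#' @export
ensemble_failure_curve <- function(params, n_runs, d_max, seed = NULL,
                                   method = "hybrid", step = 0.25,
                                   threshold = 0.5, tau = 0.01) {
  params <- as_failure_params(params)
  stopifnot(n_runs >= 1)
  seeds <- if (is.null(seed)) sample.int(2^31 - 1, n_runs) else {
    set.seed(as.integer(seed)); sample.int(2^31 - 1, n_runs)
  }
  half <- purrr::map_dbl(seq_len(n_runs), function(i) {
    traj <- tryCatch(
      simulate_stochastic(params, d_max = d_max, seed = seeds[i],
                          method = method, step = step, tau = tau),
      error = function(e) stop("run ", i, ": ", conditionMessage(e),
                               call. = FALSE))
    time_to_half_failure(traj, threshold = threshold)
  })
  d_grid <- seq(0, d_max, by = step)
  cdf <- tibble::tibble(
    doublings = d_grid,
    frac_failed = purrr::map_dbl(d_grid,
                                 ~ mean(!is.na(half) & half <= .x))
  )
  structure(list(params = params, n_runs = n_runs, seed = seed,
                 threshold = threshold,
                 half_failure_doublings = half, cdf = cdf),
            class = "failure_ensemble")
}

#' @export
print.failure_ensemble <- function(x, ...) {
  cat("<failure_ensemble>", x$n_runs, "runs, b =", x$params$b,
      "mu =", format(x$params$mu), "\n")
  cat("  runs failed within horizon:", sum(!is.na(x$half_failure_doublings)),
      "/", x$n_runs, "\n")
  if (any(!is.na(x$half_failure_doublings))) {
    cat("  median doublings to", paste0(100 * x$threshold, "%"), "failure:",
        round(stats::median(x$half_failure_doublings, na.rm = TRUE), 2), "\n")
  }
  invisible(x)
}

#' @rdname ensemble_failure_curve
#' @param x A `failure_ensemble` object.
#' @param ... Unused.
#' @method tidy failure_ensemble
#' @export
tidy.failure_ensemble <- function(x, ...) x$cdf

#' @rdname ensemble_failure_curve
#' @method glance failure_ensemble
#' @export
glance.failure_ensemble <- function(x, ...) {
  h <- x$half_failure_doublings
  tibble::tibble(
    n_runs = x$n_runs,
    n_failed = sum(!is.na(h)),
    frac_failed = mean(!is.na(h)),
    median_half_failure = if (mean(!is.na(h)) >= 0.5) {
      stats::median(h, na.rm = TRUE)
    } else NA_real_
  )
}

#' Cell divisions needed to grow a culture
#'
#' Number of population doublings from a founding population to a saturated
#' culture: `log2(final / start)`. The final count is `volume_ml *
#' density_cells_per_ml` unless given directly via `final_cells` (e.g. a
#' colony of ~8e6 cells grown from one cell takes ~23 divisions; that colony
#' grown in 4 ml LB to 5e9 cells/ml takes ~11 more).
#'
#' @param volume_ml Culture volume in ml.
#' @param density_cells_per_ml Saturation cell density per ml.
#' @param start_cells Founding population size (default 1).
#' @param final_cells Final population size; overrides
#'   `volume_ml * density_cells_per_ml`.
#' @return A one-row tibble with `divisions` and the nearest-integer
#'   `divisions_rounded` for display.
#' @examples
#' divisions_for_culture(final_cells = 8e6)                  # colony, ~23
#' divisions_for_culture(4, 5e9, start_cells = 8e6)          # test tube, ~11
#' @export
divisions_for_culture <- function(volume_ml = NULL, density_cells_per_ml = NULL,
                                  start_cells = 1, final_cells = NULL) {
  if (is.null(final_cells)) {
    if (is.null(volume_ml) || is.null(density_cells_per_ml)) {
      stop("give either `final_cells` or both `volume_ml` and ",
           "`density_cells_per_ml`", call. = FALSE)
    }
    stopifnot(volume_ml > 0, density_cells_per_ml > 0)
    final_cells <- volume_ml * density_cells_per_ml
  }
  stopifnot(start_cells > 0)
  if (final_cells < start_cells) {
    stop("final cell count is below the founding population", call. = FALSE)
  }
  d <- log2(final_cells / start_cells)
  tibble::tibble(divisions = d, divisions_rounded = round(d))
}

#' Failure mutation rate from base substitutions
#'
#' Expected per-division failure rate contributed by point mutations:
#' `length_bp * lof_fraction * per_bp_rate`. With the canonical E. coli
#' substitution rate of 5e-10 per bp per generation, a 1000-bp coding
#' sequence in which 20% of substitutions break function fails at ~1e-7 per
#' division.
#'
#' @param length_bp Functional sequence length in base pairs.
#' @param lof_fraction Fraction of substitutions that cause loss of function.
#' @param per_bp_rate Substitution rate per bp per cell division
#'   (default 5e-10).
#' @return Failure rate per cell division.
#' @export
substitution_failure_rate <- function(length_bp, lof_fraction,
                                      per_bp_rate = 5e-10) {
  if (any(length_bp < 0) || any(per_bp_rate < 0)) {
    stop("lengths and rates must be non-negative", call. = FALSE)
  }
  if (any(lof_fraction < 0) || any(lof_fraction > 1)) {
    stop("`lof_fraction` must be in [0, 1]", call. = FALSE)
  }
  length_bp * lof_fraction * per_bp_rate
}

#' Effective failure rate for a multicopy plasmid
#'
#' Each plasmid copy is independently at risk, so the per-cell-division
#' chance of a mutant plasmid arising scales with copy number (a 100-copy
#' plasmid turns a 1e-9 per-copy rate into ~1e-7), capped at 1 since the
#' model's mutation rate is a probability per division.
#'
#' @param per_copy_rate Mutation rate per plasmid copy per division.
#' @param copy_number Plasmid copy number (integer >= 1).
#' @return Effective rate per cell division, capped at 1.
#' @export
effective_plasmid_rate <- function(per_copy_rate, copy_number) {
  if (any(per_copy_rate < 0)) stop("`per_copy_rate` must be >= 0", call. = FALSE)
  if (any(copy_number < 1) || any(copy_number != round(copy_number))) {
    stop("`copy_number` must be an integer >= 1", call. = FALSE)
  }
  pmin(1, per_copy_rate * copy_number)
}

#' Plot a failure-model trajectory
#'
#' @param object A `burden_traj` tibble.
#' @param ... Unused.
#' @return A ggplot showing engineered and failed counts (log10) against
#'   doublings.
#' @method autoplot burden_traj
#' @export
autoplot.burden_traj <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "doublings", "E", "F"),
    c("E", "F"), names_to = "population", values_to = "cells")
  ggplot2::ggplot(dplyr::filter(df, .data$cells > 0),
                  ggplot2::aes(.data$doublings, .data$cells,
                               colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "population doublings", y = "cells",
                  colour = NULL) +
    ggplot2::scale_colour_manual(
      values = c(E = "#2166ac", F = "#b2182b"),
      labels = c(E = "engineered", F = "failed"))
}

#' Plot an ensemble cumulative failure curve
#'
#' @param object A `failure_ensemble` object.
#' @param ... Unused.
#' @return A ggplot of the cumulative fraction of runs failed vs doublings.
#' @method autoplot failure_ensemble
#' @export
autoplot.failure_ensemble <- function(object, ...) {
  ggplot2::ggplot(object$cdf,
                  ggplot2::aes(.data$doublings, .data$frac_failed)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "population doublings",
                  y = paste0("fraction of runs past ",
                             100 * object$threshold, "% failure"))
}
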