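make_plate <- function(seed = 11, ...) {
  gen <- generate_plate(synth_config(...), seed = seed)
  join_plate(gen$run, gen$layout, "P1")
}

test_that("generated plates survive a CSV round trip through read_plate", {
  gen <- generate_plate(synth_config(), seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_synth(gen, dir)
  expect_no_warning(
    plate <- read_plate(paths[1], paths[2], plate_id = "P1"))
  direct <- join_plate(gen$run, gen$layout, "P1")
  expect_equal(as.data.frame(plate), as.data.frame(direct),
               tolerance = 1e-12)
  expect_equal(nrow(plate), 96 * 37 * 2)
})

test_that("malformed run or layout tables are rejected with named errors", {
  gen <- generate_plate(synth_config(n_test = 3), seed = 1)
  run <- gen$run; layout <- gen$layout
  expect_error(join_plate(rbind(run, run[1, ]), layout), "duplicate")
  expect_error(join_plate(run, layout[-1, ]), "missing from layout")
  bad <- layout; bad$role[1] <- "sample"
  expect_error(join_plate(run, bad), "unknown roles")
  run2 <- run; run2$time_min[2] <- run2$time_min[2] + 4
  expect_warning(join_plate(run2, layout), "non-uniform sampling")
})

test_that("blank subtraction removes the blank mean at every timepoint", {
  plate <- make_plate(seed = 7, n_test = 3)
  sub <- subtract_blanks(plate)
  resid <- sub |>
    dplyr::filter(role == "blank") |>
    dplyr::group_by(time_min, channel) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  expect_lt(max(abs(resid$m)), 1e-12)
  # wells identical to blanks go to zero exactly
  flat <- plate
  flat$value <- ifelse(flat$channel == "OD600", 0.04, 100)
  expect_true(all(abs(subtract_blanks(flat)$value) < 1e-12))
  no_blanks <- dplyr::filter(plate, role != "blank")
  expect_error(subtract_blanks(no_blanks), "blank")
})

test_that("baseline alignment equalises replicate first-hour means and conserves the grand mean", {
  plate <- subtract_blanks(make_plate(seed = 5, n_test = 4))
  aligned <- align_baselines(plate)
  fh <- aligned |>
    dplyr::filter(role != "blank", time_min <= 60) |>
    dplyr::group_by(strain, channel, well) |>
    dplyr::summarise(m = mean(value), .groups = "drop_last") |>
    dplyr::summarise(spread = max(m) - min(m), .groups = "drop")
  expect_lt(max(fh$spread), 1e-12)
  gm <- function(p) p |>
    dplyr::filter(role != "blank", time_min <= 60) |>
    dplyr::group_by(strain, channel) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  expect_equal(gm(aligned)$m, gm(plate)$m, tolerance = 1e-12)
  # symmetric +c / -c replicate offsets end up identical
  two <- plate |>
    dplyr::filter(strain == "part_01", channel == "OD600",
                  replicate <= 2)
  two$value <- ifelse(two$replicate == 1, two$value + 0.02,
                      two$value - 0.02)
  al2 <- align_baselines(two)
  m <- al2 |>
    dplyr::filter(time_min <= 60) |>
    dplyr::group_by(well) |>
    dplyr::summarise(m = mean(value), .groups = "drop")
  expect_equal(m$m[1], m$m[2], tolerance = 1e-12)
  expect_error(align_baselines(dplyr::filter(plate, time_min <= 40)),
               "baseline window")
})

test_that("blank subtraction and alignment are invariant to a global additive shift", {
  plate <- make_plate(seed = 9, n_test = 4)
  shifted <- dplyr::mutate(plate, value = value + 0.37)
  a <- align_baselines(subtract_blanks(plate))
  b <- align_baselines(subtract_blanks(shifted))
  expect_equal(a$value, b$value, tolerance = 1e-10)
})

test_that("single-replicate strains are unchanged by alignment", {
  plate <- subtract_blanks(make_plate(seed = 5, n_test = 4))
  one <- dplyr::filter(plate, strain == "part_02", replicate == 1)
  expect_equal(align_baselines(one)$value, one$value, tolerance = 1e-12)
})

test_that("noise-free exponential growth is recovered to high precision", {
  t <- seq(0, 360, 10)
  od <- 0.004 * exp(0.02 * t)
  fit <- fit_max_growth_rate(t, od)
  expect_equal(fit$status, "ok")
  expect_lt(abs(fit$r_max - 0.02), 1e-6)
  # scale invariance of the exponential rate
  fit2 <- fit_max_growth_rate(t, 3.7 * od)
  expect_lt(abs(fit2$r_max - 0.02), 1e-6)
  # series that never exceeds the OD threshold
  low <- fit_max_growth_rate(t, rep(0.02, length(t)))
  expect_equal(low$status, "no_growth")
})

test_that("window scan matches the brute-force oracle on a saturating curve", {
  t <- seq(0, 360, 10)
  r <- 0.015
  od <- 1 * 0.004 * exp(r * t) / (1 + 0.004 * (exp(r * t) - 1))  # logistic
  fit <- fit_max_growth_rate(t, od)
  oracle <- oracle_window_rmax(t, od)
  expect_lt(abs(fit$r_max - oracle) / oracle, 0.05)
  expect_lt(abs(fit$r_max - oracle) / oracle, 1e-4)  # same window, same NLS optimum
})

test_that("production-rate fits recover a constant true rate and reject flat fluorescence", {
  t <- seq(0, 360, 10)
  r <- 0.02; C0 <- 0.004; p <- 2500
  od <- C0 * exp(r * t)
  fl <- 50 + C0 * p / r * (exp(r * t) - 1)
  pf <- fit_max_production_rate(t, od, fl)
  expect_equal(pf$status, "ok")
  expect_lt(abs(pf$p_max - p) / p, 1e-3)
  flat <- fit_max_production_rate(t, od, rep(77, length(t)))
  expect_lt(abs(flat$p_max), 1e-9 * p)
})

test_that("time-varying production matches the brute-force window oracle", {
  t <- seq(0, 360, 10)
  r <- 0.018; C0 <- 0.005
  od <- C0 * exp(r * t)
  # production rate ramps up over the run
  p_t <- 1000 + 6 * t
  dt <- 1
  tf <- seq(0, 360, dt)
  integ <- cumsum((1000 + 6 * tf) * C0 * exp(r * tf) * dt)
  fl <- 30 + integ[match(t, tf)]
  pf <- fit_max_production_rate(t, od, fl)
  oracle <- oracle_window_pmax(t, od, fl)
  expect_lt(abs(pf$p_max - oracle) / oracle, 0.05)
})

test_that("fit_plate flags excluded wells and low-quality fits explicitly", {
  plate <- make_plate(seed = 13, n_test = 4)
  fits <- fit_plate(plate)
  expect_setequal(unique(fits$status), "ok")
  expect_true(all(c("r_max", "p_max_GFP", "F0_GFP", "flag_low_r2") %in%
                    names(fits)))
  excl <- fit_plate(plate, exclude = "part_01")
  expect_false("part_01" %in% excl$strain)
  expect_equal(nrow(fits) - nrow(excl), 3)
})
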