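test_that("kernel density estimate equals the direct summation oracle", {
  set.seed(1)
  vals <- rnorm(40, 0.02, 0.002)
  bw <- 0.0005
  x <- runif(50, 0.01, 0.03)
  kd <- kde_density(vals, bw, grid = x)
  expect_lt(max(abs(kd$density - oracle_kde(vals, bw, x))), 1e-12)
  # single value: unique maximum at the value
  kd1 <- kde_density(0.025, bw)
  expect_lt(abs(kd1$x[which.max(kd1$density)] - 0.025), 1e-4)
  # symmetric clusters give a symmetric density
  vals2 <- c(-0.01, -0.011, 0.01, 0.011)
  g <- seq(-0.02, 0.02, length.out = 401)
  kd2 <- kde_density(vals2, 0.002, grid = g)
  expect_lt(max(abs(kd2$density - rev(kd2$density))), 1e-12)
  expect_error(kde_density(numeric(), 0.01), "values")
})

test_that("the no-burden peak rule follows the 50%-height convention", {
  bw <- 0.0007
  # unimodal cluster
  set.seed(2)
  uni <- rnorm(30, 0.021, 0.0004)
  expect_lt(abs(no_burden_reference(uni, bw) - 0.021), bw / 2)
  # tall peak at 0.020, secondary at 0.025 with ~60% height: take 0.025
  v60 <- c(rep(0.020, 10), rep(0.025, 6))
  expect_equal(no_burden_reference(v60, bw), oracle_no_burden(v60, bw),
               tolerance = 1e-4)
  expect_gt(no_burden_reference(v60, bw), 0.024)
  # secondary peak at only ~30% height: stay at 0.020
  v30 <- c(rep(0.020, 10), rep(0.025, 3))
  expect_equal(no_burden_reference(v30, bw), oracle_no_burden(v30, bw),
               tolerance = 1e-4)
  expect_lt(no_burden_reference(v30, bw), 0.021)
  expect_error(no_burden_reference(c(1, 2), bw), "3 values")
})

test_that("plate normalization divides by the non-control reference", {
  fits <- tibble::tibble(
    plate = "P1",
    strain = c(rep(sprintf("s%d", 1:5), each = 3), rep("BFP1", 3)),
    role = rep(c("test", "control"), c(15, 3)),
    r_max = c(rep(0.02, 15), rep(0.012, 3)))
  nn <- normalize_plate(fits, "growth_rate", bandwidth = 0.0002)
  # the reference sits on the KDE grid, so agreement is grid-resolution level
  expect_equal(nn$normalized_r_max[nn$role == "test"], rep(1, 15),
               tolerance = 1e-3)
  expect_equal(nn$normalized_r_max[nn$role == "control"], rep(0.6, 3),
               tolerance = 1e-3)
  # control-only plate cannot be normalized
  ctrl_only <- dplyr::filter(fits, role == "control")
  expect_error(normalize_plate(ctrl_only, "growth_rate", 0.0002),
               "non-control")
  # idempotence: renormalizing on the rescaled bandwidth changes nothing
  ref <- attr(nn, "no_burden_value")
  nn2 <- normalize_plate(
    dplyr::mutate(nn, r_max = normalized_r_max), "growth_rate",
    bandwidth = 0.0002 / ref)
  expect_equal(nn2$normalized_r_max, nn$normalized_r_max, tolerance = 1e-9)
})

test_that("burden summary matches direct t-test computations", {
  # all measurements at the no-burden rate: zero burden, p = 1 convention
  flat <- tibble::tibble(strain = "a", normalized_r_max = rep(1, 3))
  bs <- burden_summary(flat)
  expect_equal(bs$burden_pct, 0)
  expect_equal(bs$p_vs_0, 1)
  # seeded Gaussian sample checked against stats::t.test
  set.seed(10)
  x <- rnorm(9, 0.80, 0.01)
  dat <- tibble::tibble(strain = "b", normalized_r_max = x)
  bs2 <- burden_summary(dat)
  burden <- 100 * (1 - x)
  expect_equal(bs2$burden_pct, mean(burden), tolerance = 1e-12)
  expect_equal(bs2$p_vs_0,
               t.test(burden, mu = 0, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_equal(bs2$p_vs_30,
               t.test(burden, mu = 30, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_lt(bs2$p_vs_0, 1e-6)
  expect_gt(bs2$p_vs_30, 0.05)
  expect_equal(bs2$ci95, qt(0.975, 8) * sd(burden) / 3, tolerance = 1e-12)
  # two identical measurements: zero variance above the threshold
  two <- burden_summary(tibble::tibble(strain = "c",
                                       normalized_r_max = c(0.9, 0.9)))
  expect_equal(two$burden_pct, 10)
  expect_equal(two$ci95, 0)
  expect_equal(two$p_vs_0, 0)   # mean strictly above threshold, sd = 0
  expect_equal(two$p_vs_20, 1)  # mean below threshold, sd = 0
  # single measurement is untestable
  one <- burden_summary(tibble::tibble(strain = "d", normalized_r_max = 0.8))
  expect_true(one$untestable)
  expect_true(is.na(one$p_vs_0))
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03)$p_adj, 0.03)
  expect_equal(bh_adjust(rep(0.2, 5))$p_adj, rep(0.2, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04))$p_adj, rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p)$p_adj, oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("burden significance is invariant to rescaling all raw rates on a plate", {
  gen <- generate_plate(synth_config(), seed = 31)
  fits <- fit_plate(join_plate(gen$run, gen$layout, "P1"))
  n1 <- normalize_plate(fits, "growth_rate")
  scaled <- dplyr::mutate(fits, r_max = r_max * 1.6)
  n2 <- normalize_plate(scaled, "growth_rate", bandwidth = 0.014 / 60 * 1.6)
  expect_equal(n2$normalized_r_max, n1$normalized_r_max, tolerance = 1e-9)
  b1 <- burden_summary(n1)
  b2 <- burden_summary(n2)
  expect_equal(b2$p_vs_0, b1$p_vs_0, tolerance = 1e-9)
  expect_equal(b2$significant, b1$significant)
})

test_that("SEM-vs-burden trend is null on homoskedastic parts and needs 3 parts", {
  m <- generate_normalized_measurements(1000, 6, burden = runif(1000, 0, 0.4),
                                        seed = 77)
  bs <- burden_summary(m)
  tr <- sem_burden_trend(bs)
  expect_gt(tr$p_value, 0.05)
  expect_lt(abs(tr$slope), 0.05)
  expect_error(sem_burden_trend(bs[1:2, ]), "3 parts")
})
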