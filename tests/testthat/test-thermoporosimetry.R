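# Gibbs-Thomson inversion, thermogram segmentation and integration.

test_that("gibbs_thomson_diameter matches direct arithmetic", {
  # 4 * 273.15 * 0.0121 / (1 * 1000 * 334000), sign cancelled by cos(180)
  oracle <- 4 * 273.15 * 12.1e-3 / (1 * 1000 * 334e3)
  expect_equal(gibbs_thomson_diameter(272.15), oracle, tolerance = 1e-12)
  expect_equal(gibbs_thomson_diameter(272.15) * 1e9, 39.58, tolerance = 1e-3)
  # 10 K depression is exactly one tenth of the 1 K case
  expect_equal(gibbs_thomson_diameter(263.15),
               gibbs_thomson_diameter(272.15) / 10, tolerance = 1e-12)
  expect_error(gibbs_thomson_diameter(273.15), "below T0")
  expect_error(gibbs_thomson_diameter(274), "below T0")
})

test_that("diameter scales as 1/depression over random depressions", {
  set.seed(4)
  dT <- runif(100, 0.01, 40)
  D <- gibbs_thomson_diameter(273.15 - dT)
  ref <- gibbs_thomson_diameter(273.15 - 1)
  expect_true(all(abs(D * dT / ref - 1) < 1e-10))
})

test_that("melting_temperature_for_diameter inverts the relation", {
  set.seed(9)
  D <- 10^runif(100, -9.5, -6)
  Tm <- melting_temperature_for_diameter(D)
  expect_true(all(abs(gibbs_thomson_diameter(Tm) / D - 1) < 1e-10))
  # large pores melt arbitrarily close to T0
  expect_lt(273.15 - melting_temperature_for_diameter(1), 1e-7)
  expect_error(melting_temperature_for_diameter(0), "positive")
})

test_that("1.2-10 K depressions bracket the 4-32 nm mesopore window", {
  D <- gibbs_thomson_diameter(273.15 - c(9.9, 1.24)) * 1e9
  expect_lt(D[1], 4.1); expect_gt(D[1], 3.5)
  expect_gt(D[2], 31); expect_lt(D[2], 33)
})

test_that("segment_steps finds programmed holds and flags missing ones", {
  fx <- mesopore_fixture()
  tg <- gen_dsc_thermogram(fx$dist, fx$program, seed = 1)
  win <- segment_steps(tg, fx$program)
  expect_equal(nrow(win), nrow(fx$program))
  expect_equal(win$temp_K, fx$program$temp_K)
  # windows cover essentially the full programmed hold
  expect_true(all(win$t_end - win$t_start > 0.95 * fx$program$duration_s))
  bad <- step_program(temp_C = c(-50, 2), duration_s = 600)
  expect_error(segment_steps(tg, bad), "-50")
})

test_that("single-hold flat trace yields one full-length window", {
  pr <- step_program(temp_C = -5, duration_s = 300)
  tg <- dsc_thermogram(1:300, rep(268.15, 300), rep(0, 300), 8)
  win <- segment_steps(tg, pr)
  expect_equal(nrow(win), 1L)
  expect_equal(c(win$i_start, win$i_end), c(1L, 300L))
})

test_that("integrate_endotherm recovers an analytic Gaussian area", {
  tt <- seq(1, 600)
  sigma <- 20; area <- 500                       # mJ
  hf <- area / (sigma * sqrt(2 * pi)) * exp(-((tt - 300)^2) / (2 * sigma^2))
  tg <- dsc_thermogram(tt, rep(268.15, 600), hf, sample_mass_mg = 8)
  win <- list(i_start = 1L, i_end = 600L)
  expect_equal(integrate_endotherm(win, tg), area / 8, tolerance = 0.005)
  # baseline-only window integrates to zero
  tg0 <- dsc_thermogram(tt, rep(268.15, 600), rep(0.3, 600), 8)
  expect_equal(integrate_endotherm(win, tg0), 0, tolerance = 1e-9)
  # sloped baseline with no peak cancels in linear mode
  tgs <- dsc_thermogram(tt, rep(268.15, 600), 0.01 * tt, 8)
  expect_equal(suppressWarnings(          # residual area clips to zero
    integrate_endotherm(win, tgs, baseline = "linear")), 0, tolerance = 1e-6)
  expect_error(integrate_endotherm(list(i_start = 5L, i_end = 5L), tg),
               "zero-length")
})

test_that("pore_distribution apportions water mass by melting step", {
  # two holds with equal enthalpies -> 50/50; Hf = 334 J/g
  steps <- data.frame(temp_K = c(263.15, 268.15),
                      enthalpy_J_per_g = c(167, 167))
  d <- pore_distribution(steps, sample_mass_mg = 8,
                         start_temperature_K = 243.15)
  expect_equal(d$bins$water_fraction_pct, c(50, 50))
  expect_equal(d$total_freezing_water_mg, 2 * 167 * 8 / 334)
  # one hold carrying all enthalpy -> 100% in its bin
  one <- pore_distribution(data.frame(temp_K = 268.15,
                                      enthalpy_J_per_g = 100),
                           sample_mass_mg = 8, start_temperature_K = 243.15)
  expect_equal(one$bins$water_fraction_pct, 100)
  expect_error(pore_distribution(
    data.frame(temp_K = c(263, 268), enthalpy_J_per_g = c(0, 0)),
    sample_mass_mg = 8), "degenerate")
})

test_that("bin edges follow consecutive hold temperatures", {
  steps <- data.frame(temp_K = c(263.15, 268.15, 271.15),
                      enthalpy_J_per_g = c(50, 80, 30))
  d <- pore_distribution(steps, sample_mass_mg = 5,
                         start_temperature_K = 243.15)
  expect_equal(d$bins$d_low_m,
               gibbs_thomson_diameter(c(243.15, 263.15, 268.15)))
  expect_equal(d$bins$d_high_m,
               gibbs_thomson_diameter(c(263.15, 268.15, 271.15)))
})

test_that("forward-inverse round trip recovers the 5-bin ground truth", {
  fx <- mesopore_fixture(fracs = c(10, 15, 20, 25, 10), free = 20)
  tg <- gen_dsc_thermogram(fx$dist, fx$program, seed = 2)
  rec <- suppressWarnings(thermogram_to_pores(tg, fx$program))
  # match recovered bins to ground-truth bins by upper edge
  for (i in seq_len(nrow(fx$dist$bins))) {
    j <- which.min(abs(rec$bins$d_high_m - fx$dist$bins$d_high_m[i]))
    expect_equal(rec$bins$water_fraction_pct[j],
                 fx$dist$bins$water_fraction_pct[i], tolerance = 0.02)
  }
  expect_equal(rec$free_water_fraction_pct, 20, tolerance = 0.02)
  # mass conservation within 0.5%
  expect_equal(rec$total_freezing_water_mg,
               fx$dist$total_freezing_water_mg, tolerance = 0.005)
})

test_that("total_water_content follows the oven-dry definition", {
  expect_equal(total_water_content(10, 4), 60)
  expect_equal(total_water_content(8, 8), 0)
  expect_error(total_water_content(8, 0), "positive")
  expect_error(total_water_content(4, 8), "exceeds")
})

test_that("thermogram and distribution survive CSV round trips", {
  fx <- mesopore_fixture()
  tg <- gen_dsc_thermogram(fx$dist, fx$program, seed = 1)
  f <- tempfile(fileext = ".csv")
  write_thermogram(tg, f)
  tg2 <- read_thermogram(f)
  expect_equal(attr(tg2, "sample_mass_mg"), attr(tg, "sample_mass_mg"))
  expect_equal(tg2$heat_flow_mW, tg$heat_flow_mW, tolerance = 1e-8)
  rec <- suppressWarnings(thermogram_to_pores(tg2, fx$program))
  f2 <- tempfile(fileext = ".csv")
  write_pore_distribution(rec, f2)
  tab <- read.csv(f2)
  expect_equal(tab$freezing_water_pct, rec$bins$water_fraction_pct)
  unlink(c(f, sub("\\.csv$", ".json", f), f2, sub("\\.csv$", ".json", f2)))
})
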