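# Determinism, noise handling and ground-truth bookkeeping of the
# simulators.

test_that("identical seeds give byte-identical generator output", {
  p <- cluster_params()
  expect_identical(gen_park_isotherm(p, seq(0.1, 0.9, 0.1), 0.02, seed = 5),
                   gen_park_isotherm(p, seq(0.1, 0.9, 0.1), 0.02, seed = 5))
  sched <- data.frame(aw = c(0, 0.5), duration_s = 4800)
  expect_identical(gen_dvs_kinetics(p, sched, noise_sd = 0.01, seed = 5),
                   gen_dvs_kinetics(p, sched, noise_sd = 0.01, seed = 5))
  fx <- mesopore_fixture()
  expect_identical(gen_dsc_thermogram(fx$dist, fx$program, noise_sd = 0.01,
                                      seed = 5),
                   gen_dsc_thermogram(fx$dist, fx$program, noise_sd = 0.01,
                                      seed = 5))
  expect_identical(gen_image_stack(seed = 5), gen_image_stack(seed = 5))
  specs <- list(list(label = "A", dist = "normal", mean = 0, sd = 1, n = 5),
                list(label = "B", dist = "normal", mean = 1, sd = 1, n = 5))
  expect_identical(gen_grouped_measurements(specs, seed = 5),
                   gen_grouped_measurements(specs, seed = 5))
})

test_that("gen_park_isotherm honours its noise and domain contracts", {
  p <- park_params(0, 0, 5, 0, 1)          # pure Henry
  iso <- gen_park_isotherm(p, c(0.2, 0.4), noise_sd = 0, seed = 1)
  expect_equal(iso$M, c(1, 2))
  p2 <- park_params(1, 10, 0.2, 0.5, 4)
  iso2 <- gen_park_isotherm(p2, 0.5, noise_sd = 0, seed = 1)
  expect_equal(iso2$M, 0.93353, tolerance = 1e-4)
  expect_error(gen_park_isotherm(p, c(0.2, 1.0), 0, 1), "\\[0, 1\\)")
  expect_error(gen_park_isotherm(p, c(0.4, 0.2), 0, 1), "increasing")
  expect_error(gen_park_isotherm(p, 0.5, -0.1, 1), "noise_sd")
})

test_that("gen_dvs_kinetics relaxes exponentially toward Park equilibria", {
  p <- kinetic_params()
  # single a_w = 0 hold: flat at the dry mass
  tr0 <- gen_dvs_kinetics(p, data.frame(aw = 0, duration_s = 1200), seed = 1)
  expect_true(all(abs(tr0$mass_mg - 20) < 1e-9))
  # long holds approach the asymptote to within 0.1%
  tr <- gen_dvs_kinetics(p, data.frame(aw = c(0, 0.5), duration_s = 6000),
                         tau = 600, seed = 1)
  m_end <- tr$mass_mg[nrow(tr)]
  m_eq <- 20 * (1 + park_model(p, 0.5) / 100)
  expect_lt(abs(m_end - m_eq) / m_eq, 0.001)
  expect_error(gen_dvs_kinetics(p, data.frame()), "at least one hold")
})

test_that("DSC generator conserves endotherm energy", {
  fx <- mesopore_fixture()
  tg <- gen_dsc_thermogram(fx$dist, fx$program, seed = 1)
  # total trapezoid area over the whole trace = total water mass x Hf
  hf <- tg$heat_flow_mW; tt <- tg$time_s
  area <- sum(diff(tt) * (head(hf, -1) + tail(hf, -1)) / 2)
  expect_equal(area, fx$dist$total_freezing_water_mg * 334,
               tolerance = 0.005)
  # single-bin distribution: one endotherm of analytic area
  one <- pore_size_distribution(
    data.frame(d_low_m = 4e-9, d_high_m = 8e-9, water_fraction_pct = 100),
    free_water_fraction_pct = 0, total_freezing_water_mg = 2)
  Tm <- melting_temperature_for_diameter(8e-9)
  pr <- step_program(temp_C = c(Tm - 273.15 - 5, Tm - 273.15),
                     duration_s = 600)
  tg1 <- gen_dsc_thermogram(one, pr, seed = 1)
  hf1 <- tg1$heat_flow_mW
  a1 <- sum(diff(tg1$time_s) * (head(hf1, -1) + tail(hf1, -1)) / 2)
  expect_equal(a1, 2 * 334, tolerance = 0.005)
  # two equal bins -> two equal peaks
  fx2 <- mesopore_fixture(fracs = c(50, 50), free = 0)
  tg2 <- gen_dsc_thermogram(fx2$dist, fx2$program, seed = 1)
  win <- segment_steps(tg2, fx2$program)
  dH <- vapply(seq_len(nrow(win)), function(k)
    suppressWarnings(integrate_endotherm(win[k, ], tg2)), numeric(1))
  peaks <- dH[dH > max(dH) / 2]
  expect_equal(peaks[1], peaks[2], tolerance = 0.001)
  # zero freezing water in a hold leaves it at baseline
  expect_error(gen_dsc_thermogram(
    fx$dist, structure(fx$program[c(2, 1), ], class = class(fx$program))),
    "increasing")
})

test_that("image generator separates wall and lumen as programmed", {
  st <- gen_image_stack(noise_sd = 0, seed = 1,
                        target_levels = c(wall = 100, background = 10))
  pr <- max_project(st)
  expect_true(all(pr$target[st$truth_mask] == 100))
  expect_true(all(pr$target[!st$truth_mask] == 10))
  expect_true(all(pr$counterstain[!st$truth_mask] == 0))
  # wall/lumen ratio is plausible for wood sections
  frac <- mean(st$truth_mask)
  expect_gt(frac, 0.1); expect_lt(frac, 0.6)
})

test_that("grouped generator validates distributions and sizes", {
  expect_error(gen_grouped_measurements(list(
    list(label = "A", dist = "cauchy", mean = 0, sd = 1, n = 5))),
    "unsupported")
  expect_error(gen_grouped_measurements(list(
    list(label = "A", dist = "normal", mean = 0, sd = 1, n = 2))),
    "n >= 3")
  d <- gen_grouped_measurements(list(
    list(label = "A", dist = "uniform", mean = 10, sd = 1, n = 50),
    list(label = "B", dist = "constant", mean = 3, sd = 0, n = 3)), seed = 1)
  expect_true(all(abs(d$value[d$group == "A"] - 10) <= sqrt(3) + 1e-9))
  expect_true(all(d$value[d$group == "B"] == 3))
})

test_that("ground-truth sidecars serialize the programmed parameters", {
  p <- cluster_params()
  iso <- gen_park_isotherm(p, seq(0.1, 0.9, 0.1), 0, seed = 1)
  f <- tempfile(fileext = ".json")
  write_ground_truth(iso, f)
  gt <- jsonlite::fromJSON(f)
  expect_equal(gt$A_L, 1); expect_equal(gt$k_H, 5)
  st <- gen_image_stack(seed = 1)
  f2 <- tempfile(fileext = ".json")
  write_ground_truth(st, f2)
  gt2 <- jsonlite::fromJSON(f2)
  expect_equal(gt2$wall_pixel_count, sum(st$truth_mask))
  unlink(c(f, f2))
})
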