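test_that("complex-conductivity decomposition is exact and invertible", {
  z <- sigma_components(1, 0)
  expect_equal(z$sigma_real, 1)
  expect_equal(z$sigma_imag, 0)
  # magnitude recovered from the printed quadrature/phase pair at 1 Hz
  mag <- 5.1e-5 / sin(4.1 / 1000)
  d <- sigma_components(mag, 4.1)
  expect_equal(d$sigma_imag, 5.1e-5, tolerance = 1e-12)
  expect_equal(d$sigma_real, mag * cos(0.0041), tolerance = 1e-12)
  # round trip on random pairs, and |sigma|^2 = s'^2 + s''^2
  set.seed(3)
  m0 <- runif(50, 1e-4, 1); p0 <- runif(50, 0, 100)
  dd <- sigma_components(m0, p0)
  back <- sigma_polar(dd$sigma_real, dd$sigma_imag)
  expect_lt(max(abs(back$magnitude - m0) / m0), 1e-12)
  expect_lt(max(abs(back$phase_mrad - p0) / p0), 1e-12)
  expect_lt(max(abs(dd$sigma_real^2 + dd$sigma_imag^2 - m0^2) / m0^2),
            1e-12)
  expect_error(sigma_components(-1, 0), ">= 0")
})

test_that("percent change reproduces the reported fluid-conductivity and
          polarization increases", {
  expect_equal(percent_change(1, 1), 0)
  expect_equal(percent_change(0.064, 0.0714), 12, tolerance = 0.05)
  # quadrature conductivity at 1 Hz: reported 30.6 percent (+-7)
  expect_equal(percent_change(5.1e-5, 6.7e-5), 30.6, tolerance = 0.25)
  expect_error(percent_change(0, 1), "baseline")
})

test_that("hydraulic metrics match the reported residence time and
          pore-volume throughput", {
  hm <- hydraulic_metrics(column_config())
  expect_equal(hm$residence_time_h, 32, tolerance = 0.02)
  expect_equal(hm$pore_volumes_per_day, 0.7, tolerance = 0.07)
  expect_equal(hm$pore_volume_mL, pi * 3.8^2 * 20 * 0.45,
               tolerance = 1e-12)
  # doubling the flow halves the residence time exactly
  hm2 <- hydraulic_metrics(column_config(flow_mL_min = 0.42))
  expect_equal(hm2$residence_time_h, hm$residence_time_h / 2,
               tolerance = 1e-12)
})

test_that("the precipitate budget reproduces the reported mass, volume and
          pore-space fraction", {
  pb <- precipitate_budget(4.8, 0.12e-3)
  expect_equal(pb$mass_g, 0.058, tolerance = 0.01)
  expect_equal(pb$volume_cm3, 0.021, tolerance = 0.02)
  expect_equal(pb$pore_space_pct, 0.007, tolerance = 0.1)
  # homogeneous of degree 1 in throughput and deficit
  pb2 <- precipitate_budget(2 * 4.8, 0.12e-3)
  pb3 <- precipitate_budget(4.8, 2 * 0.12e-3)
  expect_equal(pb2$mass_g, 2 * pb$mass_g, tolerance = 1e-12)
  expect_equal(pb3$mass_g, 2 * pb$mass_g, tolerance = 1e-12)
})

test_that("effluent summaries reproduce the reported steady-state changes", {
  # constant series at the measured steady effluent, vs measured influent
  series <- data.frame(time_days = seq(0, 10, by = 0.5),
                       Urea = 8.7e-3, Ca = 0.78e-3, Sr = 2.4e-6,
                       alkalinity_meq_L = 3.7)
  infl <- list(Urea = 10e-3, Ca = 1.08e-3, Sr = 3e-6,
               alkalinity_meq_L = 4.4)
  sm <- effluent_summaries(series, infl)
  expect_equal(sm$urea_hydrolyzed_pct, 13, tolerance = 1e-9)
  expect_equal(sm$ca_decrease_pct, 28, tolerance = 0.01)
  expect_equal(sm$sr_decrease_pct, 20, tolerance = 1e-9)
  expect_equal(sm$alk_decrease_pct, 16, tolerance = 0.01)
  # ~2:1 alkalinity:Ca stoichiometric ratio of calcite precipitation
  expect_equal(sm$alk_to_ca_ratio, 2.33, tolerance = 0.01)
  expect_error(effluent_summaries(series[0, ], infl), "empty|>= 1")
})

test_that("the in-phase / fluid conductivity regression behaves", {
  sw <- seq(0.05, 0.09, length.out = 20)
  exact <- suppressWarnings(archie_check(0.5 * sw, sw))
  expect_equal(exact$slope, 0.5, tolerance = 1e-12)
  expect_equal(exact$r2, 1, tolerance = 1e-12)
  set.seed(9)
  noisy <- archie_check(0.5 * sw * (1 + rnorm(20, sd = 0.01)), sw)
  expect_gt(noisy$r2, 0.99)
  set.seed(4)
  shuffled <- archie_check(sample(0.5 * sw), sw)
  expect_lt(shuffled$r2, 0.5)
  expect_error(archie_check(rep(1, 5), rep(2, 5)), "degenerate")
  expect_error(archie_check(1:2, 1:2), "n >= 3")
})

test_that("spectrum CSVs are parsed and decomposed", {
  path <- system.file("extdata", "spectrum_pre_urea.csv",
                      package = "ureocol")
  sp <- read_spectrum_csv(path)
  expect_true(all(c("sigma_real", "sigma_imag") %in% names(sp)))
  expect_equal(sp$sigma_imag[sp$frequency_hz == 1], 5.1e-5,
               tolerance = 1e-3)
  bad <- tempfile(fileext = ".csv")
  writeLines("x,y\n1,2", bad)
  expect_error(read_spectrum_csv(bad), "header")
})
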