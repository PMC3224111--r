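test_that("activity coefficients follow the extended Debye-Hueckel law", {
  expect_equal(activity_coefficient(1, 4, 0), 1)
  expect_equal(activity_coefficient(-2, 4.5, 0), 1)
  expect_equal(activity_coefficient(0, 0, 0.5), 1)
  # hand evaluation: log10(g) = -0.5085*sqrt(I)/(1 + 0.3281*4*sqrt(I))
  g_hand <- 10^(-0.5085 * 1 * sqrt(0.01) / (1 + 0.3281 * 4 * sqrt(0.01)))
  expect_equal(activity_coefficient(1, 4, 0.01), g_hand, tolerance = 1e-12)
  expect_error(activity_coefficient(1, 4, -0.1), "ionic strength")
  # monotone decreasing in I for charged species
  I <- seq(0, 0.1, length.out = 40)
  g <- activity_coefficient(2, 6, I)
  expect_true(all(diff(g) < 0))
})

test_that("pure water speciates to pH 7 at vanishing ionic strength", {
  s <- speciate(water_composition(pH = 7), mode = "charge_balance")
  expect_equal(s$pH, 7, tolerance = 1e-3)
  expect_lt(s$ionic_strength, 2e-7)
  expect_lt(abs(s$charge_balance), 1e-10)
})

test_that("fixed-pH speciation matches a hand-computed carbonate chain", {
  # 3 mM NaHCO3 at pH 8: independent closed-form mass-action chain
  w <- water_composition(Na = 3, CO3 = 3, pH = 8, unit = "mM")
  s <- speciate(w)
  A <- 0.5085; B <- 0.3281
  I <- s$ionic_strength   # take the solved ionic strength as given
  gam <- function(z, a) 10^(-A * z^2 * sqrt(I) / (1 + B * a * sqrt(I)))
  h <- 10^-8
  r1 <- 10^-6.35 / (h * gam(1, 4))
  r2 <- 10^-10.33 * gam(1, 4) / (h * gam(2, 4.5))
  co2 <- 3e-3 / (1 + r1 + r1 * r2)
  expect_equal(unname(s$molal["CO2"]), co2, tolerance = 1e-10)
  expect_equal(unname(s$pCO2_bar), co2 / 10^-1.47, tolerance = 1e-10)
  # carbon conservation
  expect_equal(sum(s$molal[c("CO2", "HCO3", "CO3")]), 3e-3,
               tolerance = 1e-12)
})

test_that("the pre-urea pore water reproduces the measured CO2 pressure", {
  s <- speciate(default_waters()$initial)
  expect_lt(abs(log10(s$pCO2_bar) - (-2.37)), 0.1)
})

test_that("charge-balance mode zeroes the residual on random waters", {
  set.seed(42)
  for (i in 1:15) {
    na <- runif(1, 0.5, 5); ca <- runif(1, 0.1, 2)
    co3 <- runif(1, 0.5, 4); nh4 <- runif(1, 0, 2)
    cl <- max(0.1, na + 2 * ca + nh4 - 2 * co3 + runif(1, -0.5, 0.5))
    w <- water_composition(Na = na, Ca = ca, CO3 = co3, NH4 = nh4,
                           Cl = cl, pH = 7, unit = "mM")
    s <- speciate(w, mode = "charge_balance")
    expect_lt(abs(s$charge_balance), 1e-10)
    expect_equal(sum(s$molal[c("CO2", "HCO3", "CO3")]), co3 / 1000,
                 tolerance = 1e-12)
    expect_equal(sum(s$molal[c("NH4", "NH3")]), nh4 / 1000,
                 tolerance = 1e-12)
    # idempotence: re-speciating the solved state changes nothing
    w2 <- w; w2$pH <- s$pH
    s2 <- speciate(w2, mode = "charge_balance")
    expect_equal(s2$pH, s$pH, tolerance = 1e-9)
  }
})

test_that("carbonate adjustment achieves charge balance at fixed pH", {
  # the urea-amended influent: residual must vanish and the implied CO2
  # pressure land near the reported 10^-3.01 bar (soft, database-bound)
  w <- adjust_carbonate_for_charge_balance(default_waters()$urea_influent)
  s <- speciate(w)
  expect_lt(abs(s$charge_balance), 1e-10)
  expect_lt(abs(log10(s$pCO2_bar) - (-3.01)), 0.2)

  # fixed point: a balanced water is returned unchanged
  w2 <- adjust_carbonate_for_charge_balance(w)
  expect_equal(w2$conc[["CO3"]], w$conc[["CO3"]], tolerance = 1e-9)

  # brute-force bisection oracle on a deliberate +0.5 meq/L cation excess
  wx <- water_composition(Na = 2.5, Cl = 2.0, CO3 = 0.1, pH = 8,
                          unit = "mM")
  adj <- adjust_carbonate_for_charge_balance(wx)
  resid <- function(tco3) {
    ww <- wx; ww$conc["CO3"] <- tco3
    speciate(ww)$charge_balance
  }
  lo <- 0; hi <- 0.01
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (resid(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal(adj$conc[["CO3"]], (lo + hi) / 2, tolerance = 1e-8)
  expect_gt(adj$conc[["CO3"]], wx$conc[["CO3"]])

  # infeasible: anion excess cannot be fixed by adding carbonate
  bad <- water_composition(Na = 1, Cl = 2, pH = 7, unit = "mM")
  expect_error(adjust_carbonate_for_charge_balance(bad), "infeasible")
})

test_that("calcite equilibration solves SI = 0 and charge balance jointly", {
  w <- equilibrate_with_calcite(default_waters()$initial)
  s <- speciate(w)
  expect_lt(abs(s$SI_calcite), 1e-6)
  expect_lt(abs(s$charge_balance), 1e-10)
  # lands near the reported in-column pH of 7.62
  expect_lt(abs(w$pH - 7.62), 0.15)
  # fixed point
  w2 <- equilibrate_with_calcite(w)
  expect_equal(w2$pH, w$pH, tolerance = 1e-6)
  # a supersaturated synthetic Ca-HCO3 water is brought exactly to SI = 0
  wx <- water_composition(Ca = 2, CO3 = 4, Na = 1, Cl = 1, pH = 8.3,
                          unit = "mM")
  wq <- equilibrate_with_calcite(wx)
  expect_lt(abs(speciate(wq)$SI_calcite), 1e-6)
  expect_equal(wq$conc[["Ca"]], wx$conc[["Ca"]])  # Ca held fixed
})

test_that("TDS sums species masses and scales with concentration", {
  expect_lt(tds(speciate(water_composition(pH = 7))), 0.01)
  w1 <- simple_water()
  s1 <- speciate(w1)
  # spreadsheet-style oracle: sum molalities times molar masses
  masses <- c(H = 1.008, OH = 17.007, CO2 = 44.009, HCO3 = 61.017,
              CO3 = 60.009, NH4 = 18.039, NH3 = 17.031, Na = 22.990,
              K = 39.098, Mg = 24.305, Ca = 40.078, Sr = 87.62,
              Cl = 35.453, NO3 = 62.004, SO4 = 96.06, Al = 26.982,
              Si = 60.084, Urea = 60.056, O2 = 31.998)
  expect_equal(tds(s1), sum(s1$molal * masses[names(s1$molal)]) * 1000,
               tolerance = 1e-12)
  # near-homogeneity: doubling all components doubles TDS within 1 percent
  w2 <- w1; w2$conc <- w1$conc * 2
  expect_equal(tds(speciate(w2)) / tds(s1), 2, tolerance = 0.01)
})

test_that("water compositions round-trip through CSV", {
  w <- default_waters()$urea_influent
  path <- tempfile(fileext = ".csv")
  write_water_csv(w, path, unit = "mM")
  w2 <- read_water_csv(path)
  expect_equal(w2$conc, w$conc, tolerance = 1e-12)
  expect_equal(w2$pH, w$pH)
  expect_error(read_water_csv({
    p <- tempfile(fileext = ".csv")
    writeLines("a,b\n1,2", p); p
  }), "header")
})
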