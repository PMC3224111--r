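test_that("a single-cation system loads the exchanger fully with that cation", {
  w <- adjust_carbonate_for_charge_balance(
    water_composition(Ca = 1, Cl = 1.9, pH = 7, unit = "mM"))
  ex <- exchanger_state(cap_eq_L = 0.1)
  eq <- equilibrate_exchange(w, ex, exchanger_config())
  expect_equal(unname(eq$exchanger$beta[["Ca"]]), 1)
  expect_equal(sum(eq$exchanger$beta), 1)
  # solution unchanged: the exchanger was already all-Ca at capacity
  expect_equal(eq$water$conc[["Ca"]], w$conc[["Ca"]], tolerance = 1e-9)
})

test_that("a two-cation Na/Ca system matches the closed-form Gapon solution", {
  cfg <- exchanger_config()
  w <- adjust_carbonate_for_charge_balance(
    water_composition(Na = 3, Ca = 1, Cl = 4.8, pH = 7, unit = "mM"))
  cap <- 0.05
  ex <- exchanger_state(c(Na = 0.3, K = 0, NH4 = 0, Ca = 0.7, Mg = 0,
                          Sr = 0), cap)
  eq <- equilibrate_exchange(w, ex, cfg)

  # independent scalar solve: unknown beta_Na; conservation gives the
  # aqueous concentrations, the Gapon relation closes the system
  s <- speciate(w)
  g_na <- unname(s$act["Na"] / s$molal["Na"])
  g_ca <- unname(s$act["Ca"] / s$molal["Ca"])
  T_na <- w$conc[["Na"]] + cap * 0.3
  T_ca <- w$conc[["Ca"]] + cap * 0.7 / 2
  K_na <- cfg$K_G[["Na"]]
  resid <- function(bna) {
    m_na <- T_na - cap * bna
    m_ca <- T_ca - cap * (1 - bna) / 2
    bna / (1 - bna) - K_na * g_na * m_na / sqrt(g_ca * m_ca)
  }
  # bracket restricted to the physically feasible range (m_Na, m_Ca > 0)
  blo <- max(1e-9, 1 - 2 * T_ca / cap + 1e-9)
  bhi <- min(1 - 1e-9, T_na / cap - 1e-9)
  bna <- uniroot(resid, c(blo, bhi), tol = 1e-14)$root
  expect_equal(unname(eq$exchanger$beta[["Na"]]), bna, tolerance = 1e-6)
  expect_equal(eq$water$conc[["Na"]], T_na - cap * bna, tolerance = 1e-9)
  expect_equal(eq$water$conc[["Ca"]], T_ca - cap * (1 - bna) / 2,
               tolerance = 1e-9)
})

test_that("equilibration conserves total equivalents of every cation", {
  z <- c(Na = 1, K = 1, NH4 = 1, Ca = 2, Mg = 2, Sr = 2)
  set.seed(11)
  for (i in 1:10) {
    conc <- runif(6, 0, 3e-3)
    names(conc) <- names(z)
    w <- water_composition(Na = conc["Na"], K = conc["K"],
                           NH4 = conc["NH4"], Ca = conc["Ca"],
                           Mg = conc["Mg"], Sr = conc["Sr"],
                           Cl = sum(conc * z), CO3 = 1e-4, pH = 7.5)
    b <- runif(6); b <- b / sum(b); names(b) <- names(z)
    cap <- runif(1, 0.01, 0.4)
    ex <- exchanger_state(b, cap)
    eq <- equilibrate_exchange(w, ex, exchanger_config())
    tot_before <- w$conc[names(z)] + cap * b / z
    tot_after <- eq$water$conc[names(z)] +
      cap * eq$exchanger$beta / z
    expect_lt(max(abs(tot_after - tot_before) / (tot_before + 1e-15)),
              1e-10)
    expect_equal(sum(eq$exchanger$beta), 1, tolerance = 1e-12)
    expect_true(all(eq$exchanger$beta >= 0))
  }
})

test_that("exchanger inventory sums to capacity", {
  ex <- exchanger_state(cap_eq_L = 0.386)
  inv <- exchanger_inventory(ex)
  expect_equal(unname(inv[["Ca"]]), 0.386)
  expect_equal(sum(inv), 0.386, tolerance = 1e-12)
  b <- c(Na = 0.1, K = 0.05, NH4 = 0.15, Ca = 0.5, Mg = 0.15, Sr = 0.05)
  inv2 <- exchanger_inventory(exchanger_state(b, 0.2))
  expect_equal(unname(inv2), unname(0.2 * b), tolerance = 1e-14)
  expect_equal(sum(inv2), 0.2, tolerance = 1e-12)
})

test_that("injected ammonium displaces sorbed calcium and strontium", {
  cfg <- exchanger_config()
  base <- adjust_carbonate_for_charge_balance(
    water_composition(Na = 3, Ca = 1.05, Sr = 2.8e-3, Cl = 5,
                      pH = 7.6, unit = "mM"))
  # pre-load the exchanger in equilibrium with the base water
  ex <- equilibrate_exchange(base, exchanger_state(cap_eq_L = 0.386),
                             cfg)$exchanger
  spiked <- base
  spiked$conc["NH4"] <- 2e-3
  spiked$conc["CO3"] <- spiked$conc[["CO3"]] + 2e-3  # keep balance
  eq_ref <- equilibrate_exchange(base, ex, cfg)      # no NH4+
  eq_nh4 <- equilibrate_exchange(spiked, ex, cfg)    # with NH4+
  # NH4+ competition keeps more Ca2+ and Sr2+ in solution
  expect_gt(eq_nh4$water$conc[["Ca"]], 1.02 * eq_ref$water$conc[["Ca"]])
  expect_gt(eq_nh4$water$conc[["Sr"]], 1.02 * eq_ref$water$conc[["Sr"]])
  expect_gt(eq_nh4$exchanger$beta[["NH4"]], ex$beta[["NH4"]])
})

test_that("exchanger capacity converts CEC to pore-water equivalents", {
  cfg <- exchanger_config()  # 11.9 cmol/kg, 1.46 kg/L, porosity 0.45
  expect_equal(exchanger_capacity(cfg, 0.45),
               11.9 * 0.01 * 1.46 / 0.45, tolerance = 1e-12)
})
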