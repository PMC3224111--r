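test_that("the default grid reproduces the reported discretization", {
  st <- make_grid(column_config())
  expect_equal(st$n, 205)
  expect_equal(sum(st$sand), 60)
  expect_true(all(st$cap[st$sand] == 0))
  expect_true(all(st$cap[!st$sand] > 0))
  # grid pore volume: cross-section x 205 mm x porosity
  expect_equal(st$Vcell_L * st$n,
               pi * 3.8^2 * 20.5 * 0.45 / 1000, tolerance = 1e-12)
  # single-cell degenerate grid is accepted
  st1 <- make_grid(column_config(n_cells = 1, cell_cm = 20))
  expect_equal(st1$n, 1)
})

test_that("a conservative steady state passes through unchanged", {
  w0 <- equilibrate_with_calcite(default_waters()$initial)
  cfg <- mini_cfg()
  st <- make_grid(cfg, initial_water = w0, kin = inert_kinetics())
  c0 <- st$conc
  for (i in 1:5) st <- advance(st, w0, 400)
  # unchanged up to the one-time relaxation onto the stepper's own
  # activity-coefficient fixed point
  expect_lt(max(abs(st$conc - c0) / (c0 + 1e-15)), 1e-5)
})

test_that("with reactions off the scheme is exactly mass-conservative", {
  cfg <- mini_cfg(duration_days = 1)
  run <- run_column(cfg, kin = inert_kinetics())
  mb <- mass_balance(run)
  expect_lt(max(abs(mb$residual_rel)), 1e-10)
})

test_that("zero-enzyme, zero-CbY run with influent = initial water returns
          the influent at the outlet", {
  w0 <- equilibrate_with_calcite(default_waters()$initial)
  cfg <- mini_cfg(duration_days = 1.5)
  kin <- default_kinetics()
  kin$ure$E_total <- 0
  kin$nit$CbY <- 0
  run <- run_column(cfg, influent = w0, initial = w0, kin = kin)
  last <- run$effluent[nrow(run$effluent), ]
  # pre-outlet concentrations match the influent within the tiny drift
  # allowed by residual Sr-driven solid-solution supersaturation
  expect_equal(last$preoutlet_Ca, w0$conc[["Ca"]], tolerance = 0.01)
  expect_equal(last$preoutlet_Sr, w0$conc[["Sr"]], tolerance = 0.01)
  expect_equal(last$Cl, w0$conc[["Cl"]], tolerance = 1e-10)
})

test_that("a conservative tracer step breaks through at one pore volume", {
  w0 <- equilibrate_with_calcite(default_waters()$initial)
  step <- w0
  step$conc["Cl"] <- w0$conc[["Cl"]] + 1e-3
  step$conc["Na"] <- w0$conc[["Na"]] + 1e-3
  cfg <- column_config(length_cm = 20, sand_cm = 6, n_cells = 50,
                       cell_cm = 0.4, duration_days = 3,
                       sample_interval_days = 0.05)
  run <- run_column(cfg, influent = step, initial = w0,
                    kin = inert_kinetics(), exchange = FALSE)
  eff <- run$effluent
  mid <- (w0$conc[["Cl"]] + step$conc[["Cl"]]) / 2
  i <- which(eff$Cl >= mid)[1]
  t_mid <- (eff$time_days[i - 1] +
              (mid - eff$Cl[i - 1]) / (eff$Cl[i] - eff$Cl[i - 1]) *
                (eff$time_days[i] - eff$time_days[i - 1])) * 24
  residence_h <- hydraulic_metrics(cfg)$residence_time_h
  expect_equal(t_mid, residence_h, tolerance = 0.1)
})

test_that("element balances close on a fully reactive run", {
  run <- run_column(mini_cfg(duration_days = 2))
  mb <- mass_balance(run)
  expect_lt(max(abs(mb$residual_rel)), 1e-3)   # contract: 0.1 percent
  expect_lt(max(abs(mb$residual_rel)), 1e-8)   # achieved: near roundoff
})

test_that("halving the time step leaves effluent trajectories unchanged
          within one percent", {
  cfg1 <- mini_cfg(duration_days = 2)
  cfg2 <- mini_cfg(duration_days = 2, max_dt_s = 208)
  r1 <- run_column(cfg1)
  r2 <- run_column(cfg2)
  for (cc in c("Urea", "NH4", "Ca", "preoutlet_Ca")) {
    v1 <- approx(r1$effluent$time_days, r1$effluent[[cc]],
                 xout = seq(0.2, 1.9, by = 0.1))$y
    v2 <- approx(r2$effluent$time_days, r2$effluent[[cc]],
                 xout = seq(0.2, 1.9, by = 0.1))$y
    # relative to the trajectory scale (early-time values are ~0)
    expect_lt(max(abs(v1 - v2)) / max(abs(v1)), 0.01)
  }
})

test_that("Courant violations are rejected", {
  st <- make_grid(mini_cfg())
  w0 <- equilibrate_with_calcite(default_waters()$initial)
  expect_error(advance(st, w0, 1e6), "Courant")
})

test_that("outlet boundary degasses, precipitates and conserves carbon", {
  db <- thermo_db()
  # sample already below the imposed pCO2 and undersaturated: unchanged
  w_low <- water_composition(Na = 1, Cl = 1, CO3 = 5e-3, pH = 5.5,
                             unit = "mM")
  out_low <- outlet_boundary(w_low, 10^-3.3, db)
  expect_equal(out_low$conc, w_low$conc)
  expect_equal(attr(out_low, "outlet_ledger")$caco3_mol_L, 0)

  # the initial pore water (pCO2 ~ 10^-2.4 bar): degasses, pH rises,
  # calcite precipitates, and carbon is conserved exactly
  w0 <- equilibrate_with_calcite(default_waters()$initial, db)
  out <- outlet_boundary(w0, 10^-3.3, db)
  led <- attr(out, "outlet_ledger")
  expect_gt(out$pH, w0$pH)
  expect_gt(led$co2_degassed_mol_L, 0)
  expect_gt(led$caco3_mol_L, 0)
  c_lost <- w0$conc[["CO3"]] - out$conc[["CO3"]]
  expect_equal(c_lost, led$co2_degassed_mol_L + led$caco3_mol_L,
               tolerance = 1e-10)
  expect_equal(w0$conc[["Ca"]] - out$conc[["Ca"]], led$caco3_mol_L,
               tolerance = 1e-14)
  s_out <- speciate(out, db)
  expect_equal(unname(log10(s_out$pCO2_bar)), -3.3, tolerance = 1e-6)
  expect_lt(abs(s_out$SI_calcite), 1e-6)
  expect_lt(abs(s_out$charge_balance), 1e-9)
})

test_that("urea amendment produces ammonium breakthrough and extra calcite", {
  cfg <- mini_cfg(duration_days = 3)
  full <- run_column(cfg)
  eff <- full$effluent
  # NH4 appears only after the urea front arrives, then rises
  expect_lt(eff$NH4[1], 1e-8)
  expect_gt(tail(eff$NH4, 1), 1e-5)
  late <- tail(eff$NH4, 10)
  expect_true(all(diff(late) >= -1e-9))
  # enabling ureolysis never decreases the column CaCO3 inventory
  nou <- run_column(cfg, ureolysis = FALSE)
  expect_gt(column_minerals(full)[["caco3"]],
            column_minerals(nou)[["caco3"]])
})
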