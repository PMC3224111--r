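# Shared fixtures: scaled-down columns that keep the default geometry of
# the experiment (7.6 cm ID, 0.45 porosity) but shorter lengths, coarser
# cells and faster throughput so that multi-day behavior is exercised in
# seconds.

# small column for reactive tests: 15 cm, 30 cells, ~32 h residence scale
mini_cfg <- function(duration_days = 2, ...) {
  column_config(length_cm = 15, sand_cm = 2, n_cells = 30, cell_cm = 0.5,
                duration_days = duration_days,
                sample_interval_days = 0.1, ...)
}

# very small, fast column for calibration / synthetic tests: ~6 h residence
tiny_cfg <- function(duration_days = 2, ...) {
  column_config(length_cm = 10, sand_cm = 2, n_cells = 10, cell_cm = 1,
                flow_mL_min = 0.68, max_dt_s = 1440,
                duration_days = duration_days,
                sample_interval_days = 0.1, ...)
}

# kinetics bundle with all reactions off (conservative transport)
inert_kinetics <- function() {
  list(ure = ureolysis_params(E_total = 1e-30),
       nit = nitrification_params(CbY = 0),
       prec = precipitation_params(k_bulk = 0))
}

# a simple balanced Na-Ca-Cl-carbonate water
simple_water <- function(Na = 2, Ca = 1, CO3 = 1, pH = 7.8) {
  w <- water_composition(Na = Na, Ca = Ca, CO3 = CO3,
                         Cl = max(0, Na + 2 * Ca - 2 * CO3), pH = pH,
                         unit = "mM")
  adjust_carbonate_for_charge_balance(w)
}

# lazily computed, cached expensive runs shared across acceptance blocks
.accept_cache <- new.env(parent = emptyenv())
acceptance_runs <- function() {
  if (is.null(.accept_cache$runs)) {
    .accept_cache$runs <- list(
      full = run_column(column_config()),
      no_ureolysis = run_column(column_config(), ureolysis = FALSE),
      no_exchange = run_column(column_config(duration_days = 8),
                               exchange = FALSE)
    )
  }
  .accept_cache$runs
}
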