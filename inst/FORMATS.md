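# File formats

All tables are plain CSV with a header, decimal points, no thousands
separators; reports and run logs are JSON; configuration is YAML.

## Water composition CSV (`read_water_csv` / `write_water_csv`)

Header `component,value,unit`. One row per component
(`Na, Mg, Al, Si, K, Ca, Sr, Cl, NO3, SO4, CO3, NH4, Urea, O2`) plus a
`pH` row with an empty unit. Units `mol/L` or `mM`.

## Effluent series CSV (`write_effluent_csv`)

Columns: `time_days`; one column per component (mol/L, after
outlet-boundary processing); `pH`; `alkalinity_meq_L`; `tds_mg_L`;
`preoutlet_Ca`, `preoutlet_Sr`, `preoutlet_NH4`, `preoutlet_pH`
(in-column values before outlet processing); `outlet_caco3_mol_L`,
`outlet_co2_mol_L` (per-litre outlet ledger); `phase`.

## Mineral profile CSV (`write_profile_csv`)

Columns: `distance_cm`, `sand` (logical), `caco3_mol`, `srco3_mol`
(moles per 1 mm cell).

## Complex-conductivity spectrum CSV (`read_spectrum_csv`)

Header `frequency_hz,magnitude_s_per_m,phase_mrad` (phase in
milliradians). The reader appends `omega_rad_s`, `sigma_real`,
`sigma_imag`.

## Configuration YAML (`load_config`)

Nested blocks `column`, `thermo`, `kinetics` (`ureolysis`,
`nitrification`, `precipitation`), `exchange`, `waters`
(`initial`/`influent` blocks with a `unit` entry and a `pH` entry),
`toggles`, `synth`, `calibration`, plus top-level `schema_version` and
`seed`. Unknown keys are rejected with the offending path. An empty file
reproduces the default experiment. See `config_defaults` in the package
source for every key and default.

## Run log JSON (`write_run_log`)

`config_hash` (FNV-1a over the serialized merged configuration), `seed`,
`package`, `version`, `timestamp`, plus caller-supplied fields. Two runs
with identical configuration and seed produce identical hashes and
byte-identical CSV outputs.
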