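# Configuration loading, validation and run-log plumbing.

config_defaults <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    column = list(length_cm = 20, id_cm = 7.6, sand_cm = 6,
                  porosity = 0.45, flow_mL_min = 0.21, n_cells = 205L,
                  cell_cm = 0.1, max_dt_s = 416, courant = 0.8,
                  outlet_pco2_bar = 10^-3.3, duration_days = 15,
                  sample_interval_days = 0.125),
    thermo = list(),
    kinetics = list(
      ureolysis = list(k = 146.4, E_total = 1e-10, K_M = 3.21e-3,
                       K_P = 1.22e-2, logK1 = -6.121, logK2 = 7.896),
      nitrification = list(mu_max = 9.53e-6, CbY = 2e-5,
                           K_NH4 = 1.48e-5, K_O2 = 2.41e-5),
      precipitation = list(k_bulk = 4.2e-10)),
    exchange = list(cec_cmol_per_kg = 11.9, bulk_density_kg_per_L = 1.46,
                    selectivity = list(Na = 0.47, K = 0.47, NH4 = 0.6,
                                       Mg = 0.9, Sr = 1.05)),
    waters = list(initial = NULL, influent = NULL),
    toggles = list(ureolysis = TRUE, exchange = TRUE),
    synth = list(phase1_days = 13, phase2_days = 3, phase3_days = 15,
                 urea_mM = 10, washout_factor = 1.3, noise_rel = 0.02,
                 sample_interval_days = 0.25),
    calibration = list(free = c("E_total", "CEC"), n_starts = 2L,
                       maxit = 25L,
                       components = c("Urea", "NH4", "Ca", "Sr", "NO3"))
  )
}

merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  if (!is.list(override)) return(override)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ",
         paste0(path, unknown, collapse = ", "))
  prov <- character(0)
  for (nm in names(override)) {
    if (is.list(defaults[[nm]]) && length(defaults[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], override[[nm]],
                                     paste0(path, nm, "."))
    } else {
      defaults[[nm]] <- override[[nm]]
    }
  }
  defaults
}

# water block: named concentrations with explicit unit, e.g.
# waters: {influent: {unit: mM, Na: 3.03, ..., pH: 8.23}}
water_from_block <- function(block) {
  if (is.null(block)) return(NULL)
  unit <- block$unit %||% "mol/L"
  pH <- block$pH
  if (is.null(pH)) stop("water block requires a pH entry")
  conc <- block[setdiff(names(block), c("unit", "pH"))]
  do.call(water_composition, c(conc, list(pH = pH, unit = unit)))
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, merges it over the package defaults
#' (which encode the reported experiment: measured waters, 205-cell /
#' 1 mm grid, 416 s maximum step, 15-day duration, printed kinetic and
#' exchange constants), rejects unknown keys, and materializes the typed
#' configuration objects. An empty file therefore reproduces the default
#' experiment. Water blocks accept an explicit \code{unit} entry
#' (\code{mol/L} or \code{mM}).
#'
#' @param path YAML file path, or \code{NULL} for pure defaults.
#' @return A \code{run_config} list with elements \code{cfg}
#'   ([column_config()]), \code{db} ([thermo_db()]), \code{kin},
#'   \code{exch_cfg}, \code{waters}, \code{toggles}, \code{synth},
#'   \code{calibration}, \code{seed}, and \code{raw} (the merged plain
#'   list).
#' @export
load_config <- function(path = NULL) {
  raw <- config_defaults()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    raw <- merge_config(raw, user)
  }
  k <- raw$kinetics
  out <- list(
    cfg = do.call(column_config, raw$column),
    db = do.call(thermo_db, raw$thermo),
    kin = list(ure = do.call(ureolysis_params, k$ureolysis),
               nit = do.call(nitrification_params, k$nitrification),
               prec = do.call(precipitation_params, k$precipitation)),
    exch_cfg = exchanger_config(
      cec_cmol_kg = raw$exchange$cec_cmol_per_kg,
      bulk_density_kg_L = raw$exchange$bulk_density_kg_per_L,
      selectivity = unlist(raw$exchange$selectivity)),
    waters = list(initial = water_from_block(raw$waters$initial),
                  influent = water_from_block(raw$waters$influent)),
    toggles = raw$toggles,
    synth = raw$synth,
    calibration = raw$calibration,
    seed = raw$seed,
    raw = raw
  )
  class(out) <- "run_config"
  out
}

# small stable FNV-1a hash over the serialized config, for run logs
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write a machine-readable run log
#'
#' Records the configuration hash, seed, package version and timestamp of
#' a run as JSON, so that outputs can be traced to the exact
#' configuration that produced them.
#'
#' @param config a \code{run_config} (or any serializable configuration).
#' @param path output JSON path.
#' @param extra optional named list of additional fields.
#' @return \code{path}, invisibly.
#' @export
write_run_log <- function(config, path, extra = list()) {
  log <- c(list(
    config_hash = config_hash(if (inherits(config, "run_config"))
      config$raw else config),
    seed = if (inherits(config, "run_config")) config$seed else NA,
    package = "ureocol",
    version = as.character(utils::packageVersion("ureocol")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), extra)
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
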