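# Derived quantities: hydraulic/residence metrics, precipitate mass-balance
# arithmetic, effluent percent changes and stoichiometric ratios, and
# complex-conductivity data reduction.

MOLAR_MASS_CACO3 <- 100.087   # g/mol
CACO3_DENSITY <- 2.7          # g/cm3

#' Decompose complex conductivity into in-phase and quadrature parts
#'
#' sigma' = |sigma| cos(phi), sigma'' = |sigma| sin(phi), with the phase
#' stored in milliradians as is conventional for laboratory spectral
#' induced-polarization data and converted internally.
#'
#' @param magnitude conductivity magnitude |sigma|, S/m (vectorized).
#' @param phase_mrad phase shift, mrad.
#' @return A data frame with columns \code{sigma_real} and
#'   \code{sigma_imag} (S/m).
#' @examples
#' sigma_components(1.244e-2, 4.1)
#' @export
sigma_components <- function(magnitude, phase_mrad) {
  if (any(magnitude < 0)) stop("magnitude must be >= 0")
  phi <- phase_mrad / 1000
  data.frame(sigma_real = magnitude * cos(phi),
             sigma_imag = magnitude * sin(phi))
}

#' @rdname sigma_components
#' @param sigma_real,sigma_imag components to recompose (S/m).
#' @return \code{sigma_polar} returns a data frame with \code{magnitude}
#'   (S/m) and \code{phase_mrad}.
#' @export
sigma_polar <- function(sigma_real, sigma_imag) {
  data.frame(magnitude = sqrt(sigma_real^2 + sigma_imag^2),
             phase_mrad = atan2(sigma_imag, sigma_real) * 1000)
}

#' Percent change relative to a baseline
#'
#' @param before baseline value (nonzero).
#' @param after new value.
#' @return 100 * (after - before) / before.
#' @examples
#' percent_change(0.064, 0.0714)   # ~ +12 percent
#' @export
percent_change <- function(before, after) {
  if (any(before == 0)) stop("zero baseline in percent_change")
  100 * (after - before) / before
}

#' Hydraulic metrics of the column
#'
#' Pore volume, mean hydraulic residence time and pore volumes exchanged
#' per day, from the physical geometry (column length, not grid length),
#' porosity and flow rate.
#'
#' @param cfg a [column_config()].
#' @return A list: \code{pore_volume_mL}, \code{residence_time_h},
#'   \code{pore_volumes_per_day}.
#' @examples
#' hydraulic_metrics(column_config())   # ~32 h, ~0.74 PV/day
#' @export
hydraulic_metrics <- function(cfg = column_config()) {
  pv <- pi * (cfg$id_cm / 2)^2 * cfg$length_cm * cfg$porosity
  list(pore_volume_mL = pv,
       residence_time_h = pv / cfg$flow_mL_min / 60,
       pore_volumes_per_day = cfg$flow_mL_min * 1440 / pv)
}

#' Precipitate budget from throughput and mean calcium deficit
#'
#' mass = throughput x deficit x M(CaCO3); volume = mass / 2.7 g/cm3;
#' the pore-space percentage is computed against the pore volume of the
#' sediment section only (column length minus sand section), where the
#' native sediments reside.
#'
#' @param throughput_L solution volume pumped through the column, L.
#' @param mean_ca_deficit mean Ca2+ removed from solution, mol/L.
#' @param cfg a [column_config()].
#' @return A list: \code{mass_g}, \code{volume_cm3}, \code{pore_space_pct}.
#' @examples
#' precipitate_budget(4.8, 0.12e-3)   # ~0.058 g, ~0.021 cm3, ~0.007 pct
#' @export
precipitate_budget <- function(throughput_L, mean_ca_deficit,
                               cfg = column_config()) {
  stopifnot(throughput_L >= 0, mean_ca_deficit >= 0)
  mass <- throughput_L * mean_ca_deficit * MOLAR_MASS_CACO3
  vol <- mass / CACO3_DENSITY
  sed_pv <- pi * (cfg$id_cm / 2)^2 * (cfg$length_cm - cfg$sand_cm) *
    cfg$porosity
  list(mass_g = mass, volume_cm3 = vol,
       pore_space_pct = 100 * vol / sed_pv)
}

#' Steady-window effluent summaries relative to the influent
#'
#' Averages the effluent over the final fraction of the record (default
#' the last 20 percent) and reports percent urea hydrolyzed, percent
#' decreases of Ca2+, Sr2+ and alkalinity, and the stoichiometric ratio of
#' alkalinity decrease (eq/L) to Ca2+ decrease (mol/L) — which is ~2 when
#' the losses are carried by CaCO3 precipitation.
#'
#' @param series effluent data frame with columns \code{time_days},
#'   \code{Urea}, \code{Ca}, \code{Sr} (mol/L) and
#'   \code{alkalinity_meq_L}.
#' @param influent either a [water_composition()] (its alkalinity is
#'   computed by speciation) or a named list/vector with \code{Urea},
#'   \code{Ca}, \code{Sr} (mol/L) and \code{alkalinity_meq_L}.
#' @param window_frac fraction of the record (from the end) to average.
#' @param db a [thermo_db()] (used only if \code{influent} is a water).
#' @return A list: \code{urea_hydrolyzed_pct}, \code{ca_decrease_pct},
#'   \code{sr_decrease_pct}, \code{alk_decrease_pct},
#'   \code{alk_to_ca_ratio}.
#' @export
effluent_summaries <- function(series, influent, window_frac = 0.2,
                               db = thermo_db()) {
  stopifnot(is.data.frame(series), nrow(series) >= 1,
            window_frac > 0, window_frac <= 1)
  t1 <- max(series$time_days)
  t0 <- t1 - window_frac * (t1 - min(series$time_days))
  w <- series[series$time_days >= t0 - 1e-12, , drop = FALSE]
  if (nrow(w) == 0) stop("empty steady-state window")
  if (inherits(influent, "water_composition")) {
    s <- speciate(influent, db, mode = "fixed_pH")
    influent <- list(Urea = influent$conc[["Urea"]],
                     Ca = influent$conc[["Ca"]],
                     Sr = influent$conc[["Sr"]],
                     alkalinity_meq_L = s$alkalinity * 1000)
  }
  mean_of <- function(col) mean(w[[col]])
  influent <- lapply(influent, as.numeric)
  list(
    urea_hydrolyzed_pct = 100 * (influent$Urea - mean_of("Urea")) /
      influent$Urea,
    ca_decrease_pct = 100 * (influent$Ca - mean_of("Ca")) / influent$Ca,
    sr_decrease_pct = 100 * (influent$Sr - mean_of("Sr")) / influent$Sr,
    alk_decrease_pct = 100 * (influent$alkalinity_meq_L -
                                mean_of("alkalinity_meq_L")) /
      influent$alkalinity_meq_L,
    alk_to_ca_ratio = ((influent$alkalinity_meq_L -
                          mean_of("alkalinity_meq_L")) / 1000) /
      (influent$Ca - mean_of("Ca"))
  )
}

#' Check the linear relation between in-phase and fluid conductivity
#'
#' Ordinary least-squares fit of sigma' against sigma_w; a tight linear
#' relation (Archie-type behavior) indicates that bulk conduction is
#' dominated by the pore fluid.
#'
#' @param sigma_prime in-phase conductivity series, S/m.
#' @param sigma_w paired fluid conductivity series, S/m.
#' @return A list: \code{slope}, \code{intercept}, \code{r2}.
#' @export
archie_check <- function(sigma_prime, sigma_w) {
  if (length(sigma_prime) != length(sigma_w) || length(sigma_w) < 3)
    stop("need equal-length paired series with n >= 3")
  if (stats::sd(sigma_w) == 0 || stats::sd(sigma_prime) == 0)
    stop("degenerate (constant) series")
  fit <- stats::lm(sigma_prime ~ sigma_w)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared)
}

#' Read a complex-conductivity spectrum CSV
#'
#' Expected header: \code{frequency_hz,magnitude_s_per_m,phase_mrad}.
#'
#' @param path file path.
#' @return A data frame with the input columns plus \code{omega_rad_s},
#'   \code{sigma_real} and \code{sigma_imag}.
#' @export
read_spectrum_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frequency_hz", "magnitude_s_per_m", "phase_mrad")
  if (!all(need %in% names(d)))
    stop("spectrum CSV must have header ", paste(need, collapse = ","),
         ": ", path)
  comp <- sigma_components(d$magnitude_s_per_m, d$phase_mrad)
  cbind(d, omega_rad_s = 2 * pi * d$frequency_hz, comp)
}
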