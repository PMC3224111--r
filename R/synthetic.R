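# Synthetic effluent-record generator: forward-runs the column model over
# the three-phase experiment schedule (equilibration washout, a null
# nutrient phase, urea amendment) and adds seeded measurement noise, so the
# calibration and observables layers can be tested without any external
# data.

#' Specification of a synthetic effluent record
#'
#' The default schedule mirrors the laboratory experiment: ~13 days of
#' groundwater equilibration during which an initially elevated-TDS pore
#' water (salt dissolution / desorption) washes out, ~3 days of dilute
#' molasses amendment with no geochemical effect (phase bookkeeping only),
#' then 15 days of 10 mM urea amendment. Measurement noise is additive
#' Gaussian with a relative standard deviation per component.
#'
#' @param phase1_days,phase2_days,phase3_days phase durations.
#' @param urea_mM urea concentration of the amended influent.
#' @param washout_factor multiplier applied to the soluble components of
#'   the initial pore water to emulate the early washout transient.
#' @param noise_rel relative standard deviation of the measurement noise.
#' @param sample_interval_days effluent sampling interval.
#' @param seed random seed (mandatory).
#' @param truth named list of parameter overrides defining the generating
#'   truth (any of \code{E_total}, \code{CbY}, \code{k_bulk}, \code{CEC}).
#' @return A \code{synthetic_spec} object.
#' @export
synthetic_spec <- function(phase1_days = 13, phase2_days = 3,
                           phase3_days = 15, urea_mM = 10,
                           washout_factor = 1.3, noise_rel = 0.02,
                           sample_interval_days = 0.25, seed,
                           truth = list()) {
  if (missing(seed)) stop("a seed is mandatory for synthetic generation")
  stopifnot(phase1_days > 0, phase2_days > 0, phase3_days > 0,
            urea_mM >= 0, washout_factor >= 1, noise_rel >= 0,
            sample_interval_days > 0)
  structure(list(phase1_days = phase1_days, phase2_days = phase2_days,
                 phase3_days = phase3_days, urea_mM = urea_mM,
                 washout_factor = washout_factor, noise_rel = noise_rel,
                 sample_interval_days = sample_interval_days,
                 seed = seed, truth = truth),
            class = "synthetic_spec")
}

#' Boundary waters and phase schedule for a synthetic experiment
#'
#' Builds the influent schedule (equilibration, nutrient-null, urea
#' amendment) and the elevated-TDS initial pore water implied by a
#' [synthetic_spec()]. Exposed so that calibration runs can reuse exactly
#' the schedule a synthetic record was generated with.
#'
#' @param spec a [synthetic_spec()].
#' @param db a [thermo_db()].
#' @return A list: \code{initial} (washout pore water) and
#'   \code{schedule} (segments for [run_column()]).
#' @export
synthetic_schedule <- function(spec, db = thermo_db()) {
  waters <- default_waters()
  groundwater <- equilibrate_with_calcite(waters$initial, db)
  urea_w <- waters$urea_influent
  urea_w$conc["Urea"] <- spec$urea_mM / 1000
  urea_w <- adjust_carbonate_for_charge_balance(urea_w, db)

  # initial pore water: soluble components scaled up, carbonate re-balanced
  washout <- groundwater
  soluble <- c("Na", "K", "Ca", "Mg", "Sr", "Cl", "NO3", "SO4")
  washout$conc[soluble] <- washout$conc[soluble] * spec$washout_factor
  washout <- adjust_carbonate_for_charge_balance(washout, db)

  list(initial = washout,
       schedule = list(
         list(duration_days = spec$phase1_days, influent = groundwater,
              label = "I"),
         list(duration_days = spec$phase2_days, influent = groundwater,
              label = "II"),
         list(duration_days = spec$phase3_days, influent = urea_w,
              label = "III")))
}

#' Generate a synthetic effluent record
#'
#' Forward-runs the column model over the three-phase schedule at the
#' truth parameters, then adds seeded relative Gaussian noise to the
#' concentration-like columns. Both the noisy record and the noise-free
#' truth are returned; the generator is pure given (spec, seed).
#'
#' @param spec a [synthetic_spec()].
#' @param cfg a [column_config()] (its \code{duration_days} is ignored;
#'   the phase schedule defines the duration).
#' @param db a [thermo_db()].
#' @return A list: \code{noisy} and \code{truth} effluent data frames
#'   (with a \code{phase} column), and \code{truth_params}.
#' @export
generate_effluent <- function(spec, cfg = column_config(),
                              db = thermo_db()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cfg$sample_interval_days <- spec$sample_interval_days
  ap <- apply_params(unlist(spec$truth), default_kinetics(),
                     exchanger_config())
  sch <- synthetic_schedule(spec, db)
  run <- run_column(cfg, initial = sch$initial, db = db, kin = ap$kin,
                    exch_cfg = ap$exch_cfg, schedule = sch$schedule)
  truth <- run$effluent

  noisy <- truth
  set.seed(spec$seed)
  noise_cols <- setdiff(names(truth)[vapply(truth, is.numeric, logical(1))],
                        c("time_days", "pH"))
  for (cc in noise_cols)
    noisy[[cc]] <- truth[[cc]] *
      (1 + stats::rnorm(nrow(truth), sd = spec$noise_rel))

  list(noisy = noisy, truth = truth,
       truth_params = c(list(E_total = ap$kin$ure$E_total,
                             CbY = ap$kin$nit$CbY,
                             k_bulk = ap$kin$prec$k_bulk,
                             CEC = ap$exch_cfg$cec_cmol_kg)))
}

#' Apply the two known sampling artifacts to a series
#'
#' Emulates the measurement artifacts the laboratory record required
#' accounting for: post-sampling oxidation of a fixed fraction of NH4+ to
#' NO3- in collected effluent (equal molar transfer), and premature
#' calcium carbonate precipitation in the influent container, represented
#' as a fractional draw-down of the Ca column with the stoichiometric
#' 2 eq/mol alkalinity loss.
#'
#' @param series an effluent data frame.
#' @param nh4_oxidation_frac fraction of NH4+ converted to NO3- after
#'   sampling.
#' @param ca_drawdown_frac fractional loss of Ca2+ (with matching
#'   alkalinity loss).
#' @return The corrupted data frame.
#' @export
corrupt_with_artifacts <- function(series, nh4_oxidation_frac = 0,
                                   ca_drawdown_frac = 0) {
  stopifnot(nh4_oxidation_frac >= 0, nh4_oxidation_frac <= 1,
            ca_drawdown_frac >= 0, ca_drawdown_frac <= 1)
  out <- series
  if (nh4_oxidation_frac > 0) {
    moved <- nh4_oxidation_frac * series$NH4
    out$NH4 <- series$NH4 - moved
    out$NO3 <- series$NO3 + moved
  }
  if (ca_drawdown_frac > 0) {
    lost <- ca_drawdown_frac * series$Ca
    out$Ca <- series$Ca - lost
    if ("alkalinity_meq_L" %in% names(out))
      out$alkalinity_meq_L <- pmax(0, out$alkalinity_meq_L -
                                     2000 * lost)
  }
  out
}
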