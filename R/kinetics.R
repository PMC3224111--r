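# Kinetic rate laws: enzymatic ureolysis with pH-dependent urease activity
# and product inhibition, Monod nitrification, and TST precipitation of the
# ideal CaCO3-SrCO3 solid solution.

#' Ureolysis rate-law parameters
#'
#' Enzymatic urea hydrolysis, urea + H+ + 2 H2O -> 2 NH4+ + HCO3-, with a
#' Michaelis-Menten rate modulated by NH4+ product inhibition and by the
#' protonation state of the urease active site. The enzyme speciates as
#' EH2+ <-> EH + H+ (logK1) and E- + H+ <-> EH (logK2); only EH is active.
#'
#' @param k rate constant, mol urea / mol urease / s.
#' @param E_total total enzyme concentration [EH]+[EH2+]+[E-], mol/L
#'   (calibrated against the column data; default the calibrated value).
#' @param K_M half-saturation constant for urea, mol/L.
#' @param K_P NH4+ inhibition constant, mol/L.
#' @param logK1,logK2 log10 enzyme protonation constants.
#' @return A \code{ureolysis_params} object.
#' @export
ureolysis_params <- function(k = 146.4, E_total = 1e-10, K_M = 3.21e-3,
                             K_P = 1.22e-2, logK1 = -6.121, logK2 = 7.896) {
  stopifnot(k > 0, E_total >= 0, K_M > 0, K_P > 0,
            is.finite(logK1), is.finite(logK2))
  structure(list(k = k, E_total = E_total, K_M = K_M, K_P = K_P,
                 logK1 = logK1, logK2 = logK2),
            class = "ureolysis_params")
}

#' Nitrification rate-law parameters
#'
#' NH4+ + 2 O2 -> NO3- + H2O + 2 H+, with dual-Monod kinetics in NH4+ and
#' dissolved O2. \code{CbY} is the lumped biomass-over-yield factor
#' C_bio/Y_bio multiplying mu_max.
#'
#' The default \code{CbY} (2e-5 mol/L) is set so that one ~32 h column
#' residence produces the observed ~0.02 mM NO3- gain at near-air-saturated
#' O2 (1.9e-4 mol/L); see the methods vignette for why the originally
#' reported 1e-15 mol/L is retained only as a documented alternative.
#'
#' @param mu_max maximum specific rate, 1/s.
#' @param CbY lumped C_bio/Y_bio factor, mol/L.
#' @param K_NH4,K_O2 half-saturation constants, mol/L.
#' @return A \code{nitrification_params} object.
#' @export
nitrification_params <- function(mu_max = 9.53e-6, CbY = 2e-5,
                                 K_NH4 = 1.48e-5, K_O2 = 2.41e-5) {
  stopifnot(mu_max > 0, CbY >= 0, K_NH4 > 0, K_O2 > 0)
  structure(list(mu_max = mu_max, CbY = CbY, K_NH4 = K_NH4, K_O2 = K_O2),
            class = "nitrification_params")
}

#' Solid-solution precipitation parameters
#'
#' Transition-state-theory rate for the ideal CaCO3-SrCO3 solid solution:
#' the whole-column rate constant \code{k_bulk} (mol/s, calibrated as a bulk
#' average incorporating surface-area effects) is multiplied by (Q/K - 1),
#' positive when supersaturated, and distributed over grid cells in
#' proportion to their pore volume.
#'
#' @param k_bulk whole-column rate constant, mol/s (0 disables
#'   precipitation, e.g. for conservative-transport verification).
#' @return A \code{precipitation_params} object.
#' @export
precipitation_params <- function(k_bulk = 4.2e-10) {
  stopifnot(k_bulk >= 0)
  structure(list(k_bulk = k_bulk), class = "precipitation_params")
}

#' Fraction of urease in the catalytically active (EH) protonation state
#'
#' [EH]/E_total = 1 / (1 + h/K1 + 1/(K2 h)) with h the H+ activity, so the
#' active fraction is single-peaked in pH with its maximum at
#' pH = (pK1 + pK2)/2 (~7.0 for the default constants).
#'
#' @param pH pH (vectorized).
#' @param p [ureolysis_params()].
#' @return Active fraction in (0, 1].
#' @examples
#' enzyme_active_fraction(7)
#' @export
enzyme_active_fraction <- function(pH, p = ureolysis_params()) {
  h <- 10^(-pH)
  K1 <- 10^p$logK1
  K2 <- 10^p$logK2
  1 / (1 + h / K1 + 1 / (K2 * h))
}

#' Enzymatic ureolysis rate
#'
#' R = k E_total f_EH(pH) * urea/(K_M + urea) * K_P/(K_P + nh4),
#' in mol urea /L/s. Monotone increasing in urea, decreasing in NH4+, and
#' single-peaked in pH; bounded by k * E_total.
#'
#' @param urea urea concentration, mol/L.
#' @param nh4 NH4+ concentration, mol/L.
#' @param pH pH.
#' @param p [ureolysis_params()].
#' @return Rate, mol urea hydrolyzed /L/s (vectorized).
#' @examples
#' ureolysis_rate(10e-3, 0, 7)
#' @export
ureolysis_rate <- function(urea, nh4, pH, p = ureolysis_params()) {
  if (any(urea < 0) || any(nh4 < 0))
    stop("urea and nh4 concentrations must be >= 0")
  p$k * p$E_total * enzyme_active_fraction(pH, p) *
    urea / (p$K_M + urea) * p$K_P / (p$K_P + nh4)
}

#' Ureolysis rate via explicit enzyme speciation
#'
#' Computes [EH] by solving the linear mass-action system for
#' {EH, EH2+, E-} at fixed total enzyme, then applies the plain
#' Michaelis-Menten-with-inhibition law R = k [EH] urea/(K_M+urea)
#' K_P/(K_P+nh4). Mathematically equivalent to [ureolysis_rate()]; kept as
#' an independent route because reactive-transport codes implement the
#' enzyme as aqueous species.
#'
#' @inheritParams ureolysis_rate
#' @return Rate, mol urea /L/s.
#' @export
ureolysis_rate_speciated <- function(urea, nh4, pH, p = ureolysis_params()) {
  if (any(urea < 0) || any(nh4 < 0))
    stop("urea and nh4 concentrations must be >= 0")
  n <- max(length(urea), length(nh4), length(pH))
  urea <- rep_len(urea, n); nh4 <- rep_len(nh4, n); pH <- rep_len(pH, n)
  K1 <- 10^p$logK1
  K2 <- 10^p$logK2
  eh <- vapply(seq_len(n), function(i) {
    h <- 10^(-pH[i])
    # unknowns x = (EH, EH2+, E-):
    #   EH2+ = EH * h / K1 ; E- = EH / (K2 h) ; sum = E_total
    A <- rbind(c(h / K1, -1, 0),
               c(1 / (K2 * h), 0, -1),
               c(1, 1, 1))
    solve(A, c(0, 0, p$E_total))[1]
  }, numeric(1))
  p$k * eh * urea / (p$K_M + urea) * p$K_P / (p$K_P + nh4)
}

#' Nitrification rate (dual Monod)
#'
#' R = mu_max CbY * nh4/(K_NH4 + nh4) * o2/(K_O2 + o2), in mol NH4+ /L/s.
#' Stoichiometry per mol NH4+ oxidized: 2 mol O2 consumed, 1 mol NO3-
#' produced, 2 mol H+ released.
#'
#' @param nh4 NH4+ concentration, mol/L.
#' @param o2 dissolved O2, mol/L.
#' @param p [nitrification_params()].
#' @return Rate, mol NH4+ /L/s (vectorized).
#' @export
nitrification_rate <- function(nh4, o2, p = nitrification_params()) {
  if (any(nh4 < 0) || any(o2 < 0)) stop("nh4 and o2 must be >= 0")
  p$mu_max * p$CbY * nh4 / (p$K_NH4 + nh4) * o2 / (p$K_O2 + o2)
}

# Saturation ratio Q/K of the ideal CaCO3-SrCO3 solid solution. For an
# ideal solid solution (end-member activities = mole fractions) the total
# saturation ratio is the sum of the end-member ion-activity-product ratios;
# at equilibrium it equals 1 with solid composition x_i = Omega_i.
solid_solution_omega <- function(SI_calcite, SI_strontianite) {
  10^SI_calcite + 10^SI_strontianite
}

#' TST precipitation/dissolution rate of the CaCO3-SrCO3 solid solution
#'
#' Net rate = k_bulk * cell_volume_fraction * (Q/K - 1) with Q/K the ideal
#' solid-solution saturation ratio (sum of calcite and strontianite
#' ion-activity-product ratios). Precipitation (Q/K > 1) is partitioned
#' between CaCO3 and SrCO3 by the aqueous activity ratio a(Ca2+):a(Sr2+);
#' dissolution is partitioned by the solid mole fraction and is zero when
#' no mineral is present.
#'
#' @param spec a \code{speciation} (uses its SI values and Ca/Sr activities).
#' @param x Sr mole fraction of the existing solid (used to partition
#'   dissolution).
#' @param p [precipitation_params()].
#' @param cell_volume_fraction fraction of total pore volume represented by
#'   the cell (1 for a whole-column estimate).
#' @param mineral_mol available moles of c(caco3, srco3), used to suppress
#'   dissolution of absent solid.
#' @return Named numeric c(caco3, srco3), mol/s; positive = precipitation.
#' @export
precipitation_rate <- function(spec, x = 0, p = precipitation_params(),
                               cell_volume_fraction = 1,
                               mineral_mol = c(caco3 = 0, srco3 = 0)) {
  stopifnot(inherits(spec, "speciation"), x >= 0, x <= 1,
            cell_volume_fraction > 0, cell_volume_fraction <= 1)
  omega <- unname(solid_solution_omega(spec$SI_calcite,
                                       spec$SI_strontianite))
  net <- p$k_bulk * cell_volume_fraction * (omega - 1)
  if (net >= 0) {
    a_ca <- spec$act[["Ca"]]
    a_sr <- spec$act[["Sr"]]
    f_sr <- if (a_ca + a_sr > 0) a_sr / (a_ca + a_sr) else 0
    stats::setNames(c(net * (1 - f_sr), net * f_sr), c("caco3", "srco3"))
  } else {
    if (sum(mineral_mol) <= 0)
      return(c(caco3 = 0, srco3 = 0))
    stats::setNames(c(net * (1 - x), net * x), c("caco3", "srco3"))
  }
}
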