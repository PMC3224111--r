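# Equilibrium aqueous chemistry: activity model, carbonate-system speciation,
# charge balance, saturation indices, and the initial/boundary water adjustments.
#
# Internally all concentrations are mol/L; at the ionic strengths handled here
# (< 10 mM) molarity and molality are treated as interchangeable.

# Aqueous components carried as totals through transport and reaction.
UREOCOL_COMPONENTS <- c("Na", "Mg", "Al", "Si", "K", "Ca", "Sr", "Cl",
                        "NO3", "SO4", "CO3", "NH4", "Urea", "O2")

# charge and Debye-Hueckel ion-size parameter (Angstrom) per aqueous species.
# Al and Si are carried as inert uncharged totals (no aluminosilicate
# reactions; Si as H4SiO4, Al negligible at sub-micromolar levels).
.species_tab <- data.frame(
  species = c("H", "OH", "CO2", "HCO3", "CO3", "NH4", "NH3", "Na", "K",
              "Mg", "Ca", "Sr", "Cl", "NO3", "SO4", "Al", "Si", "Urea", "O2"),
  charge  = c(1, -1, 0, -1, -2, 1, 0, 1, 1, 2, 2, 2, -1, -1, -2, 0, 0, 0, 0),
  size_A  = c(9, 3.5, 0, 4, 4.5, 2.5, 0, 4, 3, 8, 6, 5, 3, 3, 4, 0, 0, 0, 0),
  stringsAsFactors = FALSE
)

# molar masses (g/mol) used by tds(); Si reported as SiO2.
.molar_mass <- c(H = 1.008, OH = 17.007, CO2 = 44.009, HCO3 = 61.017,
                 CO3 = 60.009, NH4 = 18.039, NH3 = 17.031, Na = 22.990,
                 K = 39.098, Mg = 24.305, Ca = 40.078, Sr = 87.62,
                 Cl = 35.453, NO3 = 62.004, SO4 = 96.06, Al = 26.982,
                 Si = 60.084, Urea = 60.056, O2 = 31.998)

#' Thermodynamic database for the carbonate system at 25 degrees C
#'
#' Holds the log10 equilibrium constants used by [speciate()] and the
#' extended Debye-Hueckel activity-model constants. Defaults are standard
#' 25 C values; any constant can be overridden, e.g. to explore sensitivity
#' to the choice of thermodynamic data.
#'
#' Conventions: \code{logK_1} is for CO2(aq) = H+ + HCO3-, \code{logK_2} for
#' HCO3- = H+ + CO3--, \code{logK_w} for water dissociation, \code{logK_H}
#' for CO2(g) = CO2(aq) (so a_CO2(aq) = 10^logK_H * pCO2),
#' \code{logK_nh4} for NH4+ = NH3(aq) + H+, and the two solubility products
#' are for MCO3(s) = M++ + CO3--.
#'
#' @param ... named overrides of any default constant.
#' @return An object of class \code{thermo_db} (a named list).
#' @examples
#' db <- thermo_db()
#' db$logKsp_calcite
#' thermo_db(logKsp_calcite = -8.42)$logKsp_calcite
#' @export
thermo_db <- function(...) {
  db <- list(
    logK_w = -14.00,
    logK_1 = -6.35,
    logK_2 = -10.33,
    logK_H = -1.47,
    logK_nh4 = -9.25,
    logKsp_calcite = -8.48,
    logKsp_strontianite = -9.27,
    DH_A = 0.5085,
    DH_B = 0.3281
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(db))
  if (length(unknown))
    stop("unknown thermodynamic constant(s): ", paste(unknown, collapse = ", "))
  db[names(over)] <- over
  stopifnot(all(vapply(db, is.finite, logical(1))))
  class(db) <- "thermo_db"
  db
}

#' Single-ion activity coefficient (extended Debye-Hueckel)
#'
#' log10(gamma) = -A z^2 sqrt(I) / (1 + B a sqrt(I)) for charged species,
#' with A, B the 25 C Debye-Hueckel constants and a the ion-size parameter
#' in Angstrom. Uncharged species are assigned gamma = 1 (the package's
#' neutral-species convention; no salting-out term).
#'
#' @param charge integer ionic charge (sign irrelevant).
#' @param size_param ion-size parameter in Angstrom.
#' @param ionic_strength ionic strength, mol/L (must be >= 0).
#' @param db a [thermo_db()].
#' @return dimensionless activity coefficient (vectorized over
#'   \code{ionic_strength}).
#' @examples
#' activity_coefficient(1, 4, 0.01)
#' activity_coefficient(0, 0, 0.5)  # neutral convention: 1
#' @export
activity_coefficient <- function(charge, size_param, ionic_strength,
                                 db = thermo_db()) {
  if (any(ionic_strength < 0)) stop("ionic strength must be >= 0")
  if (charge == 0) return(rep(1, length(ionic_strength)))
  sq <- sqrt(ionic_strength)
  10^(-db$DH_A * charge^2 * sq / (1 + db$DH_B * size_param * sq))
}

#' Water composition (total component concentrations plus pH)
#'
#' Container for the total dissolved concentration of every transported
#' component, plus pH and temperature. \code{CO3} is total dissolved
#' carbonate (CO2(aq) + HCO3- + CO3--), \code{NH4} total ammonium-N and
#' \code{Urea} molecular urea.
#'
#' @param ... named component concentrations (any of
#'   \code{Na, Mg, Al, Si, K, Ca, Sr, Cl, NO3, SO4, CO3, NH4, Urea, O2});
#'   unnamed components default to 0.
#' @param pH fixed pH of the water.
#' @param temp_C temperature (only 25 C chemistry is implemented; stored for
#'   provenance).
#' @param unit \code{"mol/L"} (default) or \code{"mM"}.
#' @return An object of class \code{water_composition}.
#' @examples
#' w <- water_composition(Na = 3, Cl = 2.6, Ca = 1, CO3 = 3.2, pH = 7.6,
#'                        unit = "mM")
#' w$conc["Ca"]
#' @export
water_composition <- function(..., pH = 7, temp_C = 25, unit = "mol/L") {
  given <- list(...)
  unknown <- setdiff(names(given), UREOCOL_COMPONENTS)
  if (length(unknown))
    stop("unknown component(s): ", paste(unknown, collapse = ", "))
  conc <- stats::setNames(numeric(length(UREOCOL_COMPONENTS)),
                          UREOCOL_COMPONENTS)
  if (length(given)) conc[names(given)] <- unlist(given)
  if (identical(unit, "mM")) conc <- conc / 1000
  else if (!identical(unit, "mol/L")) stop("unit must be 'mol/L' or 'mM'")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (pH <= 0 || pH >= 14) stop("pH must lie in (0, 14)")
  structure(list(conc = conc, pH = pH, temp_C = temp_C),
            class = "water_composition")
}

#' @export
print.water_composition <- function(x, ...) {
  cat("<water_composition>  pH", format(x$pH, digits = 4), "\n")
  nz <- x$conc[x$conc > 0]
  print(round(nz * 1000, 5))
  cat("(concentrations in mM)\n")
  invisible(x)
}

#' Measured column waters used as defaults
#'
#' The two measured water compositions that define the default simulation:
#' \code{initial} is the groundwater-equilibrated pore water sampled at the
#' column outlet just before urea amendment, and \code{urea_influent} the
#' urea-amended (10 mM) influent groundwater. Concentrations are the
#' measured totals; dissolved O2 defaults to 1.9e-4 mol/L (~6 mg/L, near
#' air saturation). Before use in a simulation the initial water is
#' re-equilibrated with calcite ([equilibrate_with_calcite()]) and the
#' influent charge-balanced ([adjust_carbonate_for_charge_balance()]),
#' mirroring how the boundary conditions were derived from the measurements.
#'
#' @return A list with elements \code{initial} and \code{urea_influent},
#'   both [water_composition()] objects.
#' @examples
#' default_waters()$urea_influent
#' @export
default_waters <- function() {
  list(
    initial = water_composition(
      Na = 3.05, Mg = 0.466, Al = 0.28e-3, Si = 0.334, K = 0.087,
      Ca = 1.05, Sr = 2.82e-3, Cl = 2.63, NO3 = 44.5e-3, SO4 = 0.213,
      CO3 = 3.23, NH4 = 0, Urea = 1e-7, O2 = 0.19,
      pH = 7.62, unit = "mM"),
    urea_influent = water_composition(
      Na = 3.03, Mg = 0.487, Al = 0.15e-3, Si = 0.343, K = 0.066,
      Ca = 1.00, Sr = 2.83e-3, Cl = 2.63, NO3 = 18.1e-3, SO4 = 0.206,
      CO3 = 4.21, NH4 = 0, Urea = 10, O2 = 0.19,
      pH = 8.23, unit = "mM")
  )
}

# ---------------------------------------------------------------------------
# Vectorized speciation engine. `tot` is an n x length(UREOCOL_COMPONENTS)
# matrix of totals (mol/L); `pH` a length-n vector, or NULL to solve each
# row's pH from electroneutrality. Used both by speciate() (n = 1) and by
# the column driver (n = number of cells).
# ---------------------------------------------------------------------------
spec_engine <- function(tot, pH = NULL, db = thermo_db(),
                        gamma_iter = 3, bisect_iter = 45, pH_guess = NULL) {
  n <- nrow(tot)
  K1 <- 10^db$logK_1; K2 <- 10^db$logK_2
  Kw <- 10^db$logK_w; Ka <- 10^db$logK_nh4

  gam_of <- function(I) {
    g <- matrix(1, n, nrow(.species_tab),
                dimnames = list(NULL, .species_tab$species))
    sq <- sqrt(I)
    for (j in seq_len(nrow(.species_tab))) {
      z <- .species_tab$charge[j]
      if (z != 0)
        g[, j] <- 10^(-db$DH_A * z^2 * sq /
                        (1 + db$DH_B * .species_tab$size_A[j] * sq))
    }
    g
  }

  # charge carried by the pH-independent free ions (totals)
  fixed_charge <- tot[, "Na"] + tot[, "K"] +
    2 * (tot[, "Mg"] + tot[, "Ca"] + tot[, "Sr"]) -
    tot[, "Cl"] - tot[, "NO3"] - 2 * tot[, "SO4"]

  # electroneutrality residual: only the pH-dependent species recomputed
  resid_at <- function(h, g) {
    r1 <- K1 / (h * g[, "HCO3"])
    r2 <- K2 * g[, "HCO3"] / (h * g[, "CO3"])
    co2 <- tot[, "CO3"] / (1 + r1 * (1 + r2))
    hco3 <- r1 * co2
    nh4 <- tot[, "NH4"] / (1 + Ka * g[, "NH4"] / h)
    fixed_charge + nh4 + h / g[, "H"] -
      hco3 * (1 + 2 * r2) - (Kw / h) / g[, "OH"]
  }

  # full species table given H+ activity and activity coefficients
  species_at <- function(h, g) {
    m <- matrix(0, n, nrow(.species_tab),
                dimnames = list(NULL, .species_tab$species))
    m[, "H"]  <- h / g[, "H"]
    m[, "OH"] <- (Kw / h) / g[, "OH"]
    r1 <- K1 / (h * g[, "HCO3"])          # [HCO3]/[CO2]
    r2 <- K2 * g[, "HCO3"] / (h * g[, "CO3"])  # [CO3]/[HCO3]
    co2 <- tot[, "CO3"] / (1 + r1 + r1 * r2)
    m[, "CO2"]  <- co2
    m[, "HCO3"] <- r1 * co2
    m[, "CO3"]  <- r2 * m[, "HCO3"]
    rn <- Ka * g[, "NH4"] / h             # [NH3]/[NH4+]
    m[, "NH4"] <- tot[, "NH4"] / (1 + rn)
    m[, "NH3"] <- tot[, "NH4"] - m[, "NH4"]
    for (cmp in c("Na", "K", "Mg", "Ca", "Sr", "Cl", "NO3", "SO4",
                  "Al", "Si", "Urea", "O2"))
      m[, cmp] <- tot[, cmp]
    m
  }

  fixed_pH <- !is.null(pH)
  if (fixed_pH) pH <- rep_len(pH, n)
  I <- rep(0, n)
  g <- gam_of(I)
  # activity coefficients are relaxed across iterations; the final pH
  # solve and the final species table share the same coefficients, so the
  # reported electroneutrality residual is the solver's own tolerance
  for (it in seq_len(gamma_iter + 1)) {
    if (fixed_pH) {
      h <- 10^(-pH)
    } else {
      # electroneutrality residual is strictly decreasing in pH: bisection,
      # optionally warm-started from a per-row guess
      lo <- rep(2, n); hi <- rep(13, n)
      if (!is.null(pH_guess)) {
        glo <- pmax(2, pH_guess - 0.75)
        ghi <- pmin(13, pH_guess + 0.75)
        ok <- resid_at(10^(-glo), g) > 0 & resid_at(10^(-ghi), g) < 0
        lo[ok] <- glo[ok]
        hi[ok] <- ghi[ok]
      }
      for (b in seq_len(bisect_iter)) {
        mid <- (lo + hi) / 2
        up <- resid_at(10^(-mid), g) > 0
        lo[up] <- mid[up]
        hi[!up] <- mid[!up]
      }
      pH <- (lo + hi) / 2
      h <- 10^(-pH)
    }
    m <- species_at(h, g)
    if (it > gamma_iter) break      # last pass: keep g used for the solve
    I <- 0.5 * as.vector(m %*% .species_tab$charge^2)
    g <- gam_of(I)
  }
  charge_resid <- function(m) as.vector(m %*% .species_tab$charge)
  act <- m * g
  a_co3 <- act[, "CO3"]
  list(
    pH = pH,
    I = I,
    molal = m,
    act = act,
    gamma = g,
    pCO2_bar = act[, "CO2"] / 10^db$logK_H,
    SI_calcite = log10(pmax(act[, "Ca"] * a_co3, .Machine$double.xmin)) -
      db$logKsp_calcite,
    SI_strontianite = log10(pmax(act[, "Sr"] * a_co3,
                                 .Machine$double.xmin)) -
      db$logKsp_strontianite,
    charge_balance = charge_resid(m),
    alkalinity = m[, "HCO3"] + 2 * m[, "CO3"] + m[, "OH"] - m[, "H"]
  )
}

#' Speciate a water composition
#'
#' Solves the mass-action / mole-balance equations of the carbonate and
#' ammonia systems with extended Debye-Hueckel activity corrections.
#' In \code{"fixed_pH"} mode the water's stated pH is imposed and the
#' charge-balance residual reported; in \code{"charge_balance"} mode pH is
#' solved so that the solution is electroneutral.
#'
#' @param comp a [water_composition()].
#' @param db a [thermo_db()].
#' @param mode \code{"fixed_pH"} or \code{"charge_balance"}.
#' @return An object of class \code{speciation}: a list with pH, ionic
#'   strength (mol/L), per-species molarities and activities, pCO2 (bar),
#'   calcite and strontianite saturation indices, the charge-balance
#'   residual (eq/L), carbonate alkalinity (eq/L) and TDS (mg/L).
#' @examples
#' w <- default_waters()$initial
#' s <- speciate(w)
#' log10(s$pCO2_bar)
#' @export
speciate <- function(comp, db = thermo_db(),
                     mode = c("fixed_pH", "charge_balance")) {
  mode <- match.arg(mode)
  stopifnot(inherits(comp, "water_composition"))
  tot <- matrix(comp$conc, nrow = 1,
                dimnames = list(NULL, names(comp$conc)))
  e <- spec_engine(tot, pH = if (mode == "fixed_pH") comp$pH else NULL,
                   db = db)
  out <- list(
    pH = e$pH, ionic_strength = e$I,
    molal = e$molal[1, ], act = e$act[1, ],
    pCO2_bar = e$pCO2_bar, SI_calcite = e$SI_calcite,
    SI_strontianite = e$SI_strontianite,
    charge_balance = e$charge_balance,
    alkalinity = e$alkalinity,
    totals = comp$conc
  )
  out$tds_mg_L <- sum(out$molal * .molar_mass[names(out$molal)]) * 1000
  class(out) <- "speciation"
  out
}

#' @export
print.speciation <- function(x, ...) {
  cat("<speciation>  pH", format(x$pH, digits = 4),
      " I =", format(x$ionic_strength, digits = 3), "mol/L\n",
      " pCO2 = 10^", format(log10(x$pCO2_bar), digits = 3), "bar;",
      " SI(calcite) =", format(x$SI_calcite, digits = 3), ";",
      " SI(strontianite) =", format(x$SI_strontianite, digits = 3), "\n",
      " charge imbalance =", format(x$charge_balance, digits = 3), "eq/L;",
      " TDS =", format(x$tds_mg_L, digits = 4), "mg/L\n")
  invisible(x)
}

#' Total dissolved solids of a speciated water
#'
#' Sum over all dissolved species of concentration times molar mass
#' (Si reported as SiO2), in mg/L. A proxy for fluid electrical
#' conductivity at the low ionic strengths of interest.
#'
#' @param spec a \code{speciation} object from [speciate()].
#' @return TDS in mg/L.
#' @export
tds <- function(spec) {
  stopifnot(inherits(spec, "speciation"))
  sum(spec$molal * .molar_mass[names(spec$molal)]) * 1000
}

#' Adjust total carbonate to achieve charge balance at fixed pH
#'
#' Returns the same water with its total dissolved carbonate replaced by
#' the value that zeroes the electroneutrality residual at the water's
#' measured pH - the procedure used to specify the column influent from
#' measured concentrations and pH.
#'
#' @param comp a [water_composition()] (pH fixed at its measured value).
#' @param db a [thermo_db()].
#' @return A [water_composition()] identical to \code{comp} except for
#'   \code{CO3}.
#' @examples
#' w <- adjust_carbonate_for_charge_balance(default_waters()$urea_influent)
#' speciate(w)$charge_balance   # ~0
#' @export
adjust_carbonate_for_charge_balance <- function(comp, db = thermo_db()) {
  stopifnot(inherits(comp, "water_composition"))
  resid_at <- function(tco3) {
    c2 <- comp
    c2$conc["CO3"] <- tco3
    speciate(c2, db, mode = "fixed_pH")$charge_balance
  }
  r0 <- resid_at(0)
  if (r0 < 0)
    stop("infeasible adjustment: water has an anion excess of ",
         format(-r0, digits = 3),
         " eq/L even with zero dissolved carbonate")
  hi <- 1
  while (resid_at(hi) > 0 && hi < 100) hi <- hi * 10
  root <- stats::uniroot(resid_at, c(0, hi), tol = 1e-14)$root
  comp$conc["CO3"] <- root
  comp
}

#' Equilibrate a water with calcite under charge balance
#'
#' Simultaneously solves SI(calcite) = 0 and electroneutrality by adjusting
#' pH and total dissolved carbonate, holding total Ca (and all other
#' component totals) fixed. This is how the initial column pore water is
#' derived from the outlet sample, whose elevated measured pH reflected
#' CO2 loss upon sampling.
#'
#' @param comp a [water_composition()].
#' @param db a [thermo_db()].
#' @return A [water_composition()] with adjusted \code{pH} and \code{CO3}.
#' @examples
#' w0 <- default_waters()$initial
#' w <- equilibrate_with_calcite(w0)
#' speciate(w)$SI_calcite   # ~0
#' @export
equilibrate_with_calcite <- function(comp, db = thermo_db()) {
  stopifnot(inherits(comp, "water_composition"))
  if (comp$conc["Ca"] <= 0) stop("water contains no calcium")
  si_at <- function(pH) {
    c2 <- comp
    c2$pH <- pH
    c2 <- adjust_carbonate_for_charge_balance(c2, db)
    speciate(c2, db)$SI_calcite
  }
  root <- stats::uniroot(si_at, c(5, 11), tol = 1e-10)$root
  comp$pH <- root
  comp <- adjust_carbonate_for_charge_balance(comp, db)
  # polish: report exactly consistent state
  s <- speciate(comp, db)
  if (abs(s$SI_calcite) > 1e-6)
    stop("calcite equilibration did not converge; residual SI = ",
         format(s$SI_calcite))
  comp
}

#' Read / write water compositions as CSV
#'
#' The on-disk format is a three-column CSV with header
#' \code{component,value,unit}; components are the transported totals plus
#' a \code{pH} row (empty unit). Units \code{mol/L} and \code{mM} are
#' accepted.
#'
#' @param path file path.
#' @param comp a [water_composition()] (for writing).
#' @param unit unit to write concentrations in.
#' @return \code{read_water_csv} returns a [water_composition()];
#'   \code{write_water_csv} returns \code{path} invisibly.
#' @export
read_water_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("component", "value", "unit") %in% names(d)))
    stop("water CSV must have header 'component,value,unit': ", path)
  conc <- list()
  pH <- NULL
  for (i in seq_len(nrow(d))) {
    cmp <- d$component[i]
    if (identical(cmp, "pH")) { pH <- d$value[i]; next }
    if (!cmp %in% UREOCOL_COMPONENTS)
      stop("unknown component '", cmp, "' at line ", i + 1, " of ", path)
    v <- d$value[i]
    if (identical(d$unit[i], "mM")) v <- v / 1000
    else if (!identical(d$unit[i], "mol/L"))
      stop("unit must be 'mol/L' or 'mM' at line ", i + 1, " of ", path)
    conc[[cmp]] <- v
  }
  if (is.null(pH)) stop("water CSV lacks a pH row: ", path)
  do.call(water_composition, c(conc, list(pH = pH)))
}

#' @rdname read_water_csv
#' @export
write_water_csv <- function(comp, path, unit = "mM") {
  stopifnot(inherits(comp, "water_composition"), unit %in% c("mM", "mol/L"))
  f <- if (unit == "mM") 1000 else 1
  d <- data.frame(component = c(names(comp$conc), "pH"),
                  value = c(comp$conc * f, comp$pH),
                  unit = c(rep(unit, length(comp$conc)), ""))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
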