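# Gapon-convention multi-cation exchanger (Na+, K+, NH4+, Ca2+, Mg2+, Sr2+)
# with Ca2+ as reference cation, equilibrated against the aqueous phase.
#
# Mass action is written per equivalent of exchanger charge:
#   beta_M / beta_Ca = K_M * a_M^(1/z_M) / a_Ca^(1/2)
# with beta the equivalent fraction, a the free-ion activity and K_Ca = 1.
# Given the per-cell TOTAL of each cation (aqueous + exchanged), the system
# reduces to one scalar unknown, the denominator D = sum_M K_M a_M^(1/z_M):
# each free concentration then has a closed form, and D is found by
# bisection. This makes the solve exactly conservative and fully
# vectorizable across grid cells.

EXCH_CATIONS <- c("Na", "K", "NH4", "Ca", "Mg", "Sr")
EXCH_Z <- c(Na = 1, K = 1, NH4 = 1, Ca = 2, Mg = 2, Sr = 2)

#' Cation-exchanger configuration
#'
#' Capacity and Gapon selectivity coefficients (Ca2+ reference, activity
#' basis in mol/L, written per equivalent). Selectivities are not part of
#' the reported record for this sediment (they were taken from site-
#' specific literature), so they are explicit configuration with
#' literature-style defaults; K+ uses the Na+ value by assumption.
#'
#' @param cec_cmol_kg cation exchange capacity, cmol(+)/kg sediment
#'   (default the calibrated 11.9).
#' @param bulk_density_kg_L dry bulk density of the packed medium, kg/L
#'   (default 1.46 = 2.65 g/cm3 grain density x (1 - 0.45 porosity)).
#' @param selectivity named Gapon selectivity coefficients for
#'   Na, K, NH4, Mg, Sr relative to Ca (= 1).
#' @return An \code{exchanger_config} object.
#' @export
exchanger_config <- function(cec_cmol_kg = 11.9, bulk_density_kg_L = 1.46,
                             selectivity = c(Na = 0.47, K = 0.47,
                                             NH4 = 0.6, Mg = 0.9,
                                             Sr = 1.05)) {
  stopifnot(cec_cmol_kg >= 0, bulk_density_kg_L > 0)
  need <- setdiff(EXCH_CATIONS, c("Ca", names(selectivity)))
  if (length(need))
    stop("selectivity must name: ", paste(need, collapse = ", "))
  if (any(selectivity <= 0)) stop("selectivities must be > 0")
  kg <- c(selectivity[c("Na", "K", "NH4")], Ca = 1,
          selectivity[c("Mg", "Sr")])
  structure(list(cec_cmol_kg = cec_cmol_kg,
                 bulk_density_kg_L = bulk_density_kg_L,
                 K_G = kg[EXCH_CATIONS]),
            class = "exchanger_config")
}

#' Exchanger capacity per litre of pore water
#'
#' CEC (cmol+/kg) x bulk density (kg medium/L medium) / porosity
#' (L water/L medium), in eq per litre of pore water.
#'
#' @param cfg an [exchanger_config()].
#' @param porosity porosity of the medium.
#' @return Capacity, eq/L pore water.
#' @export
exchanger_capacity <- function(cfg, porosity = 0.45) {
  stopifnot(porosity > 0, porosity <= 1)
  cfg$cec_cmol_kg * 0.01 * cfg$bulk_density_kg_L / porosity
}

#' Exchanger state (equivalent fractions)
#'
#' @param beta named equivalent fractions for Na, K, NH4, Ca, Mg, Sr
#'   (must be >= 0 and sum to 1 when capacity > 0).
#' @param cap_eq_L exchanger capacity, eq per litre of pore water.
#' @return An \code{exchanger_state} object.
#' @export
exchanger_state <- function(beta = c(Na = 0, K = 0, NH4 = 0, Ca = 1,
                                     Mg = 0, Sr = 0),
                            cap_eq_L = 0.386) {
  beta <- beta[EXCH_CATIONS]
  stopifnot(all(beta >= 0), cap_eq_L >= 0)
  if (cap_eq_L > 0 && abs(sum(beta) - 1) > 1e-8)
    stop("equivalent fractions must sum to 1")
  structure(list(beta = beta, cap_eq_L = cap_eq_L),
            class = "exchanger_state")
}

# Core solver. tot: n x 6 matrix of total cation (aqueous free + exchanged)
# in mol/L pore water; g: n x 6 activity factors (gamma x free-ion fraction,
# so a_M = g * m_total_aq); cap: length-n capacities (eq/L). Returns aqueous
# totals and equivalent fractions. Rows with cap = 0 pass through unchanged.
# logD_guess optionally warm-starts the bisection bracket per row.
gapon_solve <- function(tot, g, cap, K_G, iter = 60, logD_guess = NULL) {
  n <- nrow(tot)
  z <- EXCH_Z[colnames(tot)]
  Kg <- K_G[colnames(tot)]
  aq <- tot
  beta <- matrix(0, n, ncol(tot), dimnames = dimnames(tot))
  act <- cap > 0
  if (!any(act)) return(list(aq = aq, beta = beta, logD = rep(NA_real_, n)))

  na <- sum(act)
  Tm <- tot[act, , drop = FALSE]
  capa <- cap[act]
  # hoisted coefficients: z = 1: m = T / (1 + c1/D), term = kg1 * m
  #                       z = 2: u = (-b0/D + sqrt((b0/D)^2 + 4T))/2,
  #                              m = u^2, term = kg2 * u
  c1 <- kg1 <- b0 <- kg2 <- vector("list", length(z))
  for (j in seq_along(z)) {
    if (z[j] == 1) {
      kg1[[j]] <- Kg[j] * g[act, j]
      c1[[j]] <- capa * kg1[[j]]
    } else {
      kg2[[j]] <- Kg[j] * sqrt(g[act, j])
      b0[[j]] <- (capa / 2) * kg2[[j]]
    }
  }
  s_minus_D <- function(D) {
    s <- -D
    for (j in seq_along(z)) {
      if (z[j] == 1) s <- s + kg1[[j]] * Tm[, j] / (1 + c1[[j]] / D)
      else {
        b <- b0[[j]] / D
        s <- s + kg2[[j]] * (-b + sqrt(b * b + 4 * Tm[, j])) / 2
      }
    }
    s
  }
  # default bracket in log10(D): s - D > 0 for D small, <= 0 at the
  # no-exchange cap sum_j K_j (g_j T_j)^(1/z_j)
  cap_s <- 0
  for (j in seq_along(z))
    cap_s <- cap_s + if (z[j] == 1) kg1[[j]] * Tm[, j] else
      kg2[[j]] * sqrt(Tm[, j])
  lo <- log10(pmax(cap_s, 1e-12)) - 14
  hi <- log10(pmax(cap_s, 1e-12)) + 0.001
  nit <- iter
  if (!is.null(logD_guess) && all(is.finite(logD_guess[act]))) {
    glo <- logD_guess[act] - 0.15
    ghi <- logD_guess[act] + 0.15
    ok <- s_minus_D(10^glo) > 0 & s_minus_D(10^ghi) < 0
    lo[ok] <- glo[ok]
    hi[ok] <- ghi[ok]
    if (all(ok)) nit <- 30L
  }
  for (b in seq_len(nit)) {
    mid <- (lo + hi) / 2
    up <- s_minus_D(10^mid) > 0
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  logD <- (lo + hi) / 2
  D <- 10^logD
  for (j in seq_along(z)) {
    if (z[j] == 1) {
      m <- Tm[, j] / (1 + c1[[j]] / D)
      term <- kg1[[j]] * m
    } else {
      b <- b0[[j]] / D
      u <- (-b + sqrt(b * b + 4 * Tm[, j])) / 2
      m <- u * u
      term <- kg2[[j]] * u
    }
    aq[act, j] <- m
    beta[act, j] <- term / D
  }
  # renormalize the tiny bisection residual so fractions sum exactly to 1
  bs <- rowSums(beta[act, , drop = FALSE])
  beta[act, ] <- beta[act, , drop = FALSE] / bs
  out_logD <- rep(NA_real_, n)
  out_logD[act] <- logD
  list(aq = aq, beta = beta, logD = out_logD)
}

# equivalent fractions in equilibrium with a bath of fixed activities
# (used to initialize the exchanger from the initial pore water)
gapon_fractions_from_activities <- function(a, K_G) {
  z <- EXCH_Z[names(a)]
  w <- K_G[names(a)] * a^(1 / z)
  w / sum(w)
}

#' Equilibrate a water with a cation exchanger
#'
#' Solves the Gapon mass-action relations for all six cations against the
#' water, conserving the total (aqueous + exchanged) equivalents of each
#' cation and renormalizing the exchanger fractions to 1. The water's
#' activity coefficients and NH4+/NH3 partitioning are taken from a
#' fixed-pH speciation of the input.
#'
#' @param comp a [water_composition()].
#' @param ex an [exchanger_state()].
#' @param cfg an [exchanger_config()] (provides selectivities).
#' @param db a [thermo_db()].
#' @return A list with elements \code{water} (aqueous totals after
#'   equilibration) and \code{exchanger} (updated state).
#' @examples
#' w <- default_waters()$initial
#' ex <- exchanger_state(cap_eq_L = 0.386)
#' eq <- equilibrate_exchange(w, ex, exchanger_config())
#' sum(eq$exchanger$beta)   # 1
#' @export
equilibrate_exchange <- function(comp, ex, cfg = exchanger_config(),
                                 db = thermo_db()) {
  stopifnot(inherits(comp, "water_composition"),
            inherits(ex, "exchanger_state"))
  s <- speciate(comp, db, mode = "fixed_pH")
  # activity factors a_M = g * m_total: free-ion gamma times free fraction
  g <- matrix(1, 1, length(EXCH_CATIONS),
              dimnames = list(NULL, EXCH_CATIONS))
  for (cat in EXCH_CATIONS) {
    gam <- s$act[[cat]] / max(s$molal[[cat]], .Machine$double.xmin)
    if (!is.finite(gam) || s$molal[[cat]] == 0)
      gam <- activity_coefficient(EXCH_Z[[cat]],
                                  .species_tab$size_A[.species_tab$species == cat],
                                  s$ionic_strength, db)
    free_frac <- if (cat == "NH4" && comp$conc[["NH4"]] > 0)
      s$molal[["NH4"]] / comp$conc[["NH4"]] else 1
    g[1, cat] <- gam * free_frac
  }
  tot <- matrix(comp$conc[EXCH_CATIONS] +
                  ex$cap_eq_L * ex$beta[EXCH_CATIONS] / EXCH_Z,
                nrow = 1, dimnames = list(NULL, EXCH_CATIONS))
  sol <- gapon_solve(tot, g, ex$cap_eq_L, cfg$K_G)
  out <- comp
  out$conc[EXCH_CATIONS] <- sol$aq[1, ]
  list(water = out,
       exchanger = exchanger_state(sol$beta[1, ], ex$cap_eq_L))
}

#' Exchanger inventory
#'
#' Equivalents held per cation; sums to the capacity.
#'
#' @param ex an [exchanger_state()].
#' @param cfg an [exchanger_config()] (unused for the per-litre inventory;
#'   kept for interface symmetry).
#' @return Named equivalents per litre of pore water.
#' @export
exchanger_inventory <- function(ex, cfg = exchanger_config()) {
  stopifnot(inherits(ex, "exchanger_state"))
  ex$cap_eq_L * ex$beta
}
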