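---
title: "Modeling ureolytically driven calcite precipitation in a sediment column"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ureolytically driven calcite precipitation in a sediment column}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ureocol)
```

## The system

`ureocol` models a laboratory flow-through column packed with natural
alluvial sediment over a 6 cm coarse-sand inlet section, fed with
groundwater at a constant 0.21 mL/min (about 0.7 pore volumes per day at
45 % porosity, a ~32 h residence time). When the influent is amended with
10 mM urea, urease-bearing microbes hydrolyze part of it,

$$\mathrm{H_2N(CO)NH_2 + H^+ + 2\,H_2O \rightarrow 2\,NH_4^+ + HCO_3^-},$$

raising alkalinity and driving precipitation of calcium carbonate — the
basis of a proposed strategy for immobilizing divalent radionuclides
(e.g. $^{90}$Sr) by co-precipitation. The released NH$_4^+$ also displaces
sorbed Ca$^{2+}$ and Sr$^{2+}$ from the sediment exchanger, producing the
characteristic transient effluent peaks of both cations. The package
implements the full chain — speciation, kinetics, exchange, transport,
observables, calibration, synthetic data — as testable units.

## Aqueous chemistry

Speciation covers the carbonate system (CO$_2$(aq), HCO$_3^-$,
CO$_3^{2-}$), the ammonium/ammonia couple, and water self-ionization,
with all other components carried as free ions. Activity coefficients use
the extended Debye–Hückel law with tabulated ion-size parameters
($A = 0.5085$, $B = 0.3281$ at 25 °C); neutral species are assigned
$\gamma = 1$. This is adequate for the < 10 mM ionic strengths involved;
no Pitzer terms, ion pairs, or temperature dependence are included.
Equilibrium constants default to standard 25 °C values
(log $K_1 = -6.35$, log $K_2 = -10.33$, log $K_w = -14$, Henry
log $K_H = -1.47$, log $K_{sp}$ calcite $-8.48$, strontianite $-9.27$,
NH$_4^+$ p$K_a$ 9.25); all are overridable through `thermo_db()`, and
checks against reported CO$_2$ pressures are interpreted with a
0.1–0.2 log-unit allowance for thermodynamic-database drift.

In `"charge_balance"` mode the solver finds pH by bisection on the
electroneutrality residual, which is strictly monotone in pH; the same
vectorized engine solves all 205 grid cells simultaneously, which is what
makes a pure-R reactive-transport driver fast enough.

Two measured-water adjustments mirror how the experiment's boundary
conditions were derived:

* `adjust_carbonate_for_charge_balance()` keeps the measured pH and ion
  totals and solves total carbonate so the water is electroneutral (used
  for the influent, whose reservoir had partially re-equilibrated with
  the atmosphere). For the urea-phase influent this yields ΣCO$_3$
  ≈ 3.0 mM — consistent with the reported CO$_2$ pressure of
  10$^{-3.01}$ bar, although a higher tabulated ΣCO$_3$ value
  accompanies it in the source description; the procedure, not the
  tabulated number, is authoritative here.
* `equilibrate_with_calcite()` solves SI$_{calcite}$ = 0 and charge
  balance simultaneously for (pH, ΣCO$_3$) at fixed total Ca (two
  equations, two unknowns) — used for the initial pore water, whose
  elevated measured pH reflected CO$_2$ loss on sampling.

## Kinetics

**Ureolysis.** Michaelis–Menten in urea ($K_M = 3.21\times10^{-3}$ M)
with NH$_4^+$ product inhibition ($K_P = 1.22\times10^{-2}$ M) and a
pH-dependent active-enzyme fraction from the two urease protonation
equilibria (log $K_1 = -6.121$, log $K_2 = 7.896$), which peaks at
pH $= ($p$K_1+$p$K_2)/2 \approx 7.0$. The rate constant is
$k = 146.4$ mol urea mol$_{urease}^{-1}$ s$^{-1}$ and the total enzyme
concentration $E_{tot} = 10^{-10}$ M (a calibrated, not measured,
quantity). The equivalent enzyme-speciation formulation
(`ureolysis_rate_speciated()`) solves the linear mass-action system for
{EH, EH$_2^+$, E$^-$} and is verified to agree with the closed form to
$10^{-12}$ relative — the same equivalence reactive-transport codes rely
on when they implement the enzyme as aqueous species.

**Nitrification.** Dual-Monod in NH$_4^+$ ($K = 1.48\times10^{-5}$ M) and
O$_2$ ($K = 2.41\times10^{-5}$ M) at
$\mu_{max} = 9.53\times10^{-6}$ s$^{-1}$, with 2 O$_2$ consumed and 2
H$^+$ released per NH$_4^+$. Two of the reported constants are internally
inconsistent and were re-derived once: a lumped biomass term of
$10^{-15}$ M would give rates around $10^{-20}$ M/s, twelve orders too
small to produce the observed ~0.02 mM NO$_3^-$ gain, and the stated
inlet O$_2$ of $2\times10^{-3}$ M contradicts its own ~6 mg/L gloss.
The defaults therefore use O$_2$ = $1.9\times10^{-4}$ M (6 mg/L) and
$C_{bio}/Y_{bio} = 2\times10^{-5}$ M, the value for which one ~32 h
residence produces the observed NO$_3^-$ gain; both remain ordinary
configuration values.

**Precipitation.** The CaCO$_3$–SrCO$_3$ ideal solid solution
precipitates under a transition-state-theory rate,
$R = k_{bulk}\,(Q/K - 1)$, with the whole-column
$k_{bulk} = 4.2\times10^{-10}$ mol/s (a calibrated bulk value absorbing
surface-area effects) distributed over cells in proportion to pore
volume. For an ideal solid solution with end-member activities equal to
mole fractions, the saturation ratio is the sum of the end-member
ion-activity-product ratios, $\Omega = \Omega_{cal} + \Omega_{str}$,
which passes through 1 exactly at equilibrium. Precipitated mass is
partitioned between the end members by the aqueous
a(Ca$^{2+}$):a(Sr$^{2+}$) ratio (the formalism fixes only ideality, not
the partition; this choice makes the Sr mole fraction a diagnostic
output); dissolution follows the solid's mole fraction and is capped by
the mineral present. No nucleation model is included.

## Cation exchange

Exchange of Na$^+$, K$^+$, NH$_4^+$, Ca$^{2+}$, Mg$^{2+}$, Sr$^{2+}$
follows the Gapon convention written per equivalent with Ca$^{2+}$ as
reference:
$\beta_M/\beta_{Ca} = K_M\, a_M^{1/z_M} / a_{Ca}^{1/2}$.
The capacity is the calibrated 11.9 cmol(+)/kg; with a bulk density of
1.46 kg/L (2.65 g/cm$^3$ grains at 45 % porosity — the density itself is
not part of the reported record) that is ~0.39 eq per litre of pore
water, so the exchanger strongly buffers the major cations. Selectivity
coefficients for this sediment were taken from site-specific literature
that the package cannot reproduce; they are explicit configuration with
defaults (Na 0.47, K 0.47 — equal to Na by the original assumption —
NH$_4$ 0.6, Mg 0.9, Sr 1.05 on a mol/L activity basis) chosen once as
order-of-magnitude literature values. All synthetic-data and calibration
tests treat them as the known truth set rather than as estimates of the
real sediment.

Numerically, the equilibration exploits a single-variable reduction:
given each cation's total (aqueous + exchanged), every free
concentration has a closed form once the Gapon denominator
$D = \sum_M K_M a_M^{1/z_M}$ is known ($z=1$ gives a linear relation,
$z=2$ a quadratic in $\sqrt{m}$), and $D$ itself satisfies a monotone
scalar equation solved by bisection — vectorized across all cells and
exactly conservative by construction. The per-equivalent writing of the
reference-cation convention is a documented choice; codes using a
per-mole writing will need rescaled selectivities.

## Transport and coupling

First-order explicit upwind advection on 205 cells of 1 mm (the
reported discretization; note it spans 20.5 cm against the 20 cm
physical column — derived hydraulic observables use 20 cm), maximum step
416 s (~0.8 of the Courant limit), fixed 0.21 mL/min influx. No explicit
dispersion term is included — none is part of the reported setup — so
first-order numerical dispersion stands in for physical dispersion;
temporal convergence is verified by step-halving. Transport and
chemistry are coupled sequential-iteratively: within each step the
reaction increment is re-evaluated against the updated state and the
exchanger re-equilibrated until the maximum relative component change
falls below $10^{-6}$ (at most 20 iterations) — the sharp NH$_4^+$ and
NO$_3^-$ fronts are not reproduced by a single-pass splitting. Reaction
increments are positivity-limited per cell so no concentration can be
driven negative. Element (Ca, Sr, C, N, Cl) balances over any run close
to near machine precision and are asserted to 0.1 %.

The simulation clock starts at urea injection; the earlier equilibration
and nutrient phases exist only in the synthetic-data generator. The
column outlet applies a one-way fixed-pCO$_2$ (10$^{-3.3}$ bar) boundary
to each effluent sample: the sample degasses, pH rises, and if it
becomes supersaturated calcite precipitates down to equilibrium, the
"2 HCO$_3^-$ + Ca$^{2+}$ → CaCO$_3$ + CO$_2$" effect. This
equilibrium end-member removes more Ca from the reported effluent than a
kinetically limited outlet would (the measured effluent remained
supersaturated by about one SI unit), so the effluent table also carries
the pre-outlet in-column concentrations (`preoutlet_*` columns), which
are the right place to look for the exchange-driven Ca/Sr peaks; carbon
is conserved exactly across the boundary (degassed CO$_2$ + outlet
CaCO$_3$ = carbon lost from solution).

## Calibration

The four historically calibrated parameters ($E_{tot}$,
$C_{bio}/Y_{bio}$, $k_{bulk}$, CEC) are fit by weighted least squares
against effluent time series: Nelder–Mead in log$_{10}$ space (the
parameters span orders of magnitude) with a quadratic out-of-bounds
penalty, multi-start from seeded log-uniform draws, inverse-variance
default weights, and linear time interpolation of the simulation onto
the observed samples. Starts deliberately exclude the package defaults
so that recovering a truth equal to the defaults is a genuine
optimization. A perturbation diagnostic (±25 % per parameter, scaled by
the weighted data sum of squares) flags unidentifiable parameters. No
attempt is made to reproduce the original calibration tool's exact
fitted values; its weighting and convergence settings are not public.

## Synthetic data

`generate_effluent()` forward-runs the column over the three-phase
schedule — ~13 d equilibration during which an elevated-TDS initial pore
water (soluble components scaled by 1.3, carbonate re-balanced; a
descriptive stand-in for salt dissolution and desorption, which the
record attributes but does not model) washes out, ~3 d of nutrient
amendment with no geochemical effect (phase bookkeeping only), then 15 d
of 10 mM urea — and adds seeded additive Gaussian noise with 2 %
relative standard deviation per concentration column. The truth record
always accompanies the noisy one, and the generator is pure given
(spec, seed). `corrupt_with_artifacts()` optionally applies the two
known sampling artifacts (post-sampling NH$_4^+$ oxidation;
influent-container Ca/alkalinity draw-down) for robustness experiments.
What passing tests on these records demonstrate is internal consistency
of the chain — generator, model, calibrator — not fidelity to any real
sediment: the generator shares the forward model's structural
assumptions (no dispersion, equilibrium exchange, ideal solid solution)
and its noise is uncorrelated, unlike real analytical drift.

## Numerical and design notes

* pH bisection brackets [2, 13], warm-started per cell between steps;
  exchanger bisection runs in log $D$ with a warm-started bracket.
  Activity coefficients are relaxed over the solver iterations (ionic
  strength changes little per step).
* Degenerate inputs: zero-concentration cations yield zero exchanger
  fractions analytically; dissolution of absent minerals is suppressed;
  a water whose anion excess cannot be balanced by carbonate raises an
  explicit infeasibility error.
* The urea-amended simulation hydrolyzes less urea (~4 %) than the ~13 %
  observed in the laboratory column: with the reported enzyme
  parameters the in-column pH the model maintains sits below the
  laboratory effluent's 8.5, and no attempt was made to re-tune
  $E_{tot}$ — the package's model-contrast claims (e.g. the ≥3-fold
  ureolysis enhancement of column calcite) are ratios between model
  variants and are insensitive to this.
* Problem sizes in the test-suite are scaled-down choices of this
  package: step-halving convergence on a 2-day window, calibration
  recovery on a 10-cell mini-column with ~6 h residence and a
  0.3/0.2/2.5-day phase schedule, while the acceptance checks run the
  full 15-day, 205-cell configuration.

## Known limitations

1D advection only (no dispersion term, no 2D/3D, no unsaturated flow or
permeability feedback); equilibrium exchange (no kinetic sorption, no
surface complexation); one mineral pair, no nucleation, no silicate
reactions; 25 °C only; no redox chemistry beyond the explicit
nitrification reaction; the induced-polarization layer reduces measured
spectra (σ′, σ″, percent changes, Archie-type regression) but contains
no mechanistic electrical-double-layer polarization model.
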