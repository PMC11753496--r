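---
title: "Kinetic and biophysical analysis of serpin polymerisation"
author: "serpinkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic and biophysical analysis of serpin polymerisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serpinkin)
```

## Scope

Serpins such as alpha-1-antitrypsin (AAT) inhibit proteases through a
metastable native fold; destabilising mutations divert the molecule through
a polymerisation-prone intermediate M\* that self-associates into ordered
polymers.  This package implements the quantitative solution-state analyses
used to characterise such variants:

* two-state fitting of thermal-shift (SYPRO Orange) melt curves and the
  apparent activation energy of the native-to-intermediate transition from
  the scan-rate dependence of the midpoint;
* polymerisation half-times from FRET progress curves, Arrhenius analysis
  across temperatures, and variant comparison at a reference temperature;
* acrylamide quenching of tryptophan fluorescence with the sphere-of-action
  Stern-Volmer model;
* stoichiometry of inhibition (SI) and spectral summary metrics (centre of
  spectral mass, intensity ratios);
* per-residue normalized B-factor comparison between crystal structures;
* forward simulators for every assay, exposing their ground truth so that
  each analysis stage is validated by parameter recovery.

Cell-based assays, crystallographic data processing and sequence
conservation analyses are out of scope.

## Thermal denaturation under a temperature ramp

Thermal unfolding of AAT monitored by an environment-sensitive dye is an
irreversible kinetic process: the "unfolded" state reached at the midpoint
is the polymerisation intermediate, and the observed midpoint $T_m$ shifts
with the heating rate $v$.  We model a single first-order irreversible step
with Arrhenius rate $k_d(T) = A e^{-E_a/RT}$.  Under a linear ramp the
native fraction obeys $dN/dT = -k_d(T)\,N/v$, and the midpoint satisfies,
to first order,

$$\frac{k_d(T_m)\,R\,T_m^2}{v\,E_a} = \ln 2,$$

from which the standard scan-rate transformation follows: an ordinary
least-squares regression of $\ln(v/T_m^2)$ on $1/T_m$ has slope $-E_a/R$.
`ramp_rate_activation_energy()` implements this as the default.  The
alternative transformation $\ln v$ vs $1/T_m$ (without the $T_m^2$ term) is
exposed as `mode = "lnv"`; the two differ by about $2RT_m \approx
5.5\ \mathrm{kJ\,mol^{-1}}$ here, inside the standard errors of the
published regressions, and we validated the default against the package's
own ramp simulator rather than against figure axes.  The regression is
unweighted by default because the tabulated midpoint errors are
near-uniform; a `weighted` mode using $1/\mathrm{SE}(T_m)^2$ exists.

```{r table1}
tab <- aat_tm_table()
m <- subset(tab, variant == "M")
ramp_rate_activation_energy(
  build_ramp_series(m$v_C_per_min, m$tm_C, m$tm_se_C, "M"))
```

Temperatures are degrees Celsius at every file and interface boundary and
kelvin (offset exactly 273.15) inside any Arrhenius computation.

### Two-state melt fitting

`fit_two_state()` fits
$$F(T) = B_{pre}(T) + \frac{B_{post}(T) - B_{pre}(T)}{1 + e^{(T_m - T)/m}}$$
by Levenberg-Marquardt least squares.  Three numerical choices matter:

* **Window.** SYPRO-type signals decay above the transition (dye release on
  aggregation), so the two-state model is invalid on the dissociation limb.
  The default window runs from the first temperature to the global signal
  maximum, located on a lightly smoothed copy of the trace so that noise
  cannot drag the window end along a flat top; ties resolve to the lowest
  temperature.
* **Post-transition baseline.** With the window ending at the maximum, the
  post-transition segment inside the window is too short to identify a
  baseline slope, and on asymmetric kinetic transitions a free slope trades
  off against $T_m$ (biases of several kelvin in our simulations).  The
  default therefore fits a constant upper plateau; `post_slope = "free"`
  restores the fully linear form for explicitly windowed fits.
* **Initialisation.** $T_m$ starts at the maximum of a smoothed first
  derivative (lowest temperature on ties, for determinism); baselines start
  from edge regressions.

The fitted midpoint of a symmetric sigmoid is exact; on simulated kinetic
(asymmetric) transitions it carries a small positive systematic offset
(bounded below 0.5 K in the shipped test scenarios).  The offset is common
to all scan rates and cancels in the scan-rate regression, which is the
quantity of scientific interest.

## Polymerisation kinetics

The simulator integrates the mass-action scheme

$$\mathrm{M} \underset{k_{-1}}{\overset{k_1}{\rightleftharpoons}} \mathrm{M}^*,
\qquad \mathrm{M}^* + \mathrm{M}^* \xrightarrow{k_2} \mathrm{P},$$

with P accounting for monomer mass in polymer, so $M + M^* + P = M_0$
identically; the FRET-like signal is the polymerised mass fraction
$P/M_0$.  Elongation beyond the committed association step is not
modelled - at this level of abstraction it is signal-equivalent.  The
solver is lsoda with relative tolerance $10^{-8}$, run on a grid 100 times
finer than the returned trace; the true half-time interpolated on that
dense grid ships with each trace as oracle metadata.

No experimental rate constants exist for this scheme, so the defaults of
`polym_scheme()` are calibrated constructs, chosen once: monomer activation
is rate-limiting (association is fast and effectively committed), and at a
5 uM monomer concentration half-times fall from roughly 2700 s at 50 °C to
45 s at 65 °C - the temperature window and hour scale of the experimental
FRET assay - with a near-linear Arrhenius plot ($R^2 > 0.99$).  The
simulated temperature grid is six points across 50-65 °C (the experimental
set is not enumerated in that range).

`half_time()` defaults to model-free plateau crossing because aggregation
traces take sigmoidal and biphasic shapes that no single functional form
fits reliably: the signal is normalized between plateau estimates and t0.5
is the first linear-interpolated crossing of 0.5 (earliest time on flat
segments).  The plateaus are the asymptotes of a monotone saturating
single-exponential fit whenever that fit reproduces the observed tail -
exact for curves that rise from the first sample, such as a truncated
exponential - and otherwise fall back to the medians of the first and last
5% of points (appropriate for sigmoid curves with a resolved lag).  Curves
whose final normalized value stays below 0.8 are rejected in plateau mode;
`method = "exponential_fit"` remains available for truncated curves and
reports $t_{0.5} = \ln 2 / k$.

`arrhenius_fit()` regresses $\ln t_{0.5}$ on $1/T$ (not $\ln(1/t_{0.5})$),
so the slope is $+E_a/R$ and a positive $E_a$ means faster polymerisation
at higher temperature.  `interpolate_half_time()` evaluates the fitted line
at a reference temperature - conventionally 54.8 °C, i.e.
`celsius_to_kelvin(54.8)` = 327.95 K - flagging anything more than 2 K
outside the fitted range as extrapolation, and `fold_change()` forms the
half-time ratio of two variants there with a delta-method standard error
from both regression covariances.

## Sphere-of-action quenching

Collisional quenching of tryptophan fluorescence by acrylamide follows the
Stern-Volmer law; static proximity quenching adds exponential curvature,
giving the sphere-of-action model

$$F_0/F = Y_{int} + K_{SV}\,[Q]\,e^{V[Q]}.$$

`build_titration()` converts a stepwise addition protocol into
concentrations and dilution-corrected fluorescence:
$Q_i = (\sum_j \mathrm{vol}_j c_{stock})/V_i$ and
$F_{corr,i} = F_{raw,i} V_i / V_0$.  The experimental protocol states only
the initial (90.5 uL) and final (100 uL) volumes and "0.1 M added five
times"; we read this as five equal additions each raising the nominal
concentration by ~0.1 M (1.9 uL of a ~5.26 M stock), and the builder takes
volumes and stock concentration explicitly so either reading is
expressible.  Published quenching constants are therefore magnitude context
(the raw titrations are not public); validation is by round trip, which is
exact noise-free and recovers $K_{SV}$ with a median error below 5% at 2%
multiplicative noise.

The fit is nonlinear least squares on the ratio $F_0/F$ (the plotted
quantity, with errors assumed homoscedastic in the ratio), started from
$Y_{int}=1$, $K_{SV}$ = OLS slope of the first three points, $V=0$.  $V$ is
bounded to $[0, 50]\ \mathrm{M^{-1}}$ and a fit ending on the bound is
flagged unidentifiable; an intercept further than 0.1 from 1 flags bad
normalization.  With $V = 0$ the model nests the linear Stern-Volmer law
exactly.

## Stoichiometry of inhibition and spectra

The SI titration is linear: residual protease activity $a$ declines with
the inhibitor:enzyme ratio $r$ until the endpoint.  `fit_si()` regresses
$a$ on $r$ using only points with $a > 0.05$ - readings at or past the
endpoint are saturated at zero and carry no information about the line -
and reports the x-intercept $SI = -b_0/b_1$ with a delta-method error.  The
regression is not forced through $(0, 1)$; an intercept outside
$[0.8, 1.2]$ is flagged instead.  Under the suicide-substrate partitioning
interpretation an SI of $s$ means a fraction $1 - 1/s$ of inhibitor
molecules is consumed non-productively, so `activity_reduction()` maps
SI = 1.7 to a ~41% loss of specific activity (consistent with the ~30%
conventionally quoted for an SI near 1.4).

`cosm()` computes the centre of spectral mass
$\sum \lambda_i F_i / \sum F_i$ on the wavelength axis in nm (the axis the
spectra are reported on; a wavenumber option is a possible extension), and
`intensity_ratio()` compares spectra by peak height or trapezoidal area
over the overlapping range.  Both are scale-invariant/equivariant in the
obvious way, which the tests assert.

## B-factor comparison

Crystallographic B-factors report atomic displacement but carry
dataset-level offsets (resolution, refinement protocol), so cross-crystal
comparison requires within-structure normalization.  "Normalized" is
implemented as the z-score of residue-mean B over heavy atoms - the
standard choice that removes overall-B offsets; mean-relative or min-max
alternatives can be composed from the same primitives, and min-max
rescaling (`minmax01()`) is applied only where a [0, 1] range is wanted for
colouring.  Residue identity is (chain, author residue number, insertion
code); no sequence alignment is attempted because compared structures share
numbering.  Averaging across structures restricts to residues modelled in
all inputs and reports the dropped ones (e.g. disordered loop residues) -
never imputes.  Alternate conformers contribute once via the
highest-occupancy conformer; waters and hetero groups are excluded.
`write_bfactor_column()` writes map values into the B column (`%6.2f`) for
molecular-graphics colouring.

Applying the pipeline to the real deposited structures requires downloading
PDB entries and is a documented optional workflow; tests and the shipped
analysis use synthetic structure pairs with an injected, exactly known
perturbation, which the pipeline must recover as the argmax region of the
difference map.

## Synthetic data: what it does and does not show

Every generator exposes its ground truth (true midpoint, dense-grid
half-time, model parameters, perturbed region), all randomness flows
through seeded `noise_model()` objects, and identical seeds give identical
outputs.  Noise is Gaussian, multiplicative and/or additive.  The
simulators emulate the *structure* of the real data - scan-rate-dependent
asymmetric melts with post-transition dye decay, sigmoidal mass-action
aggregation curves, stepwise diluted titrations, linear inhibition series -
but not instrument drift, well-to-well variation, outliers, or deviations
from the assumed kinetic schemes.  Passing recovery tests therefore shows
the estimators are correct and numerically stable under the stated models
and realistic noise levels; it does not certify the models against every
behaviour of real instruments.

Problem sizes used throughout (0.1 K melt steps over 25-90 °C, 200-point
kinetic traces with a 100x oracle grid, six-temperature Arrhenius series,
100-seed noise ensembles) were chosen as representative of plate-reader
output while keeping every analysis comfortably interactive.

## Known limitations

* Thermodynamic (equilibrium $\Delta H$, $\Delta G$) analysis of melts and
  multi-transition deconvolution are out of scope; the melt model is
  strictly kinetic two-state.
* Mechanistic fitting of experimental FRET traces to the activation/
  association scheme is not attempted (the simulator is forward-only), and
  nucleation-elongation model selection is out of scope.
* The sphere-of-action fit cannot separate dynamic from static quenching
  without lifetime data.
* The symmetric two-state fit carries a small positive midpoint offset on
  asymmetric kinetic transitions (see above); scan-rate regressions are
  unaffected, but absolute midpoints from different window conventions
  should not be mixed.
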