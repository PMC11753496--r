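# serpinkin

Kinetic and biophysical analysis of serpin polymerisation, motivated by
deficiency variants of alpha-1-antitrypsin (AAT) that misfold through a
polymerisation-prone intermediate M\* (scheme M ⇌ M\*, M\* + M\* → P) and
aggregate in hepatocytes.  The package turns the standard solution-state
characterisation of such variants into tested, reusable code:

* **Thermal denaturation.** Two-state fits of thermal-shift melt curves
  (`fit_two_state`) and the apparent activation energy of the
  native-to-intermediate transition from the scan-rate dependence of the
  midpoint: OLS of ln(v/Tm²) on 1/Tm, Ea = −slope·R
  (`build_ramp_series`, `ramp_rate_activation_energy`).
* **Polymerisation kinetics.** Half-times of FRET progress curves by
  model-free plateau crossing or exponential fit (`half_time`), Arrhenius
  analysis of ln t₀.₅ vs 1/T (`arrhenius_fit`), interpolation at a
  reference temperature and variant fold-change with delta-method errors
  (`interpolate_half_time`, `fold_change`).
* **Quenching.** Dilution-corrected Stern-Volmer titrations from stepwise
  acrylamide additions (`build_titration`) and the sphere-of-action fit
  F₀/F = Y_int + K_SV·[Q]·e^{V[Q]} (`fit_sphere_of_action`).
* **Bulk assays.** Stoichiometry of inhibition by linear titration
  (`fit_si`, `activity_reduction`), centre of spectral mass (`cosm`) and
  spectral intensity ratios (`intensity_ratio`).
* **Structure.** Per-residue B-factor extraction from PDB files with
  altloc/occupancy handling (`read_structure_b`), z-normalization,
  averaging, differencing and [0,1] rescaling (`znorm`, `average_maps`,
  `diff_maps`, `minmax01`), and B-column write-back for colouring
  (`write_bfactor_column`).
* **Synthetic data.** Forward simulators with machine-readable ground truth
  for every assay (`simulate_melt`, `simulate_polym`, `simulate_quench`,
  `simulate_si`, `make_toy_structures`), so each stage is validated by
  parameter recovery.

## Worked example

The packaged table of observed melting midpoints for wild-type (M) and
Gly192Cys AAT at four ramp rates drives the scan-rate regression:

```r
library(serpinkin)
tab <- aat_tm_table()
m <- subset(tab, variant == "M")
ramp_rate_activation_energy(
  build_ramp_series(m$v_C_per_min, m$tm_C, m$tm_se_C, "M"))
#> Ramp-rate activation energy [M]: Ea = 278.0 +/- 20.3 kJ/mol (R2 = 0.989, n = 4)
g <- subset(tab, variant == "Gly192Cys")
ramp_rate_activation_energy(
  build_ramp_series(g$v_C_per_min, g$tm_C, g$tm_se_C, "Gly192Cys"))
#> Ramp-rate activation energy [Gly192Cys]: Ea = 308.7 +/- 51.4 kJ/mol (R2 = 0.948, n = 4)
```

Every mutant midpoint is lower than wild-type, yet the regression slope is
steeper: the variant destabilises the native state while *raising* the
energy barrier to the polymerisation intermediate (~309 vs ~278 kJ/mol from
the table means).  The analysis scripts under `analysis/` walk through the
remaining assays in order (`01_ramp_ea_table1.R` … `06_bfactor.R`), each a
thin driver over the package that prints its finding and writes tables
under `results/`, e.g.

```
$ Rscript analysis/03_polym_kinetics.R
Arrhenius fit [baseline]: Ea = 254.1 +/- 0.7 kJ/mol (R2 = 1.000, n = 6)
Arrhenius fit [fast4x]: Ea = 254.1 +/- 0.7 kJ/mol (R2 = 1.000, n = 6)
t0.5 at 54.8 degC: baseline 757.5 s, fast4x 189.4 s
fold change (baseline/fast4x): 4.000 +/- 0.025 (truth 4)
```

(a simulated fast-polymerising variant built with an exactly 4-fold
half-time difference is recovered through the full pipeline).

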