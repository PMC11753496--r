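#' Noise model for simulated assays
#'
#' Multiplicative Gaussian noise (fractional sigma), additive Gaussian noise
#' (signal units), and an optional seed.  The same seed always yields the
#' same noise stream; `seed = NULL` draws from the current RNG state.
#'
#' @param mult fractional multiplicative sigma (e.g. 0.01 for 1%).
#' @param add additive sigma in signal units.
#' @param seed integer seed or NULL.
#' @return a `noise_model` list.
#' @export
noise_model <- function(mult = 0, add = 0, seed = NULL) {
  stopifnot(mult >= 0, add >= 0)
  structure(list(mult = mult, add = add, seed = seed), class = "noise_model")
}

apply_noise <- function(y, noise) {
  if (is.null(noise)) return(y)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  if (noise$mult > 0) y <- y * (1 + rnorm(length(y), 0, noise$mult))
  if (noise$add > 0) y <- y + rnorm(length(y), 0, noise$add)
  y
}

arrhenius_k <- function(A, ea_kJ_mol, T_K) A * exp(-ea_kJ_mol * 1000 / (.R_GAS * T_K))

#' Arrhenius parameters for the thermal-denaturation simulator
#'
#' A single first-order irreversible step N -> I with rate
#' \eqn{k_d(T) = A e^{-E_a/RT}} drives the simulated melt.
#'
#' @param A_per_min pre-exponential factor, 1/min.
#' @param ea_kJ_mol activation energy, kJ/mol.
#' @return a `melt_scheme` list.
#' @export
melt_scheme <- function(A_per_min, ea_kJ_mol) {
  stopifnot(A_per_min > 0, ea_kJ_mol >= 0)
  structure(list(A_per_min = A_per_min, ea_kJ_mol = ea_kJ_mol),
            class = "melt_scheme")
}

#' Calibrate a melt scheme to a target midpoint
#'
#' Solves the kinetic two-state midpoint condition
#' \eqn{k_d(T_m) R T_m^2 / (v E_a) = \ln 2} for the pre-exponential factor,
#' so that a simulated melt at scan rate `v_ref` has its midpoint at
#' `tm_ref_C`.  Used to place simulated scenarios in a realistic Tm range.
#'
#' @param ea_kJ_mol activation energy, kJ/mol.
#' @param tm_ref_C target midpoint at the reference rate, degC.
#' @param v_ref reference scan rate, K/min.
#' @return a `melt_scheme`.
#' @export
calibrate_melt_scheme <- function(ea_kJ_mol, tm_ref_C, v_ref = 1) {
  Ea <- ea_kJ_mol * 1000
  Tm <- celsius_to_kelvin(tm_ref_C)
  A <- log(2) * v_ref * Ea / (.R_GAS * Tm^2) * exp(Ea / (.R_GAS * Tm))
  melt_scheme(A, ea_kJ_mol)
}

#' Simulate a thermal-shift melt curve under a linear temperature ramp
#'
#' Integrates first-order irreversible denaturation in the temperature
#' domain, \eqn{dN/dT = -k_d(T) N / v}, over a linear ramp at scan rate `v`,
#' and maps the native fraction N onto a reporter signal with linear pre-
#' and post-transition baselines:
#' `signal = pre(T) * N + post(T) * (1 - N)`.  The true midpoint (N = 1/2
#' crossing) is returned as oracle metadata alongside the trace.
#'
#' @param scheme a [melt_scheme()].
#' @param v scan rate, K/min (> 0).
#' @param t_range_C temperature range of the ramp, degC.
#' @param step_C output temperature step, degC (default 0.1; integration is
#'   performed on a 10x finer grid).
#' @param noise a [noise_model()] applied to the signal, or NULL.
#' @param baseline_pre,baseline_post `c(intercept, slope_per_C)` of the two
#'   baselines.  The default post-transition baseline has a negative slope,
#'   emulating the dye-signal decay above the transition seen in SYPRO
#'   Orange thermal-shift data; it gives the trace a well-defined global
#'   maximum just past the transition, which is what the default fit window
#'   of [fit_two_state()] keys on.
#' @return list with `trace` (data.frame `temperature_C`, `signal`),
#'   `true_tm_K`, `true_tm_C`, `v`, `scheme`.
#' @export
simulate_melt <- function(scheme, v, t_range_C = c(25, 90), step_C = 0.1,
                          noise = NULL,
                          baseline_pre = c(0, 0),
                          baseline_post = c(1.5, -0.007)) {
  stopifnot(v > 0, step_C > 0)
  T_out_C <- seq(t_range_C[1], t_range_C[2], by = step_C)
  fine_C <- seq(t_range_C[1], t_range_C[2], by = step_C / 10)
  fine_K <- celsius_to_kelvin(fine_C)
  k <- arrhenius_k(scheme$A_per_min, scheme$ea_kJ_mol, fine_K)
  # cumulative trapezoid of k/v over T gives -ln N
  h <- diff(fine_K)
  cum <- c(0, cumsum(h * (head(k, -1) + tail(k, -1)) / 2)) / v
  lnN <- -cum
  if (lnN[length(lnN)] > log(0.5) || lnN[1] < log(0.5))
    sk_stop("no transition midpoint inside the simulated temperature range",
            "sk_generator_error")
  i <- which(lnN <= log(0.5))[1]
  true_tm_K <- fine_K[i - 1] + (log(0.5) - lnN[i - 1]) *
    (fine_K[i] - fine_K[i - 1]) / (lnN[i] - lnN[i - 1])
  N <- exp(approx(fine_C, lnN, xout = T_out_C)$y)
  pre <- baseline_pre[1] + baseline_pre[2] * T_out_C
  post <- baseline_post[1] + baseline_post[2] * T_out_C
  signal <- apply_noise(pre * N + post * (1 - N), noise)
  list(trace = data.frame(temperature_C = T_out_C, signal = signal),
       true_tm_K = true_tm_K, true_tm_C = kelvin_to_celsius(true_tm_K),
       v = v, scheme = scheme)
}

#' Arrhenius-parameterized rate scheme for the polymerisation simulator
#'
#' Mass-action scheme for serpin polymerisation through an activated
#' monomer: M <-> M* (activation `k1`, reversion `km1`, first order) and
#' M* + M* -> P (association `k2`, second order, irreversible).  Each rate
#' constant is Arrhenius-parameterized, \eqn{k = A e^{-E_a/RT}}, so the same
#' scheme can be simulated across a temperature series.
#'
#' The defaults are calibrated constructs (the experimental rate constants
#' are not known) chosen so that, at a 5 uM monomer concentration,
#' half-times fall from roughly 2700 s at 50 degC to 45 s at 65 degC with a
#' near-linear Arrhenius plot of ln t0.5 over that range, and so that
#' monomer activation is rate-limiting (association is fast and effectively
#' committed), giving progress curves that saturate cleanly.
#'
#' @param A1,ea1 activation step: prefactor (1/s) and Ea (kJ/mol).
#' @param Am1,eam1 reversion step: prefactor (1/s) and Ea (kJ/mol).
#' @param A2,ea2 association step: prefactor (1/(M s)) and Ea (kJ/mol).
#' @param M0_M initial monomer concentration, molar.
#' @return a `polym_scheme` list.
#' @export
polym_scheme <- function(A1 = 6.6e36, ea1 = 250,
                         Am1 = 1e9, eam1 = 70,
                         A2 = 5e14, ea2 = 55,
                         M0_M = 5e-6) {
  stopifnot(A1 > 0, Am1 > 0, A2 > 0, ea1 >= 0, eam1 >= 0, ea2 >= 0, M0_M > 0)
  structure(list(A1 = A1, ea1 = ea1, Am1 = Am1, eam1 = eam1,
                 A2 = A2, ea2 = ea2, M0_M = M0_M), class = "polym_scheme")
}

#' Scale every rate constant of a polymerisation scheme
#'
#' Multiplying all rate constants by `factor` rescales time exactly by
#' `1/factor` (mass-action time rescaling), which is useful for building
#' scheme pairs with a known half-time ratio.
#'
#' @param scheme a [polym_scheme()].
#' @param factor positive multiplier applied to the three prefactors.
#' @return a `polym_scheme`.
#' @export
scale_scheme <- function(scheme, factor) {
  stopifnot(factor > 0)
  polym_scheme(A1 = scheme$A1 * factor, ea1 = scheme$ea1,
               Am1 = scheme$Am1 * factor, eam1 = scheme$eam1,
               A2 = scheme$A2 * factor, ea2 = scheme$ea2,
               M0_M = scheme$M0_M)
}

polym_rates <- function(scheme, T_K) {
  list(k1 = arrhenius_k(scheme$A1, scheme$ea1, T_K),
       km1 = arrhenius_k(scheme$Am1, scheme$eam1, T_K),
       k2 = arrhenius_k(scheme$A2, scheme$ea2, T_K))
}

#' Simulate a polymerisation progress curve
#'
#' Integrates the activation/association scheme at a fixed hold temperature:
#' \deqn{dM/dt = -k_1 M + k_{-1} M^*}
#' \deqn{dM^*/dt = k_1 M - k_{-1} M^* - 2 k_2 {M^*}^2}
#' \deqn{dP/dt = 2 k_2 {M^*}^2}
#' with P accounting for monomer mass incorporated into polymer, so
#' \eqn{M + M^* + P = M_0} at all times.  The FRET-like signal is the
#' polymerised mass fraction \eqn{P/M_0}.  The solver (lsoda, relative
#' tolerance 1e-8) is run on a dense grid 100x finer than the returned
#' trace; the true half-time (first crossing of half the final polymer
#' mass, linearly interpolated on the dense grid) is returned as oracle
#' metadata.
#'
#' @param scheme a [polym_scheme()].
#' @param T_K hold temperature, kelvin.
#' @param t_end_s end time, seconds; if NULL it is sized automatically so
#'   that the polymerised fraction reaches at least 0.95.
#' @param n_points number of points in the returned trace.
#' @param noise a [noise_model()] or NULL.
#' @param dense_factor oracle grid refinement relative to the trace.
#' @return list with `trace` (data.frame `time_s`, `signal`), `true_t05_s`,
#'   `final_fraction`, `incomplete` flag (final fraction < 0.9), `T_K`,
#'   `states` (dense data.frame time, M, Ms, P).
#' @export
simulate_polym <- function(scheme, T_K, t_end_s = NULL, n_points = 200,
                           noise = NULL, dense_factor = 100) {
  rates <- polym_rates(scheme, T_K)
  M0 <- scheme$M0_M
  deriv <- function(t, y, parms) {
    with(as.list(c(y, rates)), {
      dM <- -k1 * M + km1 * Ms
      dMs <- k1 * M - km1 * Ms - 2 * k2 * Ms^2
      dP <- 2 * k2 * Ms^2
      list(c(dM, dMs, dP))
    })
  }
  run <- function(t_end, n) {
    times <- seq(0, t_end, length.out = n)
    out <- deSolve::ode(y = c(M = M0, Ms = 0, P = 0), times = times,
                        func = deriv, parms = NULL, method = "lsoda",
                        rtol = 1e-8, atol = 1e-14 * M0)
    as.data.frame(out)
  }
  if (is.null(t_end_s)) {
    t_end_s <- 1 / max(rates$k1, 1e-12)
    for (it in 1:30) {
      trial <- run(t_end_s, 200)
      if (trial$P[nrow(trial)] / M0 >= 0.95) break
      t_end_s <- t_end_s * 2
    }
    # trim to just past the 95% point so the trace is dominated by the
    # transition, not by the slow final approach to plateau
    i95 <- which(trial$P / M0 >= 0.95)[1]
    if (!is.na(i95)) t_end_s <- 1.1 * trial$time[i95]
  }
  n_dense <- n_points * dense_factor - (dense_factor - 1)  # coarse grid is a subset
  dense <- run(t_end_s, n_dense)
  if (min(dense$M, dense$Ms, dense$P) < -1e-6 * M0)
    sk_stop("integration failure: negative concentrations", "sk_integration_error")
  P <- dense$P
  half <- P[length(P)] / 2
  i <- which(P >= half)[1]
  true_t05 <- if (i == 1) dense$time[1] else
    dense$time[i - 1] + (half - P[i - 1]) * (dense$time[i] - dense$time[i - 1]) /
      (P[i] - P[i - 1])
  coarse_idx <- seq(1, n_dense, by = dense_factor)
  trace <- data.frame(time_s = dense$time[coarse_idx],
                      signal = apply_noise(P[coarse_idx] / M0, noise))
  frac <- P[length(P)] / M0
  list(trace = trace, true_t05_s = true_t05, final_fraction = frac,
       incomplete = frac < 0.9, T_K = T_K, states = dense)
}

#' Simulate a stepwise quenching titration
#'
#' Exact inverse of the quenching analysis pipeline: computes the cumulative
#' quencher concentration and dilution factor per step from the stated
#' protocol, evaluates the sphere-of-action model
#' \eqn{F_0/F = Y_{int} + K_{SV} Q e^{VQ}}, and un-corrects for dilution to
#' produce the raw fluorescence readings an instrument would report.
#'
#' @param ksv,v,yint model parameters (1/M, 1/M, dimensionless).
#' @param protocol list with `initial_ul`, `step_ul`, `stock_m`, `n_steps`;
#'   the default emulates five 1.9 uL additions of a 5.26 M stock into
#'   90.5 uL (final volume 100 uL, final Q close to 0.5 M).
#' @param f0_raw raw fluorescence of the quencher-free point.
#' @param noise a [noise_model()] applied to the raw readings, or NULL.
#' @return list with `data` (data.frame `f_raw`, `added_ul`) and `truth`
#'   (list ksv, v, yint, protocol).
#' @export
simulate_quench <- function(ksv, v, yint = 1,
                            protocol = list(initial_ul = 90.5, step_ul = 1.9,
                                            stock_m = 5.26, n_steps = 5),
                            f0_raw = 1000, noise = NULL) {
  added <- c(0, rep(protocol$step_ul, protocol$n_steps))
  vol <- protocol$initial_ul + cumsum(added)
  Q <- cumsum(added) * protocol$stock_m / vol
  F0 <- f0_raw                       # corrected F at Q=0 (volume factor 1)
  ratio <- yint + ksv * Q * exp(v * Q)
  # The measured Q=0 point defines F0; with yint = 1 the model curve passes
  # through it exactly and the analysis round trip is exact.  A yint away
  # from 1 models a normalization offset affecting the quenched points.
  F_corr <- F0 / ratio
  F_corr[1] <- F0
  f_raw <- apply_noise(F_corr / (vol / protocol$initial_ul), noise)
  list(data = data.frame(f_raw = f_raw, added_ul = added),
       truth = list(ksv = ksv, v = v, yint = yint, protocol = protocol))
}

#' Simulate a stoichiometry-of-inhibition titration
#'
#' Residual activity declining linearly to zero at the true SI:
#' \eqn{a(r) = \max(0, 1 - r/SI)} plus noise, on a stated ratio grid.
#'
#' @param si_true true stoichiometry of inhibition (>= 1).
#' @param ratios inhibitor:enzyme ratio grid.
#' @param noise a [noise_model()] or NULL.
#' @return list with `data` (data.frame `ratio`, `activity`) and
#'   `truth = si_true`.
#' @export
simulate_si <- function(si_true, ratios = seq(0, 2.5, by = 0.25),
                        noise = NULL) {
  stopifnot(si_true >= 1)
  a <- pmax(0, 1 - ratios / si_true)
  a <- apply_noise(a, noise)
  list(data = data.frame(ratio = ratios, activity = a), truth = si_true)
}

#' Generate a pair of toy coordinate files with controlled B-factors
#'
#' Writes two synthetic PDB files with identical backbone coordinates (an
#' ideal helical trace; N, CA, C, O per residue) whose B columns differ only
#' in a stated residue region by a stated magnitude (expressed in z-units of
#' the baseline profile).  Used to validate the B-factor comparison
#' pipeline: the perturbed region must come back as the top of the
#' difference map.
#'
#' @param path_a,path_b output PDB paths (file a is the unperturbed
#'   reference).
#' @param n_res number of residues.
#' @param chain chain identifier.
#' @param region integer residue numbers to perturb in file b.
#' @param delta_z perturbation magnitude in z-units of the baseline profile.
#' @param seed optional seed for the (smooth, reproducible) baseline profile.
#' @return invisibly, list with `b_base` and `b_perturbed` vectors.
#' @export
make_toy_structures <- function(path_a, path_b, n_res = 40, chain = "A",
                                region = 18:24, delta_z = 2, seed = NULL) {
  stopifnot(all(region >= 1), all(region <= n_res))
  if (!is.null(seed)) set.seed(seed)
  base <- 15 + 5 * sin(seq(0, 3 * pi, length.out = n_res)) +
    rnorm(n_res, 0, 0.5)
  pert <- base
  pert[region] <- pert[region] + delta_z * sd(base)
  write_helix_pdb(path_a, n_res, chain, base)
  write_helix_pdb(path_b, n_res, chain, pert)
  invisible(list(b_base = base, b_perturbed = pert))
}

write_helix_pdb <- function(path, n_res, chain, bfac) {
  # ideal alpha-helical backbone trace: 100 deg twist, 1.5 A rise per residue
  lines <- character()
  serial <- 0L
  atoms <- list(N = c(1.7, -25), CA = c(2.3, 0), C = c(2.0, 25), O = c(2.8, 40))
  for (i in seq_len(n_res)) {
    ang0 <- (i - 1) * 100 * pi / 180
    z0 <- (i - 1) * 1.5
    for (nm in names(atoms)) {
      serial <- serial + 1L
      r <- atoms[[nm]][1]
      ang <- ang0 + atoms[[nm]][2] * pi / 180
      el <- substr(nm, 1, 1)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s ALA %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, nm, chain, i, r * cos(ang), r * sin(ang), z0 + 0.3 * match(nm, names(atoms)),
        1.00, bfac[i], el))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
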