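#' Build a dilution-corrected quenching titration
#'
#' Converts a stepwise quencher-addition experiment (raw fluorescence after
#' each addition of quencher stock) into concentration/fluorescence pairs.
#' The quencher concentration after step i is the cumulative amount of added
#' stock divided by the current volume,
#' \eqn{Q_i = (\sum_j \mathrm{vol}_j \cdot c_{stock}) / V_i}, and the
#' fluorescence is corrected for dilution of the fluorophore,
#' \eqn{F_{corr,i} = F_{raw,i} \cdot V_i / V_0}.  F0 is the corrected
#' fluorescence of the first (quencher-free) point.
#'
#' @param f_raw raw fluorescence readings, one per titration point, all > 0.
#' @param added_ul volume of stock added before each reading, microlitres;
#'   the first entry must be 0 (the quencher-free reading).
#' @param initial_ul initial reaction volume, microlitres.
#' @param stock_m quencher stock concentration, molar.
#' @return A `quench_titration` data.frame with columns `Q` (M), `F_corr`,
#'   `volume` (uL), and attribute `F0`.
#' @export
build_titration <- function(f_raw, added_ul, initial_ul, stock_m) {
  stopifnot(length(f_raw) == length(added_ul))
  if (stock_m <= 0 || initial_ul <= 0)
    sk_stop("initial volume and stock concentration must be positive",
            "sk_input_error")
  if (added_ul[1] != 0)
    sk_stop("first titration point must have added_volume = 0",
            "sk_input_error")
  if (any(added_ul < 0))
    sk_stop("volumes cannot shrink: negative addition found", "sk_input_error")
  if (any(f_raw <= 0))
    sk_stop("raw fluorescence must be positive", "sk_input_error")
  vol <- initial_ul + cumsum(added_ul)
  Q <- cumsum(added_ul) * stock_m / vol   # uL*M/uL = M
  F_corr <- f_raw * vol / initial_ul
  out <- data.frame(Q = Q, F_corr = F_corr, volume = vol)
  structure(out, F0 = F_corr[1],
            class = c("quench_titration", "data.frame"))
}

#' Fit the sphere-of-action Stern-Volmer model
#'
#' Fits \deqn{F_0/F = Y_{int} + K_{SV}\,[Q]\,e^{V[Q]}} to a dilution-corrected
#' titration by nonlinear least squares on the ratio \eqn{F_0/F}.  `ksv` is
#' the Stern-Volmer quenching constant (1/M); `v` is the sphere-of-action
#' term (1/M) producing the upward curvature from static proximity
#' quenching; `yint` is the intercept, expected to be close to 1.
#'
#' Starting values: `yint = 1`, `ksv` from the ordinary least-squares slope
#' of the first three points, `v = 0`.  `v` is bounded to [0, 50] 1/M; a fit
#' ending on the upper bound is flagged as unidentifiable.
#'
#' @param titration a [build_titration()] result (>= 4 points including Q=0).
#' @param fix_yint if `TRUE`, the intercept is fixed at 1.
#' @return An `sv_fit` list: `ksv`, `v`, `yint`, `se` (named), `resid_norm`,
#'   `n`, `converged`, `flags` (character vector).
#' @export
fit_sphere_of_action <- function(titration, fix_yint = FALSE) {
  if (nrow(titration) < 4)
    sk_stop("need at least 4 titration points including Q = 0",
            "sk_insufficient_data")
  if (titration$Q[1] != 0)
    sk_stop("titration must include a Q = 0 point first", "sk_input_error")
  F0 <- attr(titration, "F0") %||% titration$F_corr[1]
  Q <- titration$Q
  r <- F0 / titration$F_corr

  ksv0 <- max(coef(lm(r[1:3] ~ Q[1:3]))[2], 1e-3)
  flags <- character()
  fit <- tryCatch({
    if (fix_yint) {
      minpack.lm::nlsLM(r ~ 1 + ksv * Q * exp(v * Q),
                        start = list(ksv = ksv0, v = 0.01),
                        lower = c(ksv = 0, v = 0), upper = c(ksv = Inf, v = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    } else {
      minpack.lm::nlsLM(r ~ yint + ksv * Q * exp(v * Q),
                        start = list(yint = 1, ksv = ksv0, v = 0.01),
                        lower = c(yint = -Inf, ksv = 0, v = 0),
                        upper = c(yint = Inf, ksv = Inf, v = 50),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    }
  }, error = function(e) NULL)

  if (is.null(fit)) {
    return(structure(list(ksv = NA_real_, v = NA_real_,
                          yint = if (fix_yint) 1 else NA_real_,
                          se = NULL, resid_norm = NA_real_, n = nrow(titration),
                          converged = FALSE, flags = "non-convergence"),
                     class = "sv_fit"))
  }
  cf <- coef(fit)
  ses <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                  error = function(e) setNames(rep(NA_real_, length(cf)), names(cf)))
  v_hat <- unname(cf["v"])
  yint_hat <- if (fix_yint) 1 else unname(cf["yint"])
  if (v_hat >= 50 - 1e-6) flags <- c(flags, "sphere term unidentifiable")
  if (abs(yint_hat - 1) > 0.1) flags <- c(flags, "intercept far from 1")
  structure(list(ksv = unname(cf["ksv"]), v = v_hat, yint = yint_hat,
                 se = setNames(as.numeric(ses), names(cf)),
                 resid_norm = sqrt(sum(residuals(fit)^2)),
                 n = nrow(titration),
                 converged = fit$convInfo$isConv %||% TRUE,
                 flags = flags), class = "sv_fit")
}

#' @export
print.sv_fit <- function(x, ...) {
  cat(sprintf("Sphere-of-action Stern-Volmer fit: KSV = %.3g 1/M, V = %.3g 1/M, Yint = %.3f\n",
              x$ksv, x$v, x$yint))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @export
fit_report.sv_fit <- function(fit) {
  list(model = "sphere_of_action_stern_volmer",
       parameters = list(ksv_per_M = fit$ksv, v_per_M = fit$v, yint = fit$yint),
       se = as.list(fit$se), n = fit$n, resid_norm = fit$resid_norm,
       converged = fit$converged, flags = as.list(fit$flags))
}
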