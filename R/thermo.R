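# Gas constant, J/mol/K; standard state 1 M throughout.
.R_GAS <- 8.314

#' Standard temperature (25 degrees Celsius) in kelvin
#' @keywords internal
.T_STANDARD <- 298.15

#' Binding free energy from a dissociation constant
#'
#' Computes the standard free energy of binding \eqn{\Delta G = RT \ln K_d}
#' with \eqn{K_d} in molar units (1 M standard state), returned in kJ/mol.
#' Sub-molar dissociation constants give negative (favorable) free energies.
#'
#' @param kd Dissociation constant in molar. Must be positive.
#' @param temperature Temperature in kelvin. Defaults to 298.15 K (25 C).
#' @return Free energy of binding in kJ/mol.
#' @examples
#' dg_from_kd(540e-9)        # ~ -35.8 kJ/mol
#' dg_from_kd(6.0e-6)        # ~ -29.8 kJ/mol
#' @export
dg_from_kd <- function(kd, temperature = .T_STANDARD) {
  if (any(!is.finite(kd)) || any(kd <= 0))
    stop("'kd' must be positive and finite (molar units)")
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("'temperature' must be positive (kelvin)")
  .R_GAS * temperature * log(kd) / 1000
}

#' Binding free energy from enthalpy and entropy terms
#'
#' \eqn{\Delta G = \Delta H + (-T\Delta S)}. Both inputs and the result are
#' in kJ/mol; the entropic term is passed as \eqn{-T\Delta S}, the sign
#' convention used in calorimetric reporting.
#'
#' @param dh Binding enthalpy, kJ/mol.
#' @param tds_neg Entropic term \eqn{-T\Delta S}, kJ/mol.
#' @return Free energy in kJ/mol.
#' @examples
#' dg_from_dh_tds(-52.3, 16.5)  # -35.8
#' @export
dg_from_dh_tds <- function(dh, tds_neg) {
  dh + tds_neg
}

#' Dissociation constant from a binding free energy
#'
#' Inverse of [dg_from_kd()]: \eqn{K_d = \exp(\Delta G / RT)} in molar.
#'
#' @param dg Free energy in kJ/mol (negative for favorable binding).
#' @param temperature Kelvin.
#' @return Dissociation constant, molar.
#' @export
kd_from_dg <- function(dg, temperature = .T_STANDARD) {
  if (any(!is.finite(temperature)) || any(temperature <= 0))
    stop("'temperature' must be positive (kelvin)")
  exp(dg * 1000 / (.R_GAS * temperature))
}

#' Construct a set of binding thermodynamic parameters
#'
#' Container for fitted single-site binding parameters at one temperature:
#' stoichiometry N, dissociation constant, enthalpy, and the derived
#' free-energy and entropy terms, each with a 1-SD uncertainty.
#'
#' Internal consistency is enforced at construction: \eqn{\Delta G}
#' is derived from \eqn{K_d} via [dg_from_kd()], and \eqn{-T\Delta S}
#' as \eqn{\Delta G - \Delta H} unless supplied explicitly (values supplied
#' explicitly are checked against the identities to within `tol`).
#'
#' @param n_value Stoichiometry (sites per receptor), dimensionless.
#' @param kd Dissociation constant, molar.
#' @param dh Enthalpy, kJ/mol.
#' @param temperature Kelvin.
#' @param dg,tds_neg Optional explicit values (kJ/mol); derived when `NULL`.
#' @param se Optional named list of 1-SD uncertainties (names among
#'   `n_value`, `kd`, `dh`, `dg`, `tds_neg`).
#' @param tol Consistency tolerance in kJ/mol for explicitly supplied
#'   `dg`/`tds_neg` (default 0.6, about the rounding granularity of
#'   typical reported tables).
#' @return An object of class `thermo_params`.
#' @export
thermo_params <- function(n_value, kd, dh, temperature = .T_STANDARD,
                          dg = NULL, tds_neg = NULL, se = list(), tol = 0.6) {
  if (!is.finite(kd) || kd <= 0) stop("'kd' must be positive (molar)")
  dg_calc <- dg_from_kd(kd, temperature)
  if (is.null(dg)) dg <- dg_calc
  else if (abs(dg - dg_calc) > tol)
    stop(sprintf("supplied dg (%.2f) inconsistent with RT*ln(kd) (%.2f)",
                 dg, dg_calc))
  tds_calc <- dg - dh
  if (is.null(tds_neg)) tds_neg <- tds_calc
  else if (abs(tds_neg - tds_calc) > tol)
    stop(sprintf("supplied tds_neg (%.2f) inconsistent with dg - dh (%.2f)",
                 tds_neg, tds_calc))
  structure(
    list(n_value = n_value, kd = kd, dh = dh, tds_neg = tds_neg,
         dg = dg, temperature = temperature, se = se),
    class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  se <- function(f) if (!is.null(x$se[[f]])) sprintf(" +/- %.3g", x$se[[f]]) else ""
  cat("Single-site binding thermodynamics at", sprintf("%.2f K", x$temperature), "\n")
  cat(sprintf("  N      = %.3g%s\n", x$n_value, se("n_value")))
  cat(sprintf("  Kd     = %.3g nM%s\n", x$kd * 1e9,
              if (!is.null(x$se$kd)) sprintf(" +/- %.3g", x$se$kd * 1e9) else ""))
  cat(sprintf("  dH     = %.3g kJ/mol%s\n", x$dh, se("dh")))
  cat(sprintf("  -TdS   = %.3g kJ/mol%s\n", x$tds_neg, se("tds_neg")))
  cat(sprintf("  dG     = %.3g kJ/mol%s\n", x$dg, se("dg")))
  invisible(x)
}

#' Construct an ITC titration experiment
#'
#' Holds the design and integrated injection heats of an isothermal titration
#' calorimetry experiment: receptor (cell) and ligand (syringe) concentrations,
#' cell volume, per-injection volumes and measured heats.
#'
#' The conventional design places the ligand in the syringe at roughly ten
#' times the cell concentration; a small initial injection (typically 0.5 uL)
#' is customarily discarded from analysis, which `discard_first` records.
#'
#' @param cell_concentration Receptor concentration in the cell, molar.
#' @param syringe_concentration Ligand concentration in the syringe, molar.
#' @param cell_volume Working cell volume, litres.
#' @param injection_volumes Numeric vector of injection volumes, litres.
#' @param measured_heats Numeric vector of integrated heats per injection,
#'   microjoules (uJ). `NULL` for a design-only object (e.g. as input to the
#'   forward model).
#' @param temperature Kelvin.
#' @param discard_first Logical; drop the first injection during fitting.
#' @return An object of class `itc_experiment`.
#' @export
itc_experiment <- function(cell_concentration, syringe_concentration,
                           cell_volume = 200e-6,
                           injection_volumes = c(0.5e-6, rep(2.0e-6, 18)),
                           measured_heats = NULL,
                           temperature = .T_STANDARD,
                           discard_first = TRUE) {
  if (cell_concentration <= 0 || syringe_concentration <= 0)
    stop("concentrations must be positive (molar)")
  if (cell_volume <= 0 || any(injection_volumes <= 0))
    stop("volumes must be positive (litres)")
  if (!is.null(measured_heats) &&
      length(measured_heats) != length(injection_volumes))
    stop("'measured_heats' must match 'injection_volumes' in length")
  structure(
    list(cell_concentration = cell_concentration,
         syringe_concentration = syringe_concentration,
         cell_volume = cell_volume,
         injection_volumes = injection_volumes,
         measured_heats = measured_heats,
         temperature = temperature,
         discard_first = discard_first),
    class = "itc_experiment")
}

# Cell concentrations after each injection under the perfusion (overflow)
# model of MicroCal-type instruments: injecting dV displaces an equal volume
# of the mixed cell contents, so existing species are diluted and the
# incoming ligand partially flows out. The symmetric correction uses the
# cumulative injected volume dV_tot:
#   [M]_i = M0 * (1 - dV_tot/2V0) / (1 + dV_tot/2V0)
#   [X]_i = Xs * (dV_tot/V0) / (1 + dV_tot/2V0)
# The "none" model treats the cell as expandable (no displacement).
.itc_concentrations <- function(experiment, dilution = c("overflow", "none")) {
  dilution <- match.arg(dilution)
  v0 <- experiment$cell_volume
  dv_tot <- cumsum(experiment$injection_volumes)
  if (dilution == "overflow") {
    m <- experiment$cell_concentration * (1 - dv_tot / (2 * v0)) / (1 + dv_tot / (2 * v0))
    x <- experiment$syringe_concentration * (dv_tot / v0) / (1 + dv_tot / (2 * v0))
  } else {
    m <- experiment$cell_concentration * v0 / (v0 + dv_tot)
    x <- experiment$syringe_concentration * dv_tot / (v0 + dv_tot)
  }
  list(receptor = m, ligand = x)
}

# Bound-ligand concentration from the single-site mass-balance quadratic.
# mt: total receptor sites = N*[M]; xt: total ligand; kd: molar.
.bound_ligand <- function(mt, xt, kd) {
  b <- mt + xt + kd
  (b - sqrt(b * b - 4 * mt * xt)) / 2
}

#' Forward single-site ("one set of sites") ITC isotherm
#'
#' Predicts the integrated heat of each injection for a single-site binding
#' model: at every step the cell concentrations are updated for the injection
#' (with displacement-volume bookkeeping under the perfusion model), the
#' bound-ligand concentration is solved from the mass-balance quadratic, and
#' the incremental heat is
#' \deqn{q_i = \Delta H \cdot V_0 \cdot \left( [B]_i - [B]_{i-1} \right) +
#'   \frac{dV_i}{V_0}\,\frac{Q_i + Q_{i-1}}{2} + \mathrm{offset}}
#' where \eqn{Q_i = \Delta H V_0 [B]_i} is the cumulative heat and the middle
#' term restores heat carried out by displaced liquid. A constant per-injection
#' `offset` absorbs dilution heats.
#'
#' @param params A [thermo_params()] object (N, Kd, dH used).
#' @param experiment An [itc_experiment()] (design; heats ignored).
#' @param offset Constant dilution heat per injection, microjoules.
#' @param dilution `"overflow"` (displacement bookkeeping, default) or
#'   `"none"` (expandable cell).
#' @return Numeric vector of per-injection heats in microjoules.
#' @export
wiseman_isotherm <- function(params, experiment, offset = 0,
                             dilution = c("overflow", "none")) {
  dilution <- match.arg(dilution)
  stopifnot(inherits(params, "thermo_params"), inherits(experiment, "itc_experiment"))
  if (params$kd <= 0) stop("'kd' must be positive")
  conc <- .itc_concentrations(experiment, dilution)
  v0 <- experiment$cell_volume
  # cumulative heat (J) after each injection; dH kJ/mol -> J/mol
  bound <- .bound_ligand(params$n_value * conc$receptor, conc$ligand, params$kd)
  q_cum <- params$dh * 1000 * v0 * bound
  q_prev <- c(0, q_cum[-length(q_cum)])
  dv <- experiment$injection_volumes
  dq <- q_cum - q_prev
  if (dilution == "overflow")
    dq <- dq + (dv / v0) * (q_cum + q_prev) / 2
  dq * 1e6 + offset  # J -> uJ
}

#' Fit the single-site model to ITC injection heats
#'
#' Nonlinear least-squares fit of (N, Kd, dH, offset) to integrated injection
#' heats using the forward model of [wiseman_isotherm()]. Kd is fitted on the
#' log scale; standard errors come from the fit covariance (delta method for
#' Kd). The derived \eqn{\Delta G} and \eqn{-T\Delta S} carry propagated
#' uncertainties.
#'
#' The first injection is dropped when the experiment's `discard_first` flag
#' is set. A Wiseman c-value (`cell concentration * N / Kd`) outside
#' \[1, 1000\] yields a warning annotation in the result (the isotherm shape
#' carries little information on Kd outside this window).
#'
#' @param experiment An [itc_experiment()] carrying `measured_heats`.
#' @param start Optional named list of starting values
#'   (`n_value`, `kd`, `dh`, `offset`).
#' @param dilution Passed to [wiseman_isotherm()].
#' @return A list of class `itc_fit` with elements `params`
#'   ([thermo_params()] with SEs), `offset`, `offset_se`, `fitted`,
#'   `residuals`, `converged`, `flags` (character vector of warnings such as
#'   `"c_value_out_of_range"` or `"kd_unidentifiable"`), `c_value`.
#' @export
fit_itc <- function(experiment, start = NULL, dilution = c("overflow", "none")) {
  dilution <- match.arg(dilution)
  stopifnot(inherits(experiment, "itc_experiment"))
  if (is.null(experiment$measured_heats)) stop("experiment carries no measured heats")
  keep <- seq_along(experiment$injection_volumes)
  if (isTRUE(experiment$discard_first)) keep <- keep[-1]
  if (length(keep) < 8) stop("need at least 8 usable injections")
  y <- experiment$measured_heats[keep]
  flags <- character()

  # Degenerate input: essentially no heat signal
  if (all(abs(y) < 1e-9) || stats::sd(y) < 1e-12) {
    p <- thermo_params(n_value = 1, kd = 1e-6, dh = 0,
                       temperature = experiment$temperature)
    return(structure(list(params = p, offset = mean(y), offset_se = NA_real_,
                          fitted = rep(mean(y), length(y)), residuals = y - mean(y),
                          converged = TRUE, flags = "kd_unidentifiable",
                          c_value = NA_real_),
                     class = "itc_fit"))
  }

  if (is.null(start)) {
    # crude heuristics: total heat ~ N*dH*V0*cell; midpoint slope ~ Kd
    q_tot <- sum(y) * 1e-6
    dh0 <- q_tot / (experiment$cell_volume * experiment$cell_concentration) / 1000
    if (!is.finite(dh0) || abs(dh0) < 1) dh0 <- sign(sum(y)) * 20
    start <- list(n_value = 1, kd = experiment$cell_concentration / 10,
                  dh = dh0, offset = y[length(y)])
  }

  model <- function(par) {
    p <- thermo_params(n_value = par[["n_value"]], kd = exp(par[["log_kd"]]),
                       dh = par[["dh"]], temperature = experiment$temperature)
    wiseman_isotherm(p, experiment, offset = par[["offset"]], dilution = dilution)[keep]
  }
  par0 <- c(n_value = start$n_value, log_kd = log(start$kd),
            dh = start$dh, offset = start$offset)
  fit <- minpack.lm::nls.lm(
    par = par0,
    fn = function(par) y - model(par),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  converged <- fit$info %in% 1:4
  if (!converged) flags <- c(flags, "non_convergence")

  est <- fit$par
  dof <- length(y) - length(est)
  sigma2 <- sum(fit$fvec^2) / max(dof, 1)
  cov <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  ses <- if (!is.null(cov) && all(diag(cov) >= 0)) sqrt(diag(cov))
         else rep(NA_real_, length(est))
  names(ses) <- names(est)

  kd_hat <- exp(est[["log_kd"]])
  kd_se <- kd_hat * ses[["log_kd"]]            # delta method
  t_k <- experiment$temperature
  dg_hat <- dg_from_kd(kd_hat, t_k)
  dg_se <- .R_GAS * t_k * ses[["log_kd"]] / 1000
  dh_se <- ses[["dh"]]
  tds_se <- sqrt(dg_se^2 + dh_se^2)            # ignores dG-dH covariance

  params <- thermo_params(
    n_value = est[["n_value"]], kd = kd_hat, dh = est[["dh"]],
    temperature = t_k,
    se = list(n_value = ses[["n_value"]], kd = kd_se, dh = dh_se,
              dg = dg_se, tds_neg = tds_se))

  c_value <- experiment$cell_concentration * est[["n_value"]] / kd_hat
  if (!is.na(c_value) && (c_value < 1 || c_value > 1000))
    flags <- c(flags, "c_value_out_of_range")

  structure(list(params = params, offset = est[["offset"]],
                 offset_se = ses[["offset"]],
                 fitted = model(est), residuals = fit$fvec,
                 converged = converged, flags = flags, c_value = c_value),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("Single-site ITC fit", if (!x$converged) "(NOT converged)", "\n")
  print(x$params)
  cat(sprintf("  offset = %.3g uJ, c-value = %.3g\n", x$offset, x$c_value))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
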