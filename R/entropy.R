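#' Construct a multi-temperature series of binding thermodynamics
#'
#' @param params_list List of [thermo_params()] objects fitted at distinct
#'   temperatures (at least 3 for heat-capacity extraction).
#' @param fragment Optional label of the ligand fragment.
#' @return Object of class `temperature_series`.
#' @export
temperature_series <- function(params_list, fragment = NULL) {
  if (!all(vapply(params_list, inherits, logical(1), "thermo_params")))
    stop("'params_list' must contain thermo_params objects")
  temps <- vapply(params_list, `[[`, numeric(1), "temperature")
  if (length(unique(temps)) < length(temps))
    stop("temperatures must be distinct")
  structure(list(params = params_list[order(temps)], fragment = fragment),
            class = "temperature_series")
}

#' Heat-capacity change from the temperature dependence of binding
#'
#' Ordinary least squares of the binding enthalpy against temperature gives
#' the heat-capacity change \eqn{\Delta C_p = d\Delta H/dT}; the entropic
#' term \eqn{-T\Delta S} is regressed the same way. Both fits return slope,
#' intercept, standard errors and 95 percent confidence intervals, plus
#' predicted values (with CI bands) at a reporting temperature.
#'
#' @param series A [temperature_series()] with at least 3 temperatures.
#' @param t_ref Temperature (K) at which fitted values are reported
#'   (default 298.15).
#' @return List of class `dcp_fit`: `dcp` (kJ/mol/K), `dcp_se`, `dcp_ci`
#'   (95 percent), `dh_fit` and `tds_fit` (each the underlying `lm`),
#'   `at_ref` (data.frame of predicted dH, -TdS, dG and the association
#'   entropy `ds_assoc` in J/mol/K with SEs at `t_ref`).
#' @export
fit_dcp <- function(series, t_ref = .T_STANDARD) {
  stopifnot(inherits(series, "temperature_series"))
  if (length(series$params) < 3) stop("need at least 3 temperatures")
  temp <- vapply(series$params, `[[`, numeric(1), "temperature")
  dh <- vapply(series$params, `[[`, numeric(1), "dh")
  tds <- vapply(series$params, `[[`, numeric(1), "tds_neg")

  d <- data.frame(temp = temp, dh = dh, tds = tds)
  fit_h <- stats::lm(dh ~ temp, data = d)
  fit_s <- stats::lm(tds ~ temp, data = d)
  sm <- summary(fit_h)$coefficients
  dcp <- sm["temp", "Estimate"]; dcp_se <- sm["temp", "Std. Error"]
  ci <- stats::confint(fit_h, "temp", level = 0.95)

  nd <- data.frame(temp = t_ref)
  pr_h <- stats::predict(fit_h, nd, se.fit = TRUE)
  pr_s <- stats::predict(fit_s, nd, se.fit = TRUE)
  dh_ref <- pr_h$fit; tds_ref <- pr_s$fit
  dg_ref <- dh_ref + tds_ref
  dg_se <- sqrt(pr_h$se.fit^2 + pr_s$se.fit^2)
  # association entropy at t_ref: dS = -(-TdS)/T, in J/mol/K
  ds_assoc <- -tds_ref * 1000 / t_ref
  ds_se <- pr_s$se.fit * 1000 / t_ref

  structure(list(
    dcp = dcp, dcp_se = dcp_se, dcp_ci = as.numeric(ci),
    dh_fit = fit_h, tds_fit = fit_s,
    at_ref = data.frame(
      temperature = t_ref, dh = dh_ref, dh_se = pr_h$se.fit,
      tds_neg = tds_ref, tds_se = pr_s$se.fit,
      dg = dg_ref, dg_se = dg_se,
      ds_assoc = ds_assoc, ds_assoc_se = ds_se)),
    class = "dcp_fit")
}

#' Default constants for the Spolar-Record entropy decomposition
#'
#' Classic literature values: the temperature at which the hydrophobic-
#' effect entropy vanishes (386 K), the proportionality between the
#' hydrophobic entropy and the heat-capacity change (1.35), the
#' rotational-translational entropy loss on bimolecular association
#' (-209 J/mol/K), and the mean conformational entropy lost per residue
#' folding (-23.4 J/mol/K). All are overridable, since adaptations for
#' intrinsically disordered ligands recalibrate them.
#'
#' @return Named list: `t_he_zero` (K), `he_coefficient`, `ds_rt`
#'   (J/mol/K), `ds_per_residue` (J/mol/K).
#' @export
spolar_record_constants <- function() {
  list(t_he_zero = 386, he_coefficient = 1.35,
       ds_rt = -209, ds_per_residue = -23.4)
}

#' Residues folding upon binding (Spolar-Record decomposition)
#'
#' Decomposes the association entropy at a reference temperature into
#' hydrophobic-effect, rotational-translational, and conformational terms,
#' and converts the conformational term into an estimated number of residues
#' folding upon binding:
#' \deqn{\Delta S_{HE} = c \,\Delta C_p \ln(T/T_{HE})}
#' \deqn{\Delta S_{conf} = \Delta S_{assoc} - \Delta S_{HE} - \Delta S_{rt}}
#' \deqn{R_{th} = \Delta S_{conf} / \Delta S_{res}}
#' with \eqn{\Delta C_p} in J/mol/K inside the formula. The SD of
#' \eqn{R_{th}} comes from Monte Carlo resampling of \eqn{\Delta C_p} and
#' \eqn{\Delta S_{assoc}} under their standard errors (Gaussian, fixed
#' seed); zero input errors give a zero SD.
#'
#' @param dcp Heat-capacity change, kJ/mol/K (typically negative).
#' @param ds_assoc Association entropy at `temperature`, J/mol/K.
#' @param dcp_se,ds_assoc_se Standard errors of the two inputs (same units).
#' @param temperature Reference temperature, K.
#' @param constants Named list as from [spolar_record_constants()]; every
#'   constant must be present.
#' @param n_mc Monte Carlo draws (default 10000).
#' @param seed RNG seed for the resampling.
#' @return List of class `spolar_record`: `ds_he`, `ds_rt`, `ds_conf`
#'   (J/mol/K), `r_th` (residues), `r_th_sd`.
#' @export
spolar_record_id <- function(dcp, ds_assoc, dcp_se = 0, ds_assoc_se = 0,
                             temperature = .T_STANDARD,
                             constants = spolar_record_constants(),
                             n_mc = 10000, seed = 20240118) {
  need <- c("t_he_zero", "he_coefficient", "ds_rt", "ds_per_residue")
  missing_c <- setdiff(need, names(constants))
  if (length(missing_c))
    stop("constant(s) not set: ", paste(missing_c, collapse = ", "))

  eval_r <- function(dcp_kj, ds) {
    ds_he <- constants$he_coefficient * dcp_kj * 1000 *
      log(temperature / constants$t_he_zero)
    ds_conf <- ds - ds_he - constants$ds_rt
    list(ds_he = ds_he, ds_conf = ds_conf,
         r_th = ds_conf / constants$ds_per_residue)
  }
  point <- eval_r(dcp, ds_assoc)

  r_sd <- 0
  if (dcp_se > 0 || ds_assoc_se > 0) {
    draws <- .with_seed(seed, {
      dd <- stats::rnorm(n_mc, dcp, dcp_se)
      ss <- stats::rnorm(n_mc, ds_assoc, ds_assoc_se)
      eval_r(dd, ss)$r_th
    })
    r_sd <- stats::sd(draws)
  }
  structure(list(ds_he = point$ds_he, ds_rt = constants$ds_rt,
                 ds_conf = point$ds_conf,
                 r_th = point$r_th, r_th_sd = r_sd,
                 temperature = temperature, constants = constants),
            class = "spolar_record")
}

#' @export
print.spolar_record <- function(x, ...) {
  cat("Spolar-Record entropy decomposition at", sprintf("%.2f K", x$temperature), "\n")
  cat(sprintf("  dS_HE   = %.1f J/mol/K\n", x$ds_he))
  cat(sprintf("  dS_rt   = %.1f J/mol/K\n", x$ds_rt))
  cat(sprintf("  dS_conf = %.1f J/mol/K\n", x$ds_conf))
  cat(sprintf("  R_th    = %.1f +/- %.1f residues folding on binding\n",
              x$r_th, x$r_th_sd))
  invisible(x)
}
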