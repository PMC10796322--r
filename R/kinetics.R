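#' Construct a stopped-flow fluorescence trace
#'
#' @param time Time points in seconds, strictly increasing.
#' @param fluorescence Fluorescence signal, arbitrary units.
#' @param condition Titrant concentration for the trace, molar.
#' @param dead_time Instrument dead time in seconds; points earlier than
#'   this are dropped before fitting (default 2 ms, set 0 to disable).
#' @return Object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time, fluorescence, condition = NA_real_,
                          dead_time = 0.002) {
  if (length(time) != length(fluorescence))
    stop("'time' and 'fluorescence' must have equal length")
  if (any(diff(time) <= 0)) stop("'time' must be strictly increasing")
  keep <- time >= dead_time
  time <- time[keep]; fluorescence <- fluorescence[keep]
  if (length(time) < 20) stop("need at least 20 points after dead-time cut")
  structure(list(time = time, fluorescence = fluorescence,
                 condition = condition),
            class = "kinetic_trace")
}

#' Fit single- or double-exponential decay to a trace
#'
#' Least-squares fit of \eqn{F(t) = F_\infty + \sum_i A_i e^{-k_i t}} with
#' one or two phases. Rates are fitted on the log scale and returned sorted
#' in descending order (fast phase first) together with their amplitudes.
#'
#' @param trace A [kinetic_trace()].
#' @param n_phases 1 or 2.
#' @param start Optional list with `rates`, `amplitudes`, `baseline`.
#' @return List of class `exp_fit`: `rates`, `rates_se`, `amplitudes`,
#'   `amplitudes_se`, `baseline`, `baseline_se`, `fitted`, `residuals`,
#'   `rss`, `converged`, `flags` (may include `"degenerate_rates"` when two
#'   fitted rates differ by < 20 percent).
#' @export
fit_exponential <- function(trace, n_phases = 1, start = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"), n_phases %in% c(1, 2))
  t <- trace$time; y <- trace$fluorescence
  flags <- character()

  if (stats::sd(y) < .Machine$double.eps^0.5) {
    # flat trace: amplitudes zero by construction
    k <- rep(1, n_phases)
    return(structure(list(rates = k, rates_se = rep(NA_real_, n_phases),
                          amplitudes = rep(0, n_phases),
                          amplitudes_se = rep(NA_real_, n_phases),
                          baseline = mean(y), baseline_se = NA_real_,
                          fitted = rep(mean(y), length(y)),
                          residuals = y - mean(y), rss = 0,
                          converged = TRUE, flags = "flat_trace"),
                     class = "exp_fit"))
  }

  if (is.null(start)) {
    # time scale from the span; amplitude from the signal swing
    k0 <- 1 / (diff(range(t)) / 3)
    amp0 <- y[1] - y[length(y)]
    start <- list(rates = if (n_phases == 1) k0 else c(3 * k0, k0 / 3),
                  amplitudes = rep(amp0 / n_phases, n_phases),
                  baseline = y[length(y)])
  }
  par <- c(log(start$rates), start$amplitudes, start$baseline)
  names(par) <- c(paste0("log_k", seq_len(n_phases)),
                  paste0("a", seq_len(n_phases)), "c")
  model <- function(par) {
    k <- exp(par[paste0("log_k", seq_len(n_phases))])
    a <- par[paste0("a", seq_len(n_phases))]
    par[["c"]] + rowSums(vapply(seq_len(n_phases),
                                function(i) a[i] * exp(-k[i] * t),
                                numeric(length(t))))
  }
  fit <- minpack.lm::nls.lm(par = par, fn = function(p) y - model(p),
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  converged <- fit$info %in% 1:4
  if (!converged) flags <- c(flags, "non_convergence")
  est <- fit$par
  dof <- max(length(y) - length(est), 1)
  cv <- tryCatch(sum(fit$fvec^2) / dof * solve(fit$hessian),
                 error = function(e) NULL)
  ses <- if (!is.null(cv) && all(diag(cv) >= 0)) sqrt(diag(cv))
         else rep(NA_real_, length(est))
  names(ses) <- names(est)

  k <- exp(est[paste0("log_k", seq_len(n_phases))])
  k_se <- k * ses[paste0("log_k", seq_len(n_phases))]
  a <- est[paste0("a", seq_len(n_phases))]
  a_se <- ses[paste0("a", seq_len(n_phases))]
  ord <- order(k, decreasing = TRUE)
  if (n_phases == 2 && max(k) / min(k) < 1.2) {
    flags <- c(flags, "degenerate_rates")
    warning("double-exponential fit returned nearly equal rates")
  }
  structure(list(rates = unname(k[ord]), rates_se = unname(k_se[ord]),
                 amplitudes = unname(a[ord]), amplitudes_se = unname(a_se[ord]),
                 baseline = est[["c"]], baseline_se = ses[["c"]],
                 fitted = model(est), residuals = fit$fvec,
                 rss = sum(fit$fvec^2), converged = converged, flags = flags),
            class = "exp_fit")
}

#' Summarize observed rates by a cumulative-Gaussian fit
#'
#' The distribution of per-trace observed rate constants is summarized by
#' fitting the empirical cumulative distribution to a Gaussian CDF
#' \eqn{\Phi((x - \mu)/\sigma)}, returning the location and spread. Identical
#' rates give `sd = 0` directly.
#'
#' @param rates Numeric vector of observed rates, 1/s (at least 5).
#' @return List of class `rate_distribution`: `mean`, `sd`, `rates`.
#' @export
rate_distribution <- function(rates) {
  if (length(rates) < 5) stop("need at least 5 rates")
  if (stats::sd(rates) < .Machine$double.eps^0.5)
    return(structure(list(mean = rates[1], sd = 0, rates = rates),
                     class = "rate_distribution"))
  x <- sort(rates)
  # midpoint plotting positions avoid the degenerate 0/1 tails
  p_emp <- (seq_along(x) - 0.5) / length(x)
  fit <- minpack.lm::nls.lm(
    par = c(mu = mean(x), log_sigma = log(stats::sd(x))),
    fn = function(par) p_emp - stats::pnorm(x, par[["mu"]],
                                            exp(par[["log_sigma"]])),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  structure(list(mean = fit$par[["mu"]], sd = exp(fit$par[["log_sigma"]]),
                 rates = rates),
            class = "rate_distribution")
}

#' Association rate constant from the kobs concentration dependence
#'
#' Under pseudo-first-order association, the observed rate grows linearly
#' with titrant concentration, \eqn{k_{obs} = k_{on}[R] + k_{off}}; the
#' association rate constant is the slope of a (weighted) linear fit. A
#' lack-of-fit diagnostic compares the linear model against a quadratic
#' alternative: a significant curvature term flags a non-linear
#' concentration dependence, for which no `kon` should be reported.
#'
#' @param concentration Titrant concentrations, molar (>= 3 distinct values).
#' @param kobs Observed rates, 1/s.
#' @param kobs_sd Optional per-point SDs for weighting.
#' @param alpha Significance level of the curvature test (default 0.05).
#' @return List of class `kon_fit`: `kon` (M^-1 s^-1), `kon_se`,
#'   `kon_uM` (uM^-1 s^-1), `intercept` (+`_se`; the dissociation-limit
#'   intercept), `nonlinear` (logical), `curvature_p`, `flags` (may include
#'   `"nonlinear_dependence"` or `"non_binding"` for zero slope).
#' @export
kon_from_kobs <- function(concentration, kobs, kobs_sd = NULL, alpha = 0.05) {
  if (length(unique(concentration)) < 3)
    stop("need at least 3 distinct concentrations")
  w <- if (is.null(kobs_sd)) NULL else 1 / pmax(kobs_sd, 1e-12)^2
  d <- data.frame(c = concentration, k = kobs)
  lin <- stats::lm(k ~ c, data = d, weights = w)
  quad <- stats::lm(k ~ c + I(c^2), data = d, weights = w)
  an <- stats::anova(lin, quad)
  curvature_p <- an$`Pr(>F)`[2]
  sm <- summary(lin)
  kon <- sm$coefficients["c", "Estimate"]
  kon_se <- sm$coefficients["c", "Std. Error"]
  slope_p <- sm$coefficients["c", "Pr(>|t|)"]
  flags <- character()
  nonlinear <- is.finite(curvature_p) && curvature_p < alpha
  if (nonlinear) flags <- c(flags, "nonlinear_dependence")
  if (!is.finite(slope_p) || slope_p > alpha || kon <= 0)
    flags <- c(flags, "non_binding")
  structure(list(kon = kon, kon_se = kon_se,
                 kon_uM = kon * 1e-6, kon_uM_se = kon_se * 1e-6,
                 intercept = sm$coefficients["(Intercept)", "Estimate"],
                 intercept_se = sm$coefficients["(Intercept)", "Std. Error"],
                 nonlinear = nonlinear, curvature_p = curvature_p,
                 flags = flags),
            class = "kon_fit")
}

#' Dissociation rate constant from competitive displacement
#'
#' In a displacement experiment the observed dissociation rate rises with
#' competitor concentration toward a plateau equal to the intrinsic
#' dissociation rate. The plateau is estimated by fitting
#' \eqn{k_{obs}(c) = k_{off} - A e^{-c/c_0}} and reporting the asymptote.
#' A biphasic dissociation is handled per phase by passing each phase's
#' `kobs` series separately (or a matrix with one column per phase).
#'
#' @param concentration Competitor concentrations, molar (>= 4).
#' @param kobs Observed dissociation rates (vector, or matrix with one
#'   column per phase).
#' @return For a vector input, a list of class `koff_fit`: `koff`,
#'   `koff_se`, `amplitude`, `c0`, `flags` (includes `"no_plateau"` when the
#'   fitted c0 exceeds the concentration range). For a matrix, a list of
#'   such fits, one per column.
#' @export
koff_from_displacement <- function(concentration, kobs) {
  if (is.matrix(kobs))
    return(lapply(seq_len(ncol(kobs)), function(j)
      koff_from_displacement(concentration, kobs[, j])))
  if (length(unique(concentration)) < 4)
    stop("need at least 4 concentrations spanning the plateau")
  flags <- character()
  if (stats::sd(kobs) < .Machine$double.eps^0.5 * max(abs(kobs), 1)) {
    return(structure(list(koff = mean(kobs), koff_se = 0, amplitude = 0,
                          c0 = NA_real_, flags = "constant_series"),
                     class = "koff_fit"))
  }
  par <- c(koff = max(kobs), A = max(kobs) - min(kobs),
           log_c0 = log(stats::median(concentration)))
  fit <- minpack.lm::nls.lm(
    par = par,
    fn = function(p) kobs - (p[["koff"]] - p[["A"]] *
                               exp(-concentration / exp(p[["log_c0"]]))),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- fit$par
  dof <- max(length(kobs) - 3, 1)
  cv <- tryCatch(sum(fit$fvec^2) / dof * solve(fit$hessian),
                 error = function(e) NULL)
  koff_se <- if (!is.null(cv) && cv[1, 1] >= 0) sqrt(cv[1, 1]) else NA_real_
  c0 <- exp(est[["log_c0"]])
  if (c0 > 2 * max(concentration)) {
    flags <- c(flags, "no_plateau")
    warning("plateau not reached within the concentration range")
  }
  structure(list(koff = est[["koff"]], koff_se = koff_se,
                 amplitude = est[["A"]], c0 = c0, flags = flags),
            class = "koff_fit")
}
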