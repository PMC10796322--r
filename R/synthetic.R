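#' Synthetic-data generators
#'
#' Every generator in this file produces one of the input kinds the analysis
#' stages consume, from a known ground-truth parameter set, with Gaussian
#' measurement noise (multinomial sampling for screen counts) and a fixed
#' seed. The generating parameters, noise model and seed are attached to the
#' result as the `"ground_truth"` attribute so recovery can be checked
#' downstream; regeneration under the same seed is bit-identical.
#'
#' @name synthetic_data
#' @keywords internal
NULL

.attach_truth <- function(x, truth) {
  attr(x, "ground_truth") <- truth
  x
}

#' Ground truth attached to a synthetic dataset
#' @param x A generated object.
#' @return The generating parameter list (with `seed` and noise settings).
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Generate a synthetic ITC experiment
#'
#' Heats come from the forward single-site model of [wiseman_isotherm()]
#' plus i.i.d. Gaussian noise. The default design mirrors a typical
#' high-affinity titration: 15 uM receptor in the cell, a 10x syringe, one
#' discarded 0.5 uL pre-injection followed by 18 x 2.0 uL injections. The
#' default parameters describe a sub-micromolar enthalpy-driven interaction
#' (Kd 510 nM, dH -50.7 kJ/mol, N 0.98).
#'
#' @param params A [thermo_params()] (defaults as above).
#' @param cell_concentration,syringe_concentration,cell_volume,
#'   injection_volumes,temperature Design; see [itc_experiment()].
#' @param offset Constant dilution heat per injection, uJ.
#' @param noise_sd Gaussian heat noise SD in uJ (0 for noiseless).
#' @param seed RNG seed.
#' @return An [itc_experiment()] with `measured_heats`, carrying a
#'   `ground_truth` attribute.
#' @export
gen_itc <- function(params = thermo_params(0.98, 510e-9, -50.7),
                    cell_concentration = 15e-6,
                    syringe_concentration = 150e-6,
                    cell_volume = 200e-6,
                    injection_volumes = c(0.5e-6, rep(2.0e-6, 18)),
                    temperature = .T_STANDARD,
                    offset = 0, noise_sd = 0, seed = 20240118) {
  experiment <- itc_experiment(cell_concentration, syringe_concentration,
                               cell_volume, injection_volumes,
                               temperature = temperature)
  q <- wiseman_isotherm(params, experiment, offset = offset)
  if (noise_sd > 0)
    q <- q + .with_seed(seed, stats::rnorm(length(q), 0, noise_sd))
  experiment$measured_heats <- q
  .attach_truth(experiment,
                list(params = params, offset = offset,
                     noise_sd = noise_sd, seed = seed))
}

#' Generate a multi-temperature thermodynamic series
#'
#' Produces fitted-parameter sets across temperatures with
#' \eqn{\Delta H(T) = \Delta H_{ref} + \Delta C_p (T - T_{ref})} and a
#' smooth free energy (\eqn{\Delta G} held at its reference value, a good
#' local approximation when entropy-enthalpy compensation is strong), plus
#' optional Gaussian noise on each derived quantity.
#'
#' @param dh_ref Enthalpy at `t_ref`, kJ/mol.
#' @param dcp Heat-capacity change, kJ/mol/K.
#' @param kd_ref Dissociation constant at `t_ref`, molar.
#' @param temperatures Kelvin (>= 3).
#' @param t_ref Reference temperature, K.
#' @param noise_sd Gaussian SD added to dH and -TdS, kJ/mol.
#' @param seed RNG seed.
#' @return A [temperature_series()] with a `ground_truth` attribute.
#' @export
gen_temperature_series <- function(dh_ref = -50.7, dcp = -2.0,
                                   kd_ref = 510e-9,
                                   temperatures = seq(288.15, 308.15, by = 5),
                                   t_ref = .T_STANDARD,
                                   noise_sd = 0, seed = 20240118) {
  if (length(temperatures) < 3) stop("need at least 3 temperatures")
  dg_ref <- dg_from_kd(kd_ref, t_ref)
  eps <- if (noise_sd > 0)
    .with_seed(seed, stats::rnorm(2 * length(temperatures), 0, noise_sd))
  else rep(0, 2 * length(temperatures))
  params <- lapply(seq_along(temperatures), function(i) {
    tk <- temperatures[i]
    dh <- dh_ref + dcp * (tk - t_ref) + eps[2 * i - 1]
    tds <- dg_ref - (dh_ref + dcp * (tk - t_ref)) + eps[2 * i]
    kd <- kd_from_dg(dh + tds, tk)
    thermo_params(1, kd, dh, temperature = tk, tds_neg = tds, tol = Inf)
  })
  .attach_truth(temperature_series(params),
                list(dh_ref = dh_ref, dcp = dcp, kd_ref = kd_ref,
                     t_ref = t_ref, noise_sd = noise_sd, seed = seed))
}

#' Generate synthetic CEST profiles
#'
#' Simulates intensity-ratio profiles for a group of residues sharing the
#' exchange kinetics of `model` but each with its own bound-state shift(s),
#' at one or more saturation field strengths, with Gaussian intensity noise.
#' The default fields (25, 12.5, 6.25 Hz) are a standard three-field design.
#'
#' @param model An [exchange_model()] providing populations, kex and
#'   relaxation; its own offsets are used when `dw_by_residue` is `NULL`.
#' @param dw_by_residue Optional named list: per residue, a numeric vector
#'   of minor-state offsets (ppm), length `n_states - 1`.
#' @param b1_fields Saturation fields, Hz.
#' @param offsets_ppm Carrier offsets sampled, ppm.
#' @param t_sat Saturation time, s.
#' @param freq_mhz Spectrometer frequency, MHz.
#' @param noise_sd Gaussian SD on the intensity ratio.
#' @param seed RNG seed.
#' @return Long-format data.frame (`residue`, `b1_hz`, `offset_ppm`,
#'   `intensity_ratio`) with a `ground_truth` attribute; ready for
#'   [fit_cest()].
#' @export
gen_cest <- function(model, dw_by_residue = NULL,
                     b1_fields = c(25, 12.5, 6.25),
                     offsets_ppm = seq(-8, 8, by = 0.4),
                     t_sat = 0.5, freq_mhz = 81.1,
                     noise_sd = 0, seed = 20240118) {
  stopifnot(inherits(model, "exchange_model"))
  if (is.null(dw_by_residue))
    dw_by_residue <- list(res1 = model$offsets_ppm[-1])
  rows <- list()
  for (res in names(dw_by_residue)) {
    m <- exchange_model(model$populations,
                        c(0, dw_by_residue[[res]]), model$kex,
                        r1 = model$r1, r2 = model$r2)
    for (b1 in b1_fields) {
      sim <- simulate_cest(m, b1, offsets_ppm, t_sat, freq_mhz)
      rows[[length(rows) + 1]] <- data.frame(
        residue = res, b1_hz = b1, offset_ppm = sim$offset_ppm,
        intensity_ratio = sim$intensity_ratio)
    }
  }
  out <- do.call(rbind, rows)
  if (noise_sd > 0)
    out$intensity_ratio <- out$intensity_ratio +
      .with_seed(seed, stats::rnorm(nrow(out), 0, noise_sd))
  .attach_truth(out, list(populations = model$populations, kex = model$kex,
                          dw_by_residue = dw_by_residue, r1 = model$r1,
                          r2 = model$r2, t_sat = t_sat, freq_mhz = freq_mhz,
                          noise_sd = noise_sd, seed = seed))
}

#' Generate stopped-flow trace sets
#'
#' Association traces follow pseudo-first-order kinetics with
#' \eqn{k_{obs} = k_{on} [R] + k_{off}}; displacement (dissociation) traces
#' are mono- or biphasic exponential decays. Each condition yields
#' `n_replicates` traces whose individual rates are jittered by
#' `rate_scatter` (relative SD across replicates, emulating trace-to-trace
#' variability) before Gaussian signal noise is added.
#'
#' @param kind `"association"` or `"dissociation"`.
#' @param kon Association rate constant, M^-1 s^-1 (association only).
#' @param koff Dissociation rate constant(s), 1/s: one value for monophasic,
#'   two for biphasic dissociation.
#' @param concentrations Condition concentrations, molar (receptor for
#'   association; competitor for dissociation, where the observed rate
#'   approaches `koff` with saturation constant `c_half`).
#' @param c_half Competitor concentration scale of the displacement
#'   saturation (molar; dissociation only).
#' @param amplitude,baseline Signal amplitude(s) and baseline, a.u.
#' @param n_replicates Traces per condition (default 20).
#' @param n_points,t_max Trace sampling (points, end time s).
#' @param noise_sd Gaussian signal noise SD, a.u.
#' @param rate_scatter Relative SD of per-trace rate jitter.
#' @param seed RNG seed.
#' @return List of [kinetic_trace()] objects with a `ground_truth`
#'   attribute; element names encode condition and replicate.
#' @export
gen_traces <- function(kind = c("association", "dissociation"),
                       kon = 29e6, koff = 15,
                       concentrations = c(0.5, 1, 2, 4, 8) * 1e-6,
                       c_half = 1e-6,
                       amplitude = 1, baseline = 0.2,
                       n_replicates = 20, n_points = 200, t_max = NULL,
                       noise_sd = 0, rate_scatter = 0,
                       seed = 20240118) {
  kind <- match.arg(kind)
  n_phases <- if (kind == "dissociation") length(koff) else 1
  amplitude <- rep_len(amplitude, n_phases)
  .with_seed(seed, {
    traces <- list()
    for (conc in concentrations) {
      rates_true <- if (kind == "association") kon * conc + koff[1]
                    else koff * (1 - exp(-conc / c_half))
      for (rep_i in seq_len(n_replicates)) {
        k <- rates_true * (1 + if (rate_scatter > 0)
          stats::rnorm(n_phases, 0, rate_scatter) else 0)
        k <- pmax(k, 1e-6)
        tm <- if (is.null(t_max)) 5 / min(k) else t_max
        tt <- seq(0, tm, length.out = n_points)
        y <- baseline
        for (ph in seq_len(n_phases))
          y <- y + amplitude[ph] * exp(-k[ph] * tt)
        if (noise_sd > 0) y <- y + stats::rnorm(n_points, 0, noise_sd)
        traces[[sprintf("c%.4g_r%02d", conc * 1e6, rep_i)]] <-
          kinetic_trace(tt, y, condition = conc, dead_time = 0)
      }
    }
    .attach_truth(traces,
                  list(kind = kind, kon = kon, koff = koff,
                       concentrations = concentrations, c_half = c_half,
                       n_replicates = n_replicates, noise_sd = noise_sd,
                       rate_scatter = rate_scatter, seed = seed))
  })
}

#' Generate a synthetic NMR titration series
#'
#' Per-residue CSP trajectories follow the exact single-site quadratic
#' isotherm (ligand depletion included); shift noise is Gaussian on both
#' dimensions. The direction of each residue's shift change is randomized
#' but its magnitude saturates at the residue's `csp_max`.
#'
#' @param truth data.frame with columns `residue`, `kd` (molar; `Inf` for a
#'   non-binding residue) and `csp_max` (ppm).
#' @param ligand_totals Titration points, molar (0 is added automatically
#'   as the reference).
#' @param receptor_total Constant receptor concentration, molar.
#' @param noise_sd Gaussian shift noise SD, ppm (applied to dH; the dN noise
#'   is scaled by 1/0.154 so the combined-CSP noise stays comparable).
#' @param seed RNG seed.
#' @return A [titration_series()] with a `ground_truth` attribute.
#' @export
gen_titration <- function(truth,
                          ligand_totals = c(50, 100, 200, 400, 800, 1600) * 1e-6,
                          receptor_total = 125e-6,
                          noise_sd = 0, seed = 20240118) {
  stopifnot(all(c("residue", "kd", "csp_max") %in% names(truth)))
  ligand_totals <- sort(unique(c(0, ligand_totals)))
  .with_seed(seed, {
    rows <- do.call(rbind, lapply(seq_len(nrow(truth)), function(i) {
      fb <- if (is.finite(truth$kd[i]))
        .bound_fraction_quadratic(ligand_totals, receptor_total, truth$kd[i])
      else rep(0, length(ligand_totals))
      csp_true <- truth$csp_max[i] * fb
      # split the combined CSP over the two dimensions at a fixed angle
      ang <- stats::runif(1, 0.2, 1.35)
      d_h <- csp_true * cos(ang)
      d_n <- csp_true * sin(ang) / 0.154
      if (noise_sd > 0) {
        nz <- ligand_totals > 0   # the reference point defines zero shift
        d_h[nz] <- d_h[nz] + stats::rnorm(sum(nz), 0, noise_sd)
        d_n[nz] <- d_n[nz] + stats::rnorm(sum(nz), 0, noise_sd / 0.154)
      }
      data.frame(residue = truth$residue[i], ligand = ligand_totals,
                 d_h = d_h, d_n = d_n,
                 intensity = rep(1, length(ligand_totals)))
    }))
    .attach_truth(titration_series(rows, receptor_total),
                  list(truth = truth, receptor_total = receptor_total,
                       noise_sd = noise_sd, seed = seed))
  })
}

#' Generate a synthetic activation-domain tiling screen
#'
#' Draws multinomial sorting-bin counts per tile: a tile's bin probabilities
#' interpolate between a bottom-bin-heavy profile (activity 0) and a
#' top-bin-heavy profile (activity 1) according to its true activity, so
#' expected screen scores are monotone in activity.
#'
#' @param activity Numeric vector in \[0, 1\], one value per tile
#'   (1 = maximally activating).
#' @param tiles data.frame from [tile_sequence()] matching `activity`.
#' @param depth Total reads per tile (multinomial size).
#' @param n_bins Number of sorting bins.
#' @param bin_medians Per-bin median activity ratios (default `1:n_bins`).
#' @param concentration Dirichlet-like sharpness of the bin profiles; larger
#'   values concentrate reads in fewer bins.
#' @param seed RNG seed.
#' @return A [tile_screen()] with a `ground_truth` attribute.
#' @export
gen_tilescreen <- function(activity, tiles, depth = 2000, n_bins = 8,
                           bin_medians = seq_len(n_bins),
                           concentration = 4, seed = 20240118) {
  if (length(activity) != nrow(tiles))
    stop("'activity' must have one value per tile")
  if (any(activity < 0 | activity > 1)) stop("'activity' must be in [0, 1]")
  bin_pos <- seq(0, 1, length.out = n_bins)
  .with_seed(seed, {
    counts <- t(vapply(activity, function(a) {
      w <- exp(-concentration * abs(bin_pos - a) * n_bins / 2)
      as.numeric(stats::rmultinom(1, depth, w / sum(w)))
    }, numeric(n_bins)))
    .attach_truth(tile_screen(tiles, counts, bin_medians),
                  list(activity = activity, depth = depth, n_bins = n_bins,
                       concentration = concentration, seed = seed))
  })
}
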