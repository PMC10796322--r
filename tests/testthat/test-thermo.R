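test_that("free energy from Kd follows RT*ln(Kd) and rejects bad input", {
  expect_equal(dg_from_kd(1.0), 0)
  expect_equal(dg_from_kd(540e-9), 8.314 * 298.15 * log(540e-9) / 1000)
  expect_lt(dg_from_kd(540e-9), 0)
  # inverse identity
  expect_equal(kd_from_dg(dg_from_kd(3.3e-7)), 3.3e-7)
  expect_error(dg_from_kd(0), "positive")
  expect_error(dg_from_kd(-1e-6), "positive")
  expect_error(dg_from_kd(1e-6, temperature = -5), "positive")
})

test_that("thermodynamic closure holds for every complete reference row", {
  tab <- thermo_reference_table(complete_only = TRUE)
  expect_gte(nrow(tab), 15)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    dg_kd <- dg_from_kd(row$kd_nm * 1e-9)
    # combined reported precision: dG rounding + Kd error propagated into dG
    tol_kd <- row$dg_sd + 8.314 * 298.15 / 1000 * row$kd_sd_nm / row$kd_nm + 0.05
    expect_lt(abs(dg_kd - row$dg), tol_kd, label = row$fragment)
    dg_hs <- dg_from_dh_tds(row$dh, row$tds_neg)
    tol_hs <- row$dg_sd + row$dh_sd + row$tds_sd + 0.1
    expect_lt(abs(dg_hs - row$dg), tol_hs, label = row$fragment)
  }
})

test_that("thermo_params enforces internal consistency", {
  p <- thermo_params(1.0, 510e-9, -50.7)
  expect_equal(p$dg, p$dh + p$tds_neg)
  expect_error(thermo_params(1, 510e-9, -50.7, dg = -20), "inconsistent")
  expect_error(thermo_params(1, -1e-9, -50), "positive")
})

test_that("forward isotherm matches the bisection equilibrium oracle", {
  cases <- list(
    list(n = 1.0, kd = 510e-9, dh = -50.7, cell = 15e-6),
    list(n = 0.86, kd = 6e-6, dh = -54.0, cell = 60e-6),
    list(n = 1.2, kd = 5e-8, dh = 30, cell = 5e-6))
  for (cs in cases) {
    pars <- thermo_params(cs$n, cs$kd, cs$dh)
    experiment <- itc_experiment(cs$cell, 10 * cs$cell)
    q <- wiseman_isotherm(pars, experiment, offset = 0.4)
    q_oracle <- oracle_itc_heats(cs$n, cs$kd, cs$dh, cs$cell, 10 * cs$cell,
                                 200e-6, c(0.5e-6, rep(2e-6, 18)), offset = 0.4)
    expect_lt(max(abs(q - q_oracle) / pmax(abs(q_oracle), 1e-3)), 1e-3)
  }
})

test_that("zero-enthalpy isotherm returns only the offset", {
  pars <- thermo_params(1, 510e-9, 0)
  q <- wiseman_isotherm(pars, itc_experiment(15e-6, 150e-6), offset = 1.5)
  expect_equal(q, rep(1.5, 19))
})

test_that("cumulative heat saturates at the cell content heat", {
  # huge ligand excess: everything in the cell ends up bound
  pars <- thermo_params(1, 1e-9, -50)
  experiment <- itc_experiment(5e-6, 500e-6, cell_volume = 200e-6,
                               injection_volumes = rep(2e-6, 30))
  q <- wiseman_isotherm(pars, experiment, dilution = "none")
  q_total <- sum(q) * 1e-6                     # uJ -> J
  expect_equal(q_total, -50 * 1000 * 200e-6 * 5e-6, tolerance = 0.05)
})

test_that("noiseless round-trip recovers generating parameters to <0.5%", {
  for (kd in c(150e-9, 510e-9, 2e-6)) {       # c-values ~ 7-100
    experiment <- gen_itc(params = thermo_params(0.98, kd, -50.7),
                          offset = 0.3, noise_sd = 0)
    fit <- fit_itc(experiment)
    expect_true(fit$converged)
    expect_lt(abs(fit$params$kd - kd) / kd, 0.005)
    expect_lt(abs(fit$params$n_value - 0.98) / 0.98, 0.005)
    expect_lt(abs(fit$params$dh - (-50.7)) / 50.7, 0.005)
  }
})

test_that("all-zero heats yield a flagged, unidentifiable fit", {
  experiment <- itc_experiment(15e-6, 150e-6,
                               measured_heats = rep(0, 19))
  fit <- fit_itc(experiment)
  expect_equal(fit$params$dh, 0)
  expect_true("kd_unidentifiable" %in% fit$flags)
})

test_that("extreme c-value is annotated", {
  experiment <- gen_itc(params = thermo_params(1, 50e-6, -40),
                        cell_concentration = 15e-6,
                        syringe_concentration = 150e-6)
  fit <- fit_itc(experiment)
  expect_true("c_value_out_of_range" %in% fit$flags)
})

test_that("heat-capacity fit is exact on noiseless linear series", {
  series <- gen_temperature_series(dcp = -2.0, noise_sd = 0)
  fit <- suppressWarnings(fit_dcp(series))       # exact-fit lm warning
  expect_equal(fit$dcp, -2.0, tolerance = 1e-10)
  # constant enthalpy: zero heat capacity
  s0 <- gen_temperature_series(dcp = 0, noise_sd = 0)
  expect_equal(suppressWarnings(fit_dcp(s0))$dcp, 0, tolerance = 1e-10)
  expect_error(fit_dcp(temperature_series(list(
    thermo_params(1, 5e-7, -50, temperature = 288.15),
    thermo_params(1, 5e-7, -52, temperature = 298.15)))), "3 temperatures")
})

test_that("dCp confidence interval attains near-nominal coverage", {
  hits <- 0L; n_rep <- 400L
  for (i in seq_len(n_rep)) {
    series <- gen_temperature_series(dcp = -2.0, noise_sd = 1.0, seed = 5000 + i)
    fit <- fit_dcp(series)
    ci <- fit$dcp_ci
    if (ci[1] <= -2.0 && -2.0 <= ci[2]) hits <- hits + 1L
  }
  coverage <- hits / n_rep
  expect_gt(coverage, 0.90)   # nominal 0.95; binomial SE ~ 0.011
  expect_lt(coverage, 0.99)
})

test_that("Spolar-Record evaluation matches an independent hand calculation", {
  res <- spolar_record_id(dcp = -2.0, ds_assoc = -49.6)
  # spreadsheet-style recomputation with the documented constants
  ds_he_hand <- 1.35 * (-2.0 * 1000) * log(298.15 / 386)
  ds_conf_hand <- -49.6 - ds_he_hand - (-209)
  expect_equal(res$ds_he, ds_he_hand)
  expect_equal(res$ds_conf, ds_conf_hand)
  expect_equal(res$r_th, ds_conf_hand / (-23.4))
  # zero conformational entropy maps to zero residues folding
  ds_zero <- ds_he_hand + (-209)
  expect_equal(spolar_record_id(-2.0, ds_zero)$r_th, 0)
})

test_that("Spolar-Record Monte Carlo SD vanishes with zero input error and scales with it", {
  r0 <- spolar_record_id(-2.0, -49.6, dcp_se = 0, ds_assoc_se = 0)
  expect_identical(r0$r_th_sd, 0)
  r1 <- spolar_record_id(-2.0, -49.6, dcp_se = 0.1, ds_assoc_se = 5)
  r2 <- spolar_record_id(-2.0, -49.6, dcp_se = 0.2, ds_assoc_se = 10)
  expect_gt(r1$r_th_sd, 0)
  # linear small-error scaling: doubling input SEs ~ doubles the output SD
  expect_equal(r2$r_th_sd / r1$r_th_sd, 2, tolerance = 0.1)
  # reproducible under the fixed seed
  expect_identical(r1$r_th_sd,
                   spolar_record_id(-2.0, -49.6, dcp_se = 0.1,
                                    ds_assoc_se = 5)$r_th_sd)
  expect_error(spolar_record_id(-2.0, -49.6, constants = list(t_he_zero = 386)),
               "not set")
})
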