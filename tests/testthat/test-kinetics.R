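test_that("kinetic traces validate and truncate the dead time", {
  tt <- seq(0, 1, length.out = 100)
  tr <- kinetic_trace(tt, exp(-5 * tt), dead_time = 0.002)
  expect_true(all(tr$time >= 0.002))
  expect_error(kinetic_trace(c(0, 0.1, 0.1, 0.2), rep(1, 4), dead_time = 0),
               "increasing")
  expect_error(kinetic_trace(seq(0, 1, length.out = 10), rep(1, 10),
                             dead_time = 0), "20 points")
})

test_that("flat traces fit with zero amplitude", {
  tr <- kinetic_trace(seq(0, 1, length.out = 50), rep(2.5, 50), dead_time = 0)
  fit <- fit_exponential(tr, 1)
  expect_equal(fit$amplitudes, 0)
  expect_equal(fit$baseline, 2.5)
})

test_that("single- and double-exponential rates are recovered from noisy traces", {
  set.seed(100)
  tt <- seq(0, 1, length.out = 300)
  y1 <- 0.2 + 1.0 * exp(-5 * tt) + rnorm(300, 0, 0.01)
  f1 <- fit_exponential(kinetic_trace(tt, y1, dead_time = 0), 1)
  expect_lt(abs(f1$rates - 5) / 5, 0.02)

  y2 <- 0.2 + 0.8 * exp(-25 * tt) + 0.6 * exp(-5 * tt) + rnorm(300, 0, 0.005)
  f2 <- fit_exponential(kinetic_trace(tt, y2, dead_time = 0), 2)
  expect_lt(abs(f2$rates[1] - 25) / 25, 0.05)
  expect_lt(abs(f2$rates[2] - 5) / 5, 0.05)
  expect_true(f2$rates[1] > f2$rates[2])   # sorted descending
})

test_that("the biphasic model is preferred for biphasic decays by residuals", {
  set.seed(5)
  tt <- seq(0, 2, length.out = 400)
  y <- 0.1 + 0.7 * exp(-20 * tt) + 0.7 * exp(-2 * tt) + rnorm(400, 0, 0.004)
  tr <- kinetic_trace(tt, y, dead_time = 0)
  f1 <- fit_exponential(tr, 1)
  f2 <- fit_exponential(tr, 2)
  expect_lt(f2$rss, f1$rss / 5)
  # while a genuinely monophasic decay gains almost nothing from 2 phases
  ym <- 0.1 + 1.0 * exp(-5 * tt) + rnorm(400, 0, 0.004)
  trm <- kinetic_trace(tt, ym, dead_time = 0)
  g1 <- fit_exponential(trm, 1)
  g2 <- suppressWarnings(fit_exponential(trm, 2))
  expect_gt(g2$rss, g1$rss * 0.9)
})

test_that("rate distributions summarize by cumulative-Gaussian fit", {
  expect_error(rate_distribution(c(1, 2)), "at least 5")
  rid <- rate_distribution(rep(7, 10))
  expect_equal(rid$mean, 7); expect_identical(rid$sd, 0)
  set.seed(9)
  x <- rnorm(100, 50, 4)
  rd <- rate_distribution(x)
  expect_equal(rd$mean, mean(x), tolerance = 3 * 4 / sqrt(100) / 50)
  expect_equal(rd$sd, 4, tolerance = 0.3)
})

test_that("small-sample rate summaries cover the true mean", {
  # replicate count at the lower end of stopped-flow practice (n = 19)
  hits <- 0L; n_rep <- 1000L
  set.seed(11)
  for (i in seq_len(n_rep)) {
    x <- rnorm(19, 30, 3)
    rd <- rate_distribution(x)
    # nominal ~95% interval for the location
    half <- 1.96 * rd$sd / sqrt(19)
    if (abs(rd$mean - 30) < half) hits <- hits + 1L
  }
  expect_gt(hits / n_rep, 0.88)
})

test_that("kon comes from the slope of a linear kobs dependence", {
  conc <- c(1, 2, 4, 6, 8) * 1e-6
  kobs <- 29 * (conc * 1e6) + 15          # slope 29 uM^-1 s^-1
  fit <- suppressWarnings(kon_from_kobs(conc, kobs))  # exact fit warning
  expect_equal(fit$kon_uM, 29, tolerance = 1e-10)
  expect_equal(fit$intercept, 15, tolerance = 1e-8)
  expect_false(fit$nonlinear)
  # zero slope flags non-binding
  f0 <- kon_from_kobs(conc, rep(15, 5) + c(0.01, -0.01, 0, 0.01, -0.01))
  expect_true("non_binding" %in% f0$flags)
  expect_error(kon_from_kobs(c(1e-6, 2e-6), c(1, 2)), "3 distinct")
})

test_that("saturating kobs dependence raises the nonlinearity flag", {
  conc <- c(0.5, 1, 2, 4, 8, 16) * 1e-6
  kobs_hyp <- 400 * conc / (conc + 2e-6) + 10    # hyperbolic saturation
  fit <- kon_from_kobs(conc, kobs_hyp)
  expect_true(fit$nonlinear)
  expect_true("nonlinear_dependence" %in% fit$flags)
})

test_that("kon recovery is unbiased under Gaussian kobs noise", {
  set.seed(21)
  conc <- c(1, 2, 4, 6, 8) * 1e-6
  est <- replicate(500, {
    kobs <- 29 * (conc * 1e6) + 15 + rnorm(5, 0, 3)
    kon_from_kobs(conc, kobs)$kon_uM
  })
  expect_lt(abs(mean(est) - 29) / 29, 0.02)
})

test_that("koff is the displacement plateau", {
  conc <- c(0.5, 1, 2, 4, 8, 16, 32) * 1e-6
  kobs <- 12 - 9 * exp(-conc / 2e-6)
  fit <- koff_from_displacement(conc, kobs)
  expect_equal(fit$koff, 12, tolerance = 0.03)
  # constant series: koff equals the constant with zero amplitude
  fc <- koff_from_displacement(conc, rep(8, 7))
  expect_equal(fc$koff, 8); expect_equal(fc$amplitude, 0)
  # plateau far beyond the range: warning flag
  expect_warning(fp <- koff_from_displacement(conc, 12 - 9 * exp(-conc / 5e-4)),
                 "plateau")
  expect_true("no_plateau" %in% fp$flags)
})

test_that("biphasic displacement returns one koff per phase", {
  conc <- c(0.5, 1, 2, 4, 8, 16, 32) * 1e-6
  kobs <- cbind(fast = 40 - 30 * exp(-conc / 2e-6),
                slow = 6 - 4 * exp(-conc / 2e-6))
  fits <- koff_from_displacement(conc, kobs)
  expect_length(fits, 2)
  expect_equal(fits[[1]]$koff, 40, tolerance = 0.03)
  expect_equal(fits[[2]]$koff, 6, tolerance = 0.03)
})

test_that("trace-level pipeline: generated replicates to kon within a few percent", {
  concs <- c(1, 2, 4, 8) * 1e-6
  traces <- gen_traces("association", kon = 29e6, koff = 15,
                       concentrations = concs, n_replicates = 19,
                       n_points = 120, noise_sd = 0.01, rate_scatter = 0.03,
                       seed = 33)
  per_cond <- split(traces, vapply(traces, `[[`, numeric(1), "condition"))
  summ <- lapply(per_cond, function(trs) {
    rates <- vapply(trs, function(tr) fit_exponential(tr, 1)$rates[1],
                    numeric(1))
    rate_distribution(rates)
  })
  kobs <- vapply(summ, `[[`, numeric(1), "mean")
  ksd <- vapply(summ, `[[`, numeric(1), "sd")
  fit <- kon_from_kobs(sort(concs), kobs[order(as.numeric(names(kobs)))],
                       kobs_sd = ksd[order(as.numeric(names(ksd)))])
  expect_equal(fit$kon_uM, 29, tolerance = 0.05)
  # kinetic-thermodynamic consistency: koff/kon gives back the generating Kd
  kd_kin <- fit$intercept / fit$kon
  expect_equal(kd_kin, 15 / 29e6, tolerance = 0.25)
})
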