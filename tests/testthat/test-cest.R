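test_that("exchange model validates populations, rates and topology", {
  expect_error(exchange_model(c(0.9, 0.2), c(0, 3), 50), "sum to 1")
  expect_error(exchange_model(c(0.95, 0.05), c(0, 3), c(50, 60)),
               "one rate per minor state")
  expect_error(exchange_model(c(0.95, 0.05), c(0, 3), -5), "non-negative")
  m <- exchange_model(c(0.9, 0.06, 0.04), c(0, 3, -4), c(40, 80))
  K <- proswitch:::.exchange_matrix(m)
  # columns of a rate matrix sum to zero (conservation)
  expect_equal(colSums(K), rep(0, 3), tolerance = 1e-12)
  # detailed balance on each edge
  expect_equal(K[2, 1] * m$populations[1], K[1, 2] * m$populations[2])
  expect_equal(K[3, 1] * m$populations[1], K[1, 3] * m$populations[3])
  # star topology: no bound-bound exchange
  expect_identical(K[2, 3], 0); expect_identical(K[3, 2], 0)
})

test_that("single state without exchange gives one dip at its offset", {
  m <- exchange_model(1, 0, numeric(0), r1 = 1.5, r2 = 10)
  sim <- simulate_cest(m, 25, seq(-5, 5, 0.25), t_sat = 0.4)
  # dip centred on the state's offset (exact on-resonance point can retain
  # nutation signal; the minimum sits within the RF linewidth of 0)
  expect_lte(abs(sim$offset_ppm[which.min(sim$intensity_ratio)]), 0.3)
  expect_equal(sim$intensity_ratio, rev(sim$intensity_ratio))  # symmetric
  # far off resonance the ratio returns to ~1
  expect_equal(sim$intensity_ratio[1], 1, tolerance = 0.02)
  expect_equal(sim$intensity_ratio[nrow(sim)], 1, tolerance = 0.02)
})

test_that("vanishing B1 produces a flat profile with no minor dip", {
  m <- exchange_model(c(0.95, 0.05), c(0, 3), 50)
  sim <- simulate_cest(m, 1e-4, seq(-5, 5, 0.5), t_sat = 0.4)
  expect_lt(diff(range(sim$intensity_ratio)), 1e-4)
  expect_equal(mean(sim$intensity_ratio), 1, tolerance = 1e-3)
})

test_that("matrix-exponential propagation equals ODE integration on random models", {
  skip_if_not_installed("deSolve")
  set.seed(314)
  worst <- 0
  for (i in 1:40) {
    n <- sample(2:3, 1)
    p_minor <- runif(n - 1, 0.01, 0.10)
    pops <- c(1 - sum(p_minor), p_minor)
    offs <- c(0, runif(n - 1, -6, 6))
    kex <- runif(n - 1, 10, 300)
    r1 <- runif(1, 0.5, 3); r2 <- runif(1, 5, 30)
    b1 <- sample(c(6.25, 12.5, 25), 1)
    carrier <- runif(1, -7, 7)
    t_sat <- runif(1, 0.2, 0.6)
    m <- exchange_model(pops, offs, kex, r1 = r1, r2 = r2)
    got <- simulate_cest(m, b1, carrier, t_sat)$intensity_ratio
    want <- oracle_cest_ratio(pops, offs, kex, r1, r2, b1, carrier,
                              t_sat, 81.1)
    worst <- max(worst, abs(got - want))
  }
  expect_lt(worst, 1e-6)
})

test_that("minor-dip depth grows with minor population in slow exchange", {
  depth <- vapply(c(0.02, 0.04, 0.06, 0.08), function(p) {
    m <- exchange_model(c(1 - p, p), c(0, 3.5), 50)
    sim <- simulate_cest(m, 12.5, 3.5, t_sat = 0.5)
    1 - sim$intensity_ratio
  }, numeric(1))
  expect_true(all(diff(depth) > 0))
})

test_that("normalization holds far off resonance", {
  m <- exchange_model(c(0.95, 0.05), c(0, 2), 50, r1 = 0.5, r2 = 10)
  # >= 50 linewidths away from every state, short saturation
  sim <- simulate_cest(m, 6.25, c(-400, 400), t_sat = 0.2)
  expect_equal(sim$intensity_ratio, c(1, 1), tolerance = 0.01)
})

test_that("two-state global fit recovers populations and shifts", {
  truth_p <- 0.036
  m <- exchange_model(c(1 - truth_p, truth_p), c(0, 3.5), kex = 60)
  prof <- gen_cest(m, dw_by_residue = list(G1 = 3.5, G2 = -2.5),
                   b1_fields = c(25, 12.5, 6.25),
                   offsets_ppm = seq(-7, 7, 0.5),
                   noise_sd = 0.01, seed = 7)
  fit <- fit_cest(prof, n_states = 2, noise_sd = 0.01)
  expect_true(fit$converged)
  expect_lt(abs(fit$populations - truth_p), 0.003)
  expect_equal(fit$kex, 60, tolerance = 0.15)
  dw <- fit$dw$dw_ppm[order(fit$dw$residue)]
  expect_equal(dw, c(3.5, -2.5), tolerance = 0.02)
})

test_that("noiseless two-state fit recovers parameters to optimizer tolerance", {
  m <- exchange_model(c(0.95, 0.05), c(0, 4), kex = 80)
  prof <- gen_cest(m, dw_by_residue = list(r1 = 4),
                   b1_fields = c(25, 12.5), offsets_ppm = seq(-7, 7, 0.5),
                   noise_sd = 0)
  fit <- fit_cest(prof, n_states = 2, noise_sd = 0.005)
  expect_lt(abs(fit$populations - 0.05), 1e-4)
  expect_lt(abs(fit$kex - 80) / 80, 1e-3)
})

test_that("three-state star fit separates the two bound states", {
  m <- exchange_model(c(1 - 0.047, 0.027, 0.020), c(0, 3.0, -4.0),
                      kex = c(40, 80))
  prof <- gen_cest(m, dw_by_residue = list(F1 = c(3.0, -4.0),
                                           E2 = c(2.2, 5.5)),
                   b1_fields = c(25, 12.5, 6.25),
                   offsets_ppm = seq(-8, 8, 0.5), noise_sd = 0.01, seed = 11)
  fit <- fit_cest(prof, n_states = 3, noise_sd = 0.01,
                  start = list(p = c(0.03, 0.03), kex = c(50, 50),
                               dw = list(F1 = c(3.2, -4.2), E2 = c(2.4, 5.3))))
  expect_true(fit$converged)
  expect_equal(sum(fit$populations), 0.047, tolerance = 0.1)
  expect_equal(sort(fit$populations), c(0.020, 0.027), tolerance = 0.15)
  dw_f1 <- fit$dw$dw_ppm[fit$dw$residue == "F1"]
  expect_equal(dw_f1, c(3.0, -4.0), tolerance = 0.05)
})

test_that("profiles without exchange are excluded from global groups", {
  m <- exchange_model(c(0.95, 0.05), c(0, 3.5), kex = 60)
  prof <- gen_cest(m, dw_by_residue = list(active = 3.5),
                   b1_fields = c(25, 12.5), offsets_ppm = seq(-7, 7, 0.5),
                   noise_sd = 0.005, seed = 3)
  flat <- gen_cest(exchange_model(1, 0, numeric(0)),
                   dw_by_residue = list(inert = numeric(0)),
                   b1_fields = c(25, 12.5), offsets_ppm = seq(-7, 7, 0.5),
                   noise_sd = 0.005, seed = 4)
  flat$residue <- "inert"
  fit <- fit_cest(rbind(prof, flat), n_states = 2, noise_sd = 0.005)
  expect_true("inert" %in% fit$excluded)
  expect_false("inert" %in% fit$dw$residue)
})

test_that("CSP extraction applies the significance threshold", {
  m <- exchange_model(c(1 - 0.05, 0.05), c(0, 3.5), kex = 60)
  prof <- gen_cest(m, dw_by_residue = list(big = 3.5, small = 1.0),
                   b1_fields = c(25, 12.5), offsets_ppm = seq(-7, 7, 0.5),
                   noise_sd = 0)
  fit <- fit_cest(prof, n_states = 2, noise_sd = 0.005)
  cs <- extract_csp(fit, significance = 2.2)
  expect_true(cs$significant[cs$residue == "big"])
  expect_false(cs$significant[cs$residue == "small"])
  # threshold 0 marks everything; huge threshold nothing
  expect_true(all(extract_csp(fit, 0)$significant))
  expect_false(any(extract_csp(fit, 100)$significant))
})

test_that("bound-state shift sets partition into min and max by magnitude", {
  dw <- data.frame(
    residue = c("A", "A", "A", "A", "B"),
    nucleus = c("N", "N", "CA", "CA", "N"),
    dw_ppm  = c(1.2, -3.4, 0.5, 0.9, 2.0))
  sets <- bound_state_shifts(dw)
  expect_equal(sets$min_set$N[sets$min_set$residue == "A"], 1.2)
  expect_equal(sets$max_set$N[sets$max_set$residue == "A"], -3.4)
  expect_equal(sets$min_set$CA[sets$min_set$residue == "A"], 0.5)
  # single detected state: same value in both sets, flagged
  expect_equal(sets$min_set$N[sets$min_set$residue == "B"],
               sets$max_set$N[sets$max_set$residue == "B"])
  expect_true(any(sets$degenerate$residue == "B"))
  # missing nucleus stays NA
  expect_true(is.na(sets$min_set$CA[sets$min_set$residue == "B"]))
  # identical min/max inputs give identical sets
  dw_same <- data.frame(residue = "A", nucleus = "N", dw_ppm = c(2, 2))
  s2 <- bound_state_shifts(dw_same)
  expect_identical(s2$min_set$N, s2$max_set$N)
})
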