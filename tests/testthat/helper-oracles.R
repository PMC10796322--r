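# Independent brute-force oracles used to cross-check the package's
# closed-form / matrix-exponential implementations. These re-derive each
# result by a different numerical route (bisection, ODE integration, set
# arithmetic) and deliberately share no code with the implementation.

# ITC: per-injection heats with the bound concentration found by bisection
# on the free-ligand concentration at every step (no quadratic formula).
oracle_itc_heats <- function(n_value, kd, dh, cell_conc, syr_conc,
                             cell_volume, injection_volumes, offset = 0) {
  v0 <- cell_volume
  dv_tot <- cumsum(injection_volumes)
  mt <- cell_conc * (1 - dv_tot / (2 * v0)) / (1 + dv_tot / (2 * v0))
  xt <- syr_conc * (dv_tot / v0) / (1 + dv_tot / (2 * v0))
  bound <- mapply(function(m, x) {
    if (x == 0) return(0)
    f <- function(lf) lf + n_value * m * lf / (kd + lf) - x
    lo <- 0; hi <- x
    for (i in 1:200) {           # plain bisection
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
    }
    x - (lo + hi) / 2
  }, mt, xt)
  q_cum <- dh * 1000 * v0 * bound
  q_prev <- c(0, q_cum[-length(q_cum)])
  dq <- q_cum - q_prev + (injection_volumes / v0) * (q_cum + q_prev) / 2
  dq * 1e6 + offset
}

# CEST: step-wise ODE integration of the Bloch-McConnell system. Builds its
# own generator from the model definition (star topology, RF along x).
oracle_cest_ratio <- function(populations, offsets_state_ppm, kex, r1, r2,
                              b1_hz, carrier_ppm, t_sat, freq_mhz) {
  n <- length(populations)
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n)
  K <- matrix(0, n, n)
  for (j in seq_len(n - 1)) {
    s <- j + 1
    kf <- kex[j] * populations[s] / (populations[1] + populations[s])
    kr <- kex[j] * populations[1] / (populations[1] + populations[s])
    K[1, 1] <- K[1, 1] - kf; K[s, 1] <- K[s, 1] + kf
    K[s, s] <- K[s, s] - kr; K[1, s] <- K[1, s] + kr
  }
  build <- function(w1) {
    A <- matrix(0, 3 * n, 3 * n)
    d <- 2 * pi * (offsets_state_ppm - carrier_ppm) * freq_mhz
    for (i in seq_len(n)) {
      ix <- 3 * (i - 1)
      A[ix + 1, ix + 1] <- -r2[i]; A[ix + 1, ix + 2] <- -d[i]
      A[ix + 2, ix + 1] <- d[i];   A[ix + 2, ix + 2] <- -r2[i]
      A[ix + 2, ix + 3] <- -w1;    A[ix + 3, ix + 2] <- w1
      A[ix + 3, ix + 3] <- -r1[i]
    }
    for (comp in 1:3) {
      idx <- seq(comp, 3 * n, by = 3)
      A[idx, idx] <- A[idx, idx] + K
    }
    A
  }
  m0 <- as.vector(rbind(0, 0, populations))
  A <- build(2 * pi * b1_hz)
  sol <- deSolve::ode(y = m0, times = c(0, t_sat),
                      func = function(t, y, p) list(A %*% y),
                      rtol = 1e-11, atol = 1e-13, maxsteps = 1e6)
  mz <- sol[2, 1 + 3]
  Kz <- K - diag(r1, n)
  i0 <- deSolve::ode(y = populations, times = c(0, t_sat),
                     func = function(t, y, p) list(Kz %*% y),
                     rtol = 1e-11, atol = 1e-13, maxsteps = 1e6)[2, 2]
  mz / i0
}

# AD regions by explicit set arithmetic: residues covered by at least one
# tile, minus residues covered by any tile at or below the threshold.
oracle_ad_regions <- function(starts, ends, scores, threshold) {
  covered <- sort(unique(unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))))
  bad_tiles <- which(!(scores > threshold))
  bad <- sort(unique(unlist(mapply(seq, starts[bad_tiles], ends[bad_tiles],
                                   SIMPLIFY = FALSE))))
  good <- setdiff(covered, bad)
  if (!length(good)) return(data.frame(start = integer(), end = integer()))
  brk <- c(0, which(diff(good) > 1), length(good))
  data.frame(start = good[brk[-length(brk)] + 1],
             end = good[brk[-1]])
}
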