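#' Construct an N-state chemical exchange model
#'
#' Describes a system of exchanging spin states for CEST simulation: state
#' populations, chemical-shift offsets, longitudinal/transverse relaxation
#' rates, and exchange rates. The exchange topology is a star on the first
#' state (the observed free state): every minor state exchanges with state 1
#' only, and there is no direct minor-minor (bound-bound) exchange.
#' Microscopic rates obey detailed balance: for the edge between state 1 and
#' state j with total rate `kex_j`, the forward rate is
#' `kex_j * p_j / (p_1 + p_j)` and the reverse `kex_j * p_1 / (p_1 + p_j)`.
#'
#' Offsets are expressed in ppm relative to the free-state peak (state 1 sits
#' at 0 ppm by convention; a minor-state offset is the bound-state chemical
#' shift difference).
#'
#' @param populations Numeric vector of state populations summing to 1;
#'   first element is the major (free) state.
#' @param offsets_ppm State offsets in ppm relative to the free state
#'   (first element normally 0).
#' @param kex Exchange rate(s) in 1/s, one per minor state (length
#'   `length(populations) - 1`).
#' @param r1,r2 Longitudinal/transverse relaxation rates, 1/s; scalars are
#'   recycled to all states.
#' @param labels Optional state labels.
#' @return Object of class `exchange_model`.
#' @export
exchange_model <- function(populations, offsets_ppm, kex, r1 = 1.5, r2 = 10,
                           labels = NULL) {
  n <- length(populations)
  if (n < 1) stop("need at least one state")
  if (abs(sum(populations) - 1) > 1e-8)
    stop("populations must sum to 1")
  if (any(populations < 0)) stop("populations must be non-negative")
  if (length(offsets_ppm) != n) stop("'offsets_ppm' must match state count")
  if (length(kex) != max(n - 1, 0)) stop("'kex' must have one rate per minor state")
  if (any(kex < 0)) stop("exchange rates must be non-negative")
  r1 <- rep_len(r1, n); r2 <- rep_len(r2, n)
  if (any(r1 < 0) || any(r2 < 0)) stop("relaxation rates must be non-negative")
  if (is.null(labels))
    labels <- c("free", if (n > 1) paste0("bound", seq_len(n - 1)))
  structure(list(populations = populations, offsets_ppm = offsets_ppm,
                 kex = kex, r1 = r1, r2 = r2, labels = labels),
            class = "exchange_model")
}

# Exchange-rate matrix (n x n) for the star topology: K[i,j] is the rate
# j -> i (so dM/dt = K %*% M for the exchange part).
.exchange_matrix <- function(model) {
  n <- length(model$populations)
  K <- matrix(0, n, n)
  p <- model$populations
  for (j in seq_len(n - 1)) {
    s <- j + 1
    psum <- p[1] + p[s]
    k_fwd <- if (psum > 0) model$kex[j] * p[s] / psum else 0  # free -> bound_j
    k_rev <- if (psum > 0) model$kex[j] * p[1] / psum else 0  # bound_j -> free
    K[1, 1] <- K[1, 1] - k_fwd; K[s, 1] <- K[s, 1] + k_fwd
    K[s, s] <- K[s, s] - k_rev; K[1, s] <- K[1, s] + k_rev
  }
  K
}

# Full Bloch-McConnell generator for saturation at a given carrier offset.
# Per-state block (Mx, My, Mz) with RF along x (amplitude w1 rad/s) and
# resonance offset d_i rad/s; exchange acts identically on all components.
# Thermal recovery is omitted (homogeneous system), which cancels in the
# I/I0 normalization.
.bm_generator <- function(model, b1_hz, carrier_ppm, freq_mhz) {
  n <- length(model$populations)
  w1 <- 2 * pi * b1_hz
  d <- 2 * pi * (model$offsets_ppm - carrier_ppm) * freq_mhz  # rad/s
  A <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n)) {
    ix <- 3 * (i - 1)
    A[ix + 1, ix + 1] <- -model$r2[i]
    A[ix + 1, ix + 2] <- -d[i]
    A[ix + 2, ix + 1] <- d[i]
    A[ix + 2, ix + 2] <- -model$r2[i]
    A[ix + 2, ix + 3] <- -w1
    A[ix + 3, ix + 2] <- w1
    A[ix + 3, ix + 3] <- -model$r1[i]
  }
  K <- .exchange_matrix(model)
  for (comp in 1:3)
    A[seq(comp, 3 * n, by = 3), seq(comp, 3 * n, by = 3)] <-
      A[seq(comp, 3 * n, by = 3), seq(comp, 3 * n, by = 3)] + K
  A
}

# exp(A*t) %*% v via eigendecomposition, with Pade (Matrix::expm) fallback
# for (near-)defective generators where the eigenbasis is ill-conditioned.
.expm_apply <- function(A, t, v) {
  eg <- tryCatch(eigen(A), error = function(e) NULL)
  if (!is.null(eg)) {
    w <- tryCatch(solve(eg$vectors, v), error = function(e) NULL)
    if (!is.null(w)) {
      resid <- max(abs(Re(eg$vectors %*% w) - v))
      if (is.finite(resid) && resid < 1e-8)
        return(Re(eg$vectors %*% (exp(eg$values * t) * w)))
    }
  }
  as.numeric(Matrix::expm(Matrix::Matrix(A * t)) %*% v)
}

#' Simulate a CEST intensity-ratio profile
#'
#' Propagates the coupled Bloch-McConnell equations of an [exchange_model()]
#' through the saturation period at each carrier offset by matrix
#' exponentiation of the combined relaxation/exchange/RF generator, and
#' returns the free-state intensity ratio I/I0. The reference intensity I0
#' is the free-state z magnetization after the same evolution with the RF
#' amplitude set to zero, so a far off-resonance carrier gives a ratio of 1
#' up to the saturation the RF itself causes there.
#'
#' @param model An [exchange_model()].
#' @param b1_hz Saturation field amplitude, Hz.
#' @param offsets_ppm Carrier offsets to sample, ppm relative to the
#'   free-state peak.
#' @param t_sat Saturation time, s.
#' @param freq_mhz Spectrometer frequency of the observed nucleus, MHz
#'   (converts ppm to Hz; default 81.1, a 15N frequency at 800 MHz 1H).
#' @return data.frame of class `cest_profile`: `offset_ppm`,
#'   `intensity_ratio`, with attributes `b1_hz`, `t_sat`, `freq_mhz`.
#' @export
simulate_cest <- function(model, b1_hz, offsets_ppm, t_sat, freq_mhz = 81.1) {
  stopifnot(inherits(model, "exchange_model"))
  if (t_sat <= 0) stop("'t_sat' must be positive")
  n <- length(model$populations)
  m0 <- as.vector(rbind(0, 0, model$populations))  # (Mx,My,Mz) per state
  iz_free <- 3
  # reference: no RF, z block decouples from x/y
  Kz <- .exchange_matrix(model) - diag(model$r1, n)
  i0 <- .expm_apply(Kz, t_sat, model$populations)[1]
  ratio <- vapply(offsets_ppm, function(cp) {
    A <- .bm_generator(model, b1_hz, cp, freq_mhz)
    .expm_apply(A, t_sat, m0)[iz_free] / i0
  }, numeric(1))
  structure(data.frame(offset_ppm = offsets_ppm, intensity_ratio = ratio),
            b1_hz = b1_hz, t_sat = t_sat, freq_mhz = freq_mhz,
            class = c("cest_profile", "data.frame"))
}

# Flag exchange for one residue's profiles: compare the observed ratios with
# a simulated exchange-free (single-state) reference at the same fields, and
# measure the largest saturation deficit outside a small mask around the
# free-state line (where the reference is sensitive to the assumed R1/R2).
# A deficit below 3x the noise SD means "no exchange".
.has_exchange <- function(df, free_mask_ppm, noise_sd, r1, r2,
                          t_sat, freq_mhz) {
  ref_model <- exchange_model(1, 0, numeric(0), r1 = r1, r2 = r2)
  deficit <- unlist(lapply(split(df, df$b1_hz), function(dfb) {
    ref <- simulate_cest(ref_model, dfb$b1_hz[1], dfb$offset_ppm,
                         t_sat, freq_mhz)$intensity_ratio
    (ref - dfb$intensity_ratio)[abs(dfb$offset_ppm) > free_mask_ppm]
  }))
  length(deficit) == 0 || max(deficit) >= 3 * noise_sd
}

#' Globally fit two- or three-state exchange to CEST profiles
#'
#' Least-squares global fit of grouped CEST profiles recorded at one or more
#' saturation field strengths. All residues in the group share the minor-
#' state population(s) and exchange rate(s); each residue has its own
#' bound-state shift(s). Profiles showing no exchange (maximum dip depth
#' outside the free-state region below `3 * noise_sd`) are excluded from the
#' fit and listed in the result.
#'
#' Input is long-format data: one row per (residue, B1 field, offset), with
#' offsets in ppm relative to each residue's free-state peak.
#'
#' Relaxation rates are shared nuisance parameters: fixed at `r1`/`r2` by
#' default, or refined globally (single shared R1 and R2) when
#' `fit_relaxation = TRUE`. For three-state systems the topology is a star
#' on the free state.
#'
#' @param profiles data.frame with columns `residue`, `b1_hz`, `offset_ppm`,
#'   `intensity_ratio`.
#' @param n_states 2 or 3.
#' @param t_sat Saturation time, s.
#' @param freq_mhz Spectrometer frequency, MHz.
#' @param r1,r2 Relaxation-rate values (1/s) used for all states.
#' @param fit_relaxation Refine shared R1/R2 in the fit.
#' @param noise_sd Intensity-ratio noise SD used for the exchange flag and
#'   chi-square scaling (default 0.01).
#' @param start Optional named list overriding starting values: `p` (minor
#'   population(s)), `kex`, and `dw` — either a numeric vector applied to
#'   every residue or a list named by residue with one shift per minor
#'   state (e.g. dip positions read off the profiles). Consistent state
#'   assignment across residues in a three-state group relies on these
#'   starts; the automatic guess orders each residue's dips by depth.
#' @param free_mask_ppm Half-width of the free-dip mask used by the
#'   no-exchange filter (default 1.5 ppm).
#' @return List of class `cest_fit`: `populations` (+`se`), `kex` (+`se`),
#'   `dw` data.frame (`residue`, `state`, `dw_ppm`, `se`), `excluded`
#'   (residues flagged as no-exchange), `redchi2` per profile, `converged`,
#'   `flags`.
#' @export
fit_cest <- function(profiles, n_states = 2, t_sat = 0.5, freq_mhz = 81.1,
                     r1 = 1.5, r2 = 10, fit_relaxation = FALSE,
                     noise_sd = 0.01, start = NULL, free_mask_ppm = 1.5) {
  stopifnot(n_states %in% c(2, 3))
  need <- c("residue", "b1_hz", "offset_ppm", "intensity_ratio")
  if (!all(need %in% names(profiles)))
    stop("'profiles' must have columns ", paste(need, collapse = ", "))

  profiles$residue <- as.character(profiles$residue)
  split_res <- split(profiles, profiles$residue)
  keep <- vapply(split_res, .has_exchange, logical(1),
                 free_mask_ppm = free_mask_ppm, noise_sd = noise_sd,
                 r1 = r1, r2 = r2, t_sat = t_sat, freq_mhz = freq_mhz)
  excluded <- names(split_res)[!keep]
  split_res <- split_res[keep]
  if (!length(split_res))
    stop("all profiles flagged as showing no exchange; nothing to fit")
  residues <- names(split_res)
  n_minor <- n_states - 1

  # starting values -------------------------------------------------------
  guess_dw <- function(df, k) {
    outside <- abs(df$offset_ppm) > free_mask_ppm
    if (!any(outside)) return(rep(3, k) + seq_len(k) - 1)
    off <- df$offset_ppm[outside]; ir <- df$intensity_ratio[outside]
    picks <- off[which.min(ir)]
    while (length(picks) < k) {
      # next-deepest dip at least 1.5 ppm from every previous pick
      free <- vapply(off, function(o) all(abs(o - picks) > 1.5), logical(1))
      picks <- c(picks, if (any(free)) off[free][which.min(ir[free])]
                        else picks[1] + 1.5 * length(picks))
    }
    picks
  }
  dw0 <- lapply(split_res, guess_dw, k = n_minor)
  if (!is.null(start$dw)) {
    if (is.list(start$dw)) {
      # per-residue starting shifts, e.g. read off visible dip positions
      for (res in intersect(names(start$dw), residues))
        dw0[[res]] <- rep_len(start$dw[[res]], n_minor)
    } else {
      dw0 <- lapply(dw0, function(z) rep_len(start$dw, n_minor))
    }
  }
  p0 <- if (!is.null(start$p)) start$p else rep(0.05 / n_minor, n_minor)
  kex0 <- if (!is.null(start$kex)) start$kex else rep(100, n_minor)

  par <- c(stats::qlogis(p0), log(kex0))
  names(par) <- c(paste0("logit_p", seq_len(n_minor)),
                  paste0("log_kex", seq_len(n_minor)))
  for (i in seq_along(residues)) {
    nm <- paste0("dw_", residues[i], "_", seq_len(n_minor))
    par[nm] <- dw0[[i]]
  }
  if (fit_relaxation) par <- c(par, log_r1 = log(r1), log_r2 = log(r2))

  unpack <- function(par) {
    p_minor <- stats::plogis(par[paste0("logit_p", seq_len(n_minor))])
    kex <- exp(par[paste0("log_kex", seq_len(n_minor))])
    rr1 <- if (fit_relaxation) exp(par[["log_r1"]]) else r1
    rr2 <- if (fit_relaxation) exp(par[["log_r2"]]) else r2
    list(p = p_minor, kex = kex, r1 = rr1, r2 = rr2)
  }

  n_obs <- sum(vapply(split_res, nrow, integer(1)))
  resid_fn <- function(par) {
    u <- unpack(par)
    if (sum(u$p) >= 0.9) return(rep(1e3, n_obs))  # keep populations minor
    unlist(lapply(seq_along(residues), function(i) {
      df <- split_res[[i]]
      dwi <- par[paste0("dw_", residues[i], "_", seq_len(n_minor))]
      mod <- exchange_model(c(1 - sum(u$p), u$p), c(0, dwi), u$kex,
                            r1 = u$r1, r2 = u$r2)
      unlist(lapply(split(df, df$b1_hz), function(dfb) {
        sim <- simulate_cest(mod, dfb$b1_hz[1], dfb$offset_ppm, t_sat, freq_mhz)
        dfb$intensity_ratio - sim$intensity_ratio
      }))
    }))
  }

  fit <- minpack.lm::nls.lm(par = par, fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 100, ftol = 1e-10, ptol = 1e-10))
  converged <- fit$info %in% 1:4
  flags <- character()
  if (!converged) flags <- c(flags, "non_convergence")

  est <- fit$par
  u <- unpack(est)
  dof <- length(fit$fvec) - length(est)
  sigma2 <- sum(fit$fvec^2) / max(dof, 1)
  cv <- tryCatch(sigma2 * solve(fit$hessian), error = function(e) NULL)
  ses <- if (!is.null(cv) && all(diag(cv) >= 0)) sqrt(diag(cv))
         else rep(NA_real_, length(est))
  names(ses) <- names(est)
  # delta method: dp/dlogit = p(1-p)
  p_se <- u$p * (1 - u$p) * ses[paste0("logit_p", seq_len(n_minor))]
  kex_se <- u$kex * ses[paste0("log_kex", seq_len(n_minor))]

  # flat-profile identifiability guard
  if (all(abs(fit$fvec) < .Machine$double.eps^0.5) && sum(u$p) < 1e-6)
    flags <- c(flags, "unidentifiable")

  dw_tab <- do.call(rbind, lapply(seq_along(residues), function(i) {
    nm <- paste0("dw_", residues[i], "_", seq_len(n_minor))
    data.frame(residue = residues[i],
               state = paste0("bound", seq_len(n_minor)),
               dw_ppm = unname(est[nm]), se = unname(ses[nm]))
  }))

  redchi2 <- vapply(seq_along(residues), function(i) {
    df <- split_res[[i]]
    dwi <- est[paste0("dw_", residues[i], "_", seq_len(n_minor))]
    mod <- exchange_model(c(1 - sum(u$p), u$p), c(0, dwi), u$kex,
                          r1 = u$r1, r2 = u$r2)
    rss <- sum(unlist(lapply(split(df, df$b1_hz), function(dfb) {
      sim <- simulate_cest(mod, dfb$b1_hz[1], dfb$offset_ppm, t_sat, freq_mhz)
      (dfb$intensity_ratio - sim$intensity_ratio)^2
    })))
    rss / (noise_sd^2 * nrow(df))
  }, numeric(1))
  names(redchi2) <- residues

  structure(list(populations = unname(u$p), populations_se = unname(p_se),
                 kex = unname(u$kex), kex_se = unname(kex_se),
                 r1 = u$r1, r2 = u$r2,
                 dw = dw_tab, excluded = excluded, redchi2 = redchi2,
                 converged = converged, flags = flags),
            class = "cest_fit")
}

#' @export
print.cest_fit <- function(x, ...) {
  cat("Global CEST exchange fit", if (!x$converged) "(NOT converged)", "\n")
  for (i in seq_along(x$populations))
    cat(sprintf("  minor state %d: p = %.3g%% +/- %.2g%%, kex = %.4g +/- %.2g /s\n",
                i, 100 * x$populations[i], 100 * x$populations_se[i],
                x$kex[i], x$kex_se[i]))
  if (length(x$excluded))
    cat("  excluded (no exchange):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Bound-state chemical shift perturbations with significance mask
#'
#' Extracts the absolute bound-state shift differences from a [fit_cest()]
#' result and marks those exceeding a significance threshold (2.2 ppm is a
#' conventional choice for 15N).
#'
#' @param fit A `cest_fit` object.
#' @param significance Threshold in ppm (default 2.2).
#' @return data.frame: `residue`, `state`, `dw_ppm`, `abs_dw`, `significant`.
#' @export
extract_csp <- function(fit, significance = 2.2) {
  stopifnot(inherits(fit, "cest_fit"))
  out <- fit$dw
  out$abs_dw <- abs(out$dw_ppm)
  out$significant <- out$abs_dw > significance
  out[, c("residue", "state", "dw_ppm", "abs_dw", "significant")]
}

#' Assemble per-residue bound-state shift sets across nuclei
#'
#' For a system with two bound states observed through several nuclei,
#' compiles two export tables per residue: the shifts belonging to the
#' smaller-|dw| bound state and to the larger-|dw| bound state (used e.g. as
#' input for secondary-structure-propensity prediction of the two states).
#' A residue/nucleus with only one detected bound state contributes the same
#' value to both sets and is flagged `degenerate`; a missing nucleus is
#' recorded as `NA`, never imputed.
#'
#' @param dw_table data.frame with columns `residue`, `nucleus`, `dw_ppm`
#'   (one or two rows per residue/nucleus pair, one per detected bound
#'   state).
#' @return List with `min_set` and `max_set` (data.frames residue x nucleus
#'   of shifts) and `degenerate` (data.frame of flagged residue/nucleus
#'   pairs).
#' @export
bound_state_shifts <- function(dw_table) {
  need <- c("residue", "nucleus", "dw_ppm")
  if (!all(need %in% names(dw_table)))
    stop("'dw_table' must have columns ", paste(need, collapse = ", "))
  residues <- unique(dw_table$residue)
  nuclei <- unique(dw_table$nucleus)
  empty <- function() {
    m <- as.data.frame(matrix(NA_real_, length(residues), length(nuclei)))
    names(m) <- nuclei
    cbind(data.frame(residue = residues), m)
  }
  min_set <- empty(); max_set <- empty()
  degen <- list()
  for (i in seq_along(residues)) for (nuc in nuclei) {
    v <- dw_table$dw_ppm[dw_table$residue == residues[i] &
                         dw_table$nucleus == nuc]
    if (!length(v)) next
    min_set[i, nuc] <- v[which.min(abs(v))]
    max_set[i, nuc] <- v[which.max(abs(v))]
    if (length(v) == 1)
      degen[[length(degen) + 1]] <- data.frame(residue = residues[i],
                                               nucleus = nuc)
  }
  list(min_set = min_set, max_set = max_set,
       degenerate = if (length(degen)) do.call(rbind, degen)
                    else data.frame(residue = character(), nucleus = character()))
}
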