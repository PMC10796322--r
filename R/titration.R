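#' Combined amide chemical shift perturbation
#'
#' Combines 1H and 15N shift differences into a single CSP as the Euclidean
#' distance with the conventional 0.154 scaling of the nitrogen dimension:
#' \deqn{\mathrm{CSP} = \sqrt{\Delta\delta_H^2 + (0.154\,\Delta\delta_N)^2}}
#'
#' @param d_h Proton shift difference, ppm.
#' @param d_n Nitrogen shift difference, ppm.
#' @param n_weight Weight applied to the nitrogen shift (default 0.154).
#' @return Combined CSP in ppm (vectorized).
#' @export
csp <- function(d_h, d_n, n_weight = 0.154) {
  sqrt(d_h^2 + (n_weight * d_n)^2)
}

#' Tiered significance classification of CSPs
#'
#' Bins combined CSPs into `none` / `moderate` / `strong` tiers at the two
#' supplied thresholds (defaults 0.1 and 0.2 ppm).
#'
#' @param csps Numeric vector of combined CSPs, ppm.
#' @param thresholds Length-2 increasing numeric vector (ppm).
#' @return Factor with levels `none`, `moderate`, `strong`.
#' @export
csp_significance_map <- function(csps, thresholds = c(0.1, 0.2)) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0)
    stop("'thresholds' must be two increasing values")
  cut(csps, breaks = c(-Inf, thresholds, Inf),
      labels = c("none", "moderate", "strong"), right = FALSE)
}

#' Construct an NMR titration series
#'
#' Long-format container for a protein-observed titration: at every titration
#' point and residue, the amide shift differences from the ligand-free
#' reference and the peak intensity. The receptor (observed protein)
#' concentration is constant across points; the ligand concentration varies
#' and includes 0 (the reference spectrum).
#'
#' @param data A data.frame with columns `residue`, `ligand` (molar total
#'   ligand), `d_h`, `d_n` (ppm shift differences from the reference point)
#'   and optionally `intensity`.
#' @param receptor_total Constant receptor concentration, molar.
#' @return Object of class `titration_series` (the validated data.frame with
#'   attribute `receptor_total`).
#' @export
titration_series <- function(data, receptor_total) {
  need <- c("residue", "ligand", "d_h", "d_n")
  if (!all(need %in% names(data)))
    stop("'data' must have columns ", paste(need, collapse = ", "))
  if (receptor_total <= 0) stop("'receptor_total' must be positive (molar)")
  if (!any(data$ligand == 0))
    stop("series must include the zero-ligand reference point")
  structure(data, receptor_total = receptor_total,
            class = c("titration_series", class(data)))
}

# Bound receptor fraction with explicit ligand depletion: single-site
# quadratic in the complex concentration. p, l: totals (molar); kd molar.
.bound_fraction_quadratic <- function(l, p, kd) {
  b <- p + l + kd
  complex <- (b - sqrt(b * b - 4 * p * l)) / 2
  complex / p
}

#' Per-residue titration Kd from CSP saturation curves
#'
#' Fits, for each residue, \eqn{\mathrm{CSP}(L) = \mathrm{CSP}_{max}
#' \cdot f_b(L; K_d)} where \eqn{f_b} is the bound receptor fraction from
#' the exact single-site quadratic (ligand depletion is handled explicitly
#' because receptor and Kd can be comparable). Residues whose CSP range is
#' below `flat_tol` are flagged unbound and not fitted. Fitted residues are
#' classified into two affinity regimes by 1-D two-means clustering of
#' log10(Kd); with fewer than two fitted residues, or when the cluster
#' separation is below a factor of 2 in Kd, a single regime is reported.
#'
#' @param series A [titration_series()].
#' @param flat_tol Minimum CSP range (ppm) for a residue to count as
#'   responding (default 0.01).
#' @return A data.frame of class `titration_fit` with one row per residue:
#'   `residue`, `kd` (molar), `kd_se`, `csp_max`, `unbound` (logical),
#'   `regime` (factor: `"high_affinity"`/`"low_affinity"`/`NA`).
#' @export
fit_residue_kd <- function(series, flat_tol = 0.01) {
  stopifnot(inherits(series, "titration_series"))
  p_tot <- attr(series, "receptor_total")
  series$residue <- as.character(series$residue)
  out <- do.call(rbind, lapply(split(series, series$residue), function(d) {
    d <- d[order(d$ligand), ]
    y <- csp(d$d_h, d$d_n)
    l <- d$ligand
    if (length(unique(l)) < 4)
      stop("need at least 4 titration points per residue")
    if (diff(range(y)) < flat_tol)
      return(data.frame(residue = d$residue[1], kd = NA_real_,
                        kd_se = NA_real_, csp_max = NA_real_, unbound = TRUE))
    # starting values: half-saturation near mid-ligand, plateau from max CSP
    start <- c(log_kd = log(stats::median(l[l > 0])), csp_max = max(y) * 1.2)
    fit <- minpack.lm::nls.lm(
      par = start,
      fn = function(par) {
        y - par[["csp_max"]] *
          .bound_fraction_quadratic(l, p_tot, exp(par[["log_kd"]]))
      },
      control = minpack.lm::nls.lm.control(maxiter = 200))
    est <- fit$par
    dof <- max(length(y) - 2, 1)
    cv <- tryCatch(sum(fit$fvec^2) / dof * solve(fit$hessian),
                   error = function(e) NULL)
    se_log <- if (!is.null(cv) && cv[1, 1] >= 0) sqrt(cv[1, 1]) else NA_real_
    kd_hat <- exp(est[["log_kd"]])
    data.frame(residue = d$residue[1], kd = kd_hat, kd_se = kd_hat * se_log,
               csp_max = est[["csp_max"]], unbound = FALSE)
  }))
  rownames(out) <- NULL
  out$regime <- factor(NA_character_,
                       levels = c("high_affinity", "low_affinity"))
  fitted <- which(!out$unbound & is.finite(out$kd))
  if (length(fitted) >= 2 && diff(range(log10(out$kd[fitted]))) > 1e-6) {
    lk <- log10(out$kd[fitted])
    km <- stats::kmeans(lk, centers = range(lk), iter.max = 50)
    lo_cluster <- which.min(km$centers)  # smaller Kd = higher affinity
    if (abs(diff(km$centers)) > log10(2)) {
      out$regime[fitted] <- ifelse(km$cluster == lo_cluster,
                                   "high_affinity", "low_affinity")
    } else {
      out$regime[fitted] <- "high_affinity"
    }
  } else if (length(fitted) == 1) {
    out$regime[fitted] <- "high_affinity"
  }
  class(out) <- c("titration_fit", class(out))
  out
}

#' Relative peak intensities across a titration
#'
#' Traces each residue's peak intensity relative to the zero-ligand reference
#' point and flags residues whose intensity at the final titration point has
#' dropped below `threshold` (exchange-broadening signature of binding).
#'
#' @param series A [titration_series()] whose data include `intensity`.
#' @param threshold Relative-intensity cutoff for flagging (default 0.3);
#'   0 disables flagging.
#' @return List with `trace` (data.frame: `residue`, `ligand`,
#'   `rel_intensity`) and `attenuated` (character vector of flagged
#'   residues). Residues with zero reference intensity are dropped with a
#'   warning.
#' @export
intensity_trace <- function(series, threshold = 0.3) {
  stopifnot(inherits(series, "titration_series"))
  if (is.null(series$intensity)) stop("series carries no 'intensity' column")
  parts <- lapply(split(series, series$residue), function(d) {
    d <- d[order(d$ligand), ]
    i0 <- d$intensity[d$ligand == 0][1]
    if (!is.finite(i0) || i0 == 0) return(NULL)
    data.frame(residue = d$residue, ligand = d$ligand,
               rel_intensity = d$intensity / i0)
  })
  dropped <- names(parts)[vapply(parts, is.null, logical(1))]
  if (length(dropped))
    warning("residue(s) with zero reference intensity excluded: ",
            paste(dropped, collapse = ", "))
  trace <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  rownames(trace) <- NULL
  trace$residue <- as.character(trace$residue)
  final <- vapply(split(trace, trace$residue),
                  function(d) d$rel_intensity[which.max(d$ligand)], numeric(1))
  list(trace = trace,
       attenuated = names(final)[threshold > 0 & final < threshold])
}
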