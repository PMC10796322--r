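#' Cis population from HSQC peak volume pairs
#'
#' Estimates the fraction of a free ligand pool in the cis proline isomer from
#' paired cis/trans peak volumes: for each residue pair the fraction is
#' V_cis / (V_cis + V_trans); the mean and SD across pairs are returned.
#'
#' @param cis_volumes,trans_volumes Paired numeric vectors of peak volumes
#'   (one element per residue).
#' @return List with `f_cis` (mean fraction), `sd` (SD across pairs, `NA` for
#'   a single pair), `per_pair` (fractions), `n_pairs`.
#' @export
population_from_volumes <- function(cis_volumes, trans_volumes) {
  if (length(cis_volumes) != length(trans_volumes))
    stop("cis and trans volume vectors must be paired")
  if (length(cis_volumes) < 1) stop("need at least one volume pair")
  tot <- cis_volumes + trans_volumes
  bad <- tot <= 0
  if (any(bad)) {
    warning(sprintf("%d pair(s) with zero total volume skipped", sum(bad)))
    cis_volumes <- cis_volumes[!bad]; tot <- tot[!bad]
  }
  if (!length(tot)) stop("no usable volume pairs")
  frac <- cis_volumes / tot
  list(f_cis = mean(frac),
       sd = if (length(frac) > 1) stats::sd(frac) else NA_real_,
       per_pair = frac, n_pairs = length(frac))
}

#' Trans-to-cis equilibrium constant from the cis population
#'
#' \eqn{K_{eq,trans \to cis} = f_{cis} / (1 - f_{cis})}. A 30 percent cis
#' population gives Keq of about 0.43.
#'
#' @param f_cis Fraction of the free pool in the cis form, strictly in (0, 1).
#' @return Equilibrium constant (dimensionless).
#' @export
keq_from_population <- function(f_cis) {
  if (any(f_cis <= 0) || any(f_cis >= 1))
    stop("'f_cis' must lie strictly between 0 and 1")
  f_cis / (1 - f_cis)
}

#' Apparent dissociation constant of an equilibrated isomer mixture
#'
#' When the free ligand pool interconverts between cis and trans isomers fast
#' relative to the measurement (so the free-pool split stays at its
#' equilibrium value), the mixture binds with
#' \deqn{1/K_{d,app} = f_{cis}/K_{d,cis} + (1-f_{cis})/K_{d,trans}}
#' i.e. the population-weighted harmonic combination of the isomer constants.
#' This is exact in the trace-receptor limit.
#'
#' @param kd_cis,kd_trans Isomer-specific dissociation constants, molar.
#' @param f_cis_free Cis fraction of the free ligand pool.
#' @return Apparent dissociation constant, molar.
#' @export
apparent_kd <- function(kd_cis, kd_trans, f_cis_free) {
  if (any(c(kd_cis, kd_trans) <= 0)) stop("dissociation constants must be positive")
  if (any(f_cis_free < 0) || any(f_cis_free > 1)) stop("'f_cis_free' must be in [0, 1]")
  1 / (f_cis_free / kd_cis + (1 - f_cis_free) / kd_trans)
}

#' Decompose an apparent Kd into isomer-specific constants
#'
#' Resolves the dissociation constants of the cis and trans isomers of a
#' ligand from three measurable quantities: the apparent (mixture) Kd, the
#' cis fraction of the free pool, and the per-pool bound fractions of each
#' isomer (the fraction of all cis molecules that are bound, and likewise
#' for trans, as read out by CEST minor-state populations).
#'
#' Under the branched two-bound-state equilibrium (no bound-bound exchange)
#' both isomers see the same free receptor concentration, so
#' \deqn{\frac{K_{d,trans}}{K_{d,cis}} =
#'   \frac{(1-p_{b,t})/p_{b,t}}{(1-p_{b,c})/p_{b,c}}}
#' and the ratio combined with the harmonic mixture constraint of
#' [apparent_kd()] fixes both constants:
#' \eqn{K_{d,cis} = K_{d,app}\,(f_{cis} + (1-f_{cis})/r)} with
#' \eqn{r = K_{d,trans}/K_{d,cis}}.
#'
#' Uncertainties are propagated by Monte Carlo: inputs are resampled from
#' independent Gaussians with the supplied SDs and the decomposition is
#' re-evaluated for each draw.
#'
#' @param kd_app Apparent dissociation constant, molar.
#' @param f_cis_free Cis fraction of the free pool.
#' @param p_bound_cis,p_bound_trans Per-pool bound fractions, in (0, 1).
#' @param sd Optional named list of 1-SD errors for `kd_app`, `f_cis_free`,
#'   `p_bound_cis`, `p_bound_trans`; unnamed entries default to 0.
#' @param n_mc Monte Carlo draws for error propagation.
#' @param seed Seed for the Monte Carlo resampling.
#' @return List with `kd_trans`, `kd_cis` (molar), their `sd_trans`/`sd_cis`
#'   (0 when all input SDs are 0), and `ratio` (trans/cis).
#' @examples
#' d <- decompose_kd(500e-9, 0.30, p_bound_cis = 0.068, p_bound_trans = 0.036)
#' signif(d$kd_trans * 1e9, 2)  # 640
#' signif(d$kd_cis * 1e9, 2)    # 330
#' @export
decompose_kd <- function(kd_app, f_cis_free, p_bound_cis, p_bound_trans,
                         sd = list(), n_mc = 10000, seed = 20240118) {
  if (kd_app <= 0) stop("'kd_app' must be positive")
  if (f_cis_free <= 0 || f_cis_free >= 1) stop("'f_cis_free' must be in (0, 1)")
  if (any(c(p_bound_cis, p_bound_trans) <= 0) ||
      any(c(p_bound_cis, p_bound_trans) >= 1))
    stop("bound fractions must lie strictly in (0, 1)")

  point <- .decompose_point(kd_app, f_cis_free, p_bound_cis, p_bound_trans)

  get_sd <- function(nm) if (!is.null(sd[[nm]])) sd[[nm]] else 0
  sds <- vapply(c("kd_app", "f_cis_free", "p_bound_cis", "p_bound_trans"),
                get_sd, numeric(1))
  if (all(sds == 0)) {
    sd_t <- 0; sd_c <- 0
  } else {
    draws <- .with_seed(seed, {
      ka <- stats::rnorm(n_mc, kd_app, sds[["kd_app"]])
      fc <- stats::rnorm(n_mc, f_cis_free, sds[["f_cis_free"]])
      pc <- stats::rnorm(n_mc, p_bound_cis, sds[["p_bound_cis"]])
      pt <- stats::rnorm(n_mc, p_bound_trans, sds[["p_bound_trans"]])
      ok <- ka > 0 & fc > 0 & fc < 1 & pc > 0 & pc < 1 & pt > 0 & pt < 1
      r <- ((1 - pt[ok]) / pt[ok]) / ((1 - pc[ok]) / pc[ok])
      kc <- ka[ok] * (fc[ok] + (1 - fc[ok]) / r)
      list(kt = r * kc, kc = kc)
    })
    sd_t <- stats::sd(draws$kt); sd_c <- stats::sd(draws$kc)
  }
  list(kd_trans = point$kd_trans, kd_cis = point$kd_cis,
       sd_trans = sd_t, sd_cis = sd_c, ratio = point$ratio)
}

.decompose_point <- function(kd_app, f_cis, p_c, p_t) {
  r <- ((1 - p_t) / p_t) / ((1 - p_c) / p_c)   # kd_trans / kd_cis
  kd_cis <- kd_app * (f_cis + (1 - f_cis) / r)
  list(kd_trans = r * kd_cis, kd_cis = kd_cis, ratio = r)
}

#' Construct a branched isomer-binding system
#'
#' Describes the coupled equilibria R + L_cis = RL_cis and
#' R + L_trans = RL_trans where the free ligand pool keeps a fixed cis/trans
#' split set by the isomerization equilibrium constant. Exchange between the
#' two bound states is not part of the model.
#'
#' @param keq_trans_to_cis Trans-to-cis equilibrium constant of the free pool.
#' @param kd_cis,kd_trans Isomer dissociation constants, molar.
#' @param total_ligand,total_receptor Total concentrations, molar.
#' @return Object of class `isomer_binding_system`.
#' @export
isomer_binding_system <- function(keq_trans_to_cis, kd_cis, kd_trans,
                                  total_ligand, total_receptor) {
  if (keq_trans_to_cis <= 0) stop("'keq_trans_to_cis' must be positive")
  if (kd_cis <= 0 || kd_trans <= 0) stop("dissociation constants must be positive")
  if (total_ligand < 0 || total_receptor < 0) stop("totals must be non-negative")
  structure(
    list(keq = keq_trans_to_cis,
         f_cis_free = keq_trans_to_cis / (1 + keq_trans_to_cis),
         kd_cis = kd_cis, kd_trans = kd_trans,
         total_ligand = total_ligand, total_receptor = total_receptor),
    class = "isomer_binding_system")
}

#' Solve the branched isomer-binding equilibrium
#'
#' Computes all species concentrations for an [isomer_binding_system()]:
#' free receptor, free cis/trans ligand (split fixed by Keq), and both bound
#' complexes, satisfying receptor and ligand mass balance to high precision.
#'
#' @param system An [isomer_binding_system()].
#' @param tol Relative mass-balance tolerance (default 1e-12).
#' @return List with molar concentrations `receptor_free`, `ligand_free_cis`,
#'   `ligand_free_trans`, `bound_cis`, `bound_trans`, plus per-pool bound
#'   fractions `p_bound_cis`, `p_bound_trans` (fraction of each isomer pool
#'   that is bound; `NA` when the pool is empty).
#' @export
solve_equilibrium <- function(system, tol = 1e-12) {
  stopifnot(inherits(system, "isomer_binding_system"))
  lt <- system$total_ligand; rt <- system$total_receptor
  fc <- system$f_cis_free
  # effective mixture Kd seen by the receptor for an equilibrated free pool
  kmix <- 1 / (fc / system$kd_cis + (1 - fc) / system$kd_trans)
  if (rt == 0 || lt == 0) {
    lf <- lt; rf <- rt; b <- 0
  } else {
    # single quadratic in bound complex concentration with mixture Kd
    b <- .bound_ligand(rt, lt, kmix)
    # polish with uniroot on free ligand for strict mass balance
    f <- function(lf) lf + (rt * lf / (kmix + lf)) - lt
    lf <- stats::uniroot(f, c(0, lt), tol = lt * tol)$root
    rf <- rt * kmix / (kmix + lf)
    b <- lt - lf
  }
  b_c <- if (b > 0) b * (fc / system$kd_cis) /
           (fc / system$kd_cis + (1 - fc) / system$kd_trans) else 0
  b_t <- b - b_c
  lf_c <- fc * lf; lf_t <- (1 - fc) * lf
  pool_c <- lf_c + b_c; pool_t <- lf_t + b_t
  list(receptor_free = rf,
       ligand_free_cis = lf_c, ligand_free_trans = lf_t,
       bound_cis = b_c, bound_trans = b_t,
       p_bound_cis = if (pool_c > 0) b_c / pool_c else NA_real_,
       p_bound_trans = if (pool_t > 0) b_t / pool_t else NA_real_)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
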