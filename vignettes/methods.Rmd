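---
title: "Models and methods behind proswitch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind proswitch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proswitch)
```

`proswitch` implements the quantitative chain used to characterize a
bivalent short-linear-motif (SLiM) interaction of an intrinsically
disordered transcription-factor region with the Med25 activator-interaction
domain (ACID), in which a cis/trans proline isomer equilibrium in the ligand
creates two distinct bound states. This vignette explains each model, its
assumptions, the tunable parameters and their defaults, and what the
synthetic-data generators do and do not emulate.

## ITC: the one-set-of-sites isotherm

`wiseman_isotherm()` predicts integrated injection heats for single-site
binding. At each injection the total concentrations in the cell are updated
and the bound-complex concentration solved from the mass-balance quadratic

$$[RL] = \tfrac{1}{2}\left(M_t + X_t + K_d -
  \sqrt{(M_t + X_t + K_d)^2 - 4 M_t X_t}\right),$$

with $M_t = N[\mathrm{cell}]$ the total site concentration. The heat of
injection $i$ is $\Delta H\,V_0\,\Delta[RL]$ plus a constant per-injection
offset that absorbs dilution heats.

Two dilution treatments are provided. The default `"overflow"` model is the
perfusion bookkeeping of fixed-volume calorimeter cells: injecting $dV$
displaces an equal volume of mixed contents, giving, at cumulative injected
volume $\Delta V$,

$$[M] = M_0\,\frac{1 - \Delta V/2V_0}{1 + \Delta V/2V_0}, \qquad
  [X] = X_s\,\frac{\Delta V/V_0}{1 + \Delta V/2V_0},$$

and a displaced-heat correction $\frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$ on
each incremental heat. `"none"` treats the cell as expandable. Tests verify
the forward model against a bisection equilibrium solver that shares no code
with the quadratic route.

`fit_itc()` does nonlinear least squares over $(N, \log K_d, \Delta H,
\mathrm{offset})$ with `minpack.lm::nls.lm`; standard errors come from the
fit covariance, with the delta method for $K_d$, and $\Delta G$, $-T\Delta S$
are derived with propagated errors. The first (0.5 µL) injection is
discarded by default, following standard practice. The Wiseman $c$-value
$N[\mathrm{cell}]/K_d$ is reported and flagged outside $[1, 1000]$, where
the isotherm shape pins $K_d$ poorly. Noiseless round-trips recover
generating parameters to well under 0.5 % for $c$ between about 5 and 500.

Units: concentrations molar, volumes litres, heats microjoules, energies
kJ/mol, $R = 8.314$ J/mol/K, standard state 1 M, 25 °C = 298.15 K.

## Heat capacity and the Spolar-Record estimate of residues folding

`fit_dcp()` regresses $\Delta H$ on $T$ (slope $\Delta C_p$) and $-T\Delta S$
on $T$ by ordinary least squares, reporting slopes with standard errors and
95 % confidence intervals, and predicted values at a reporting temperature.
At least three temperatures are required; with typical experimental noise
the CI coverage is close to nominal (checked by simulation).

`spolar_record_id()` decomposes the association entropy at the reference
temperature:

$$\Delta S_{HE} = c\,\Delta C_p \ln(T/T_{HE}), \qquad
  \Delta S_{conf} = \Delta S_{assoc} - \Delta S_{HE} - \Delta S_{rt}, \qquad
  R_{th} = \Delta S_{conf} / \Delta S_{res}.$$

The default constants are the classic values ($T_{HE} = 386$ K, $c = 1.35$,
$\Delta S_{rt} = -209$ J/mol/K, $\Delta S_{res} = -23.4$ J/mol/K per residue
folding). Adaptations of the method for intrinsically disordered ligands
recalibrate some of these; since those recalibrated values are not part of
this package's sources they are exposed as configuration
(`spolar_record_constants()`) rather than hard-coded. Uncertainty on
$R_{th}$ is propagated by Monte Carlo over Gaussian input errors with a
fixed default seed (20240118) and 10,000 draws; zero input error gives
exactly zero output SD, and the SD scales linearly with input SEs in the
small-error limit.

## The branched isomer-binding equilibrium

A proline-containing ligand populates cis and trans isomers in the free
state with $K_{eq,t\to c} = f_{cis}/(1 - f_{cis})$, measured from cis/trans
peak-volume pairs (`population_from_volumes()`). Both isomers bind the same
receptor site with their own constants and the two bound states do not
interconvert directly (a star topology on the free state). Assuming the
free-pool isomer ratio stays equilibrated on the measurement timescale, the
mixture binds with the population-weighted harmonic apparent constant

$$\frac{1}{K_{d,app}} = \frac{f_{cis}}{K_{d,cis}} +
  \frac{1 - f_{cis}}{K_{d,trans}}.$$

CEST resolves the per-pool bound fractions $p_{b,c}, p_{b,t}$ (the fraction
of all cis molecules bound, and likewise for trans — the per-pool reading is
stated explicitly here because the readout is per isomer pool). Because both
pools see the same free receptor concentration,

$$\frac{K_{d,trans}}{K_{d,cis}} =
  \frac{(1 - p_{b,t})/p_{b,t}}{(1 - p_{b,c})/p_{b,c}}$$

holds exactly at any receptor depletion, and combined with the harmonic
constraint fixes both constants (`decompose_kd()`); this
ratio-plus-harmonic construction is the unique decomposition consistent
with the model and is adopted as the implementation. With the inputs
$K_{d,app} = 500$ nM, $f_{cis} = 0.30$, $p_{b,t} = 3.6$ %, $p_{b,c} = 6.8$ %
it returns 640 nM (trans) and 330 nM (cis) at two significant figures, the
package's reporting convention for these constants. Monte Carlo propagation
of the input errors gives the quoted SDs. `solve_equilibrium()` provides
the forward check: full mass-balance species concentrations for any totals;
tests verify exact mass conservation and the round-trip through the
decomposition.

## Effective concentration and avidity

For a bivalent ligand whose primary motif is docked, the tethered secondary
motif experiences an effective concentration set by the disordered linker.
The package models this as a power law $C_e = a L^{b}$ with default exponent
$b = -1.5$ (random-coil-like decay) and the coefficient calibrated so that
$C_e(12.5\ \mathrm{residues}) = 9$ mM. Both are explicit, overridable
assumptions (`linker_model()`): whether the underlying empirical correlation
is better described by a power law or by interpolation is not determined
here, and anchoring the curve at one calibrated point sidesteps the
distinction within the relevant length range. Secondary-site occupancy is
$C_e/(C_e + K_d)$ — 9 mM against a 4.7 mM site gives 66 %, within the
quoted 65 ± 10 % window — and the avidity-predicted bivalent constant is
$K_{d,1}/(1 + C_e/K_{d,2})$, which never falls below what tethering alone
can explain; comparing it with a measured bivalent affinity quantifies
linker or cooperativity contributions beyond tethering.

## CEST: Bloch-McConnell simulation and global fitting

`simulate_cest()` propagates, for each carrier offset, the coupled
Bloch-McConnell equations of all states' $(M_x, M_y, M_z)$ under the
combined relaxation + exchange + RF generator by matrix exponentiation
(eigendecomposition propagator with a Padé fallback). Conventions:

- offsets are ppm relative to the free-state line (the free state sits at 0);
- the RF field is ideal (no B1 inhomogeneity distribution) — an
  inhomogeneity average could be added by weighting several amplitudes, but
  the default keeps the single nominal amplitude;
- thermal recovery is omitted from the generator; it cancels in the
  normalization, where $I_0$ is the same propagation with zero RF amplitude.
  Far off resonance the ratio then returns to 1 within the RF's own residual
  saturation;
- exchange obeys detailed balance and the topology is a star on the free
  state: no bound-bound edge, matching the kinetic model in which the two
  bound proline isomer states do not interconvert directly.

The propagator is verified against independent ODE integration (`deSolve`)
to better than $10^{-6}$ on random two- and three-state models.

`fit_cest()` fits grouped profiles globally: residues in a group share the
minor population(s) and exchange rate(s), each residue has its own
bound-state shift(s). $R_1$/$R_2$ are shared nuisance values — fixed at
their configured defaults (1.5 and 10 s$^{-1}$) unless `fit_relaxation =
TRUE` refines a single shared pair; saturation time (default 0.5 s) and
spectrometer frequency (default 81.1 MHz, a nitrogen-15 frequency at an
800 MHz instrument) are configuration, since such acquisition settings
travel with the data. Profiles showing no exchange are excluded before
fitting: each profile is compared against a simulated exchange-free
single-state reference at the same field, and a maximum saturation deficit
below three times the noise SD (outside a small mask around the free line,
where the reference is sensitive to the assumed relaxation rates) means
no exchange. A fixed-width mask alone would not work because the free-dip
tail width scales with the RF amplitude.

Identifiability: in three-state groups the assignment of each residue's two
dips to the two shared states is seeded by per-residue starting shifts
(`start$dw` as a named list, i.e. dip positions read off the data, as is
standard in global exchange fitting); the automatic fallback orders dips by
depth. On synthetic data at study-like settings (minor populations 2–7 %,
three fields of 25/12.5/6.25 Hz, 1 % intensity noise, 0.5 ppm sampling) the
global fit recovers populations within ±0.3 absolute percentage points
(two-state) and separates three-state populations and shifts.

On-resonance detail: at the exact free-line position the magnetization
nutates about the RF field and can retain signal after the saturation
period; the profile minimum therefore sits within the RF linewidth of the
line rather than exactly on it. This is a property of the model, not a
numerical artifact.

## Stopped-flow kinetics

`fit_exponential()` fits one or two exponential phases plus a baseline per
trace (rates log-parameterized, returned fast-first); the instrument dead
time (default 2 ms) is truncated at trace construction. Traces are fitted
individually and the per-condition rates summarized by fitting the
empirical CDF to a Gaussian (`rate_distribution()`), matching the
trace-individual analysis convention; a pooled fit is deliberately not the
default. `kon_from_kobs()` takes the association rate constant as the slope
of the (optionally weighted) linear $k_{obs}(c)$ fit and tests for
curvature against a quadratic alternative — a significant curvature term
flags a non-linear dependence for which no $k_{on}$ should be reported.
`koff_from_displacement()` fits $k_{obs}(c) = k_{off} - A e^{-c/c_0}$ and
reports the asymptote, per phase for biphasic dissociation; this
three-parameter saturating form is the package's interpretation of an
"exponential decay toward the plateau" and is documented as such. A
fitted $c_0$ beyond the sampled range flags that the plateau was not
reached.

Bivalent constructs dissociate biphasically (two bound states emptying at
distinct rates), monovalent ones monophasically; tests confirm that on
biphasic synthetics the two-exponential model wins the residual comparison
decisively while on monophasic data it does not, and that $k_{off}/k_{on}$
reproduces the generating $K_d$ within propagation error.

## NMR titrations

Combined amide CSPs use the conventional nitrogen weight:
$\sqrt{\Delta\delta_H^2 + (0.154\,\Delta\delta_N)^2}$. Per-residue binding
isotherms are fitted with the exact single-site quadratic in the complex
concentration — ligand depletion is handled exactly rather than by the
free ≈ total approximation because the observed protein (100–150 µM) is
comparable to the tighter site's $K_d$. Residues with a flat CSP series
(range below 0.01 ppm) are flagged unbound, not fitted. Fitted residues are
classified into two affinity regimes by two-means clustering of
$\log_{10} K_d$ — a deliberately simple, replaceable rule; when the cluster
centers are closer than a factor of two in $K_d$ a single regime is
reported. Per-residue-then-cluster (rather than grouped fitting) is the
implemented interpretation of two-regime analysis. On synthetic data with a
$\geq 5\times$ $K_d$ separation the partition is recovered in $\geq 95$ %
of replicates. Relative peak intensities are traced against the zero-ligand
reference and residues ending below 0.3 are flagged as binding-attenuated.
Tier thresholds for CSP significance default to 0.1 and 0.2 ppm.

## Tiling activation-domain scores

Sequences are tiled into 40-residue windows at step 10 (1-based inclusive
coordinates). When `length - window` is not a multiple of the step, a
terminal tile anchored at the C-terminus is appended so every residue is
covered — a documented convention for the otherwise-unspecified boundary
case. Per tile, bin counts are first normalized to fractions (read-depth
differences between tiles are sequencing depth, not activity — an explicit
interpretation), dotted with the per-bin median reporter ratios, and
z-scored across the tiles of the input screen (the z-reference is the
screen at hand). Per-residue scores average all covering tiles, and AD
regions are maximal residue runs where *every* covering tile exceeds the
threshold — the conservative rule, verified in tests against an
independent set-arithmetic oracle and always a subset of the any-tile rule.

## Synthetic data and what passing tests mean

Each generator draws from the exact forward model of its analysis stage
plus the simplest noise model a scientist would assume: Gaussian heats,
intensity ratios, fluorescence and shifts; multinomial bin counts. Defaults
mirror the study conditions: 15 µM cell with a 10× syringe and 18 × 2 µL
injections; three B1 fields of 25/12.5/6.25 Hz; minor populations of a few
percent; $k_{on}$ 29 µM$^{-1}$s$^{-1}$ scale kinetics with ≥ 19 replicate
traces per condition; 100–150 µM observed protein in titrations; 40/10
tiling. Noise SDs default to values giving study-like relative errors.
Every generator is bit-identical under a fixed seed and leaves the global
RNG state untouched.

The generators deliberately do not emulate: baseline drift or integration
artifacts in calorimetry, B1 inhomogeneity or off-resonance pulse effects,
peak overlap and picking errors, photobleaching, non-specific binding, or
sequencing alignment error. Recovery tests passing on these synthetics
therefore demonstrate correctness of the estimators under their stated
models, not robustness to every real-data pathology.

## Numerical choices and problem sizes

Optimizer: Levenberg-Marquardt (`nls.lm`) with log/logit parameterizations
keeping rates, constants and populations in their domains. Matrix
exponentials via eigendecomposition with residual-checked fallback to Padé.
Equilibria solved by the closed-form quadratic, polished or cross-checked
by bracketed root finding. Monte Carlo error propagation uses 10,000 draws
and the fixed default seed 20240118; draws that leave a parameter's domain
are rejected.

Default test problem sizes (the package's own choices for a fast,
informative suite): 100 random models for the ODE-oracle equivalence in the
acceptance suite, 100 noisy ITC replicates for the bias check, 400 draws
for $\Delta C_p$ CI coverage, 60 titration-regime replicates, 200 screen
replicates, and single global CEST fits at the standard 0.5 ppm grid.

## Known limitations

- The CEST model covers longitudinal two-/three-state exchange of uncoupled
  spins: no TROSY effects, scalar-coupling corrections, or pulse-sequence
  detail.
- The effective-concentration power law is a calibrated assumption, valid
  near the calibration length; it is not a polymer-physics derivation.
- The displacement-asymptote form for $k_{off}$ is an interpretation; other
  saturating forms would give the same asymptote but different approach
  shapes.
- The two-regime classifier assumes exactly one or two regimes; more
  structured affinity landscapes need a different clustering rule.
- Spolar-Record constants default to the classic calibration; conclusions
  about absolute numbers of residues folding inherit that calibration's
  uncertainty.
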