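# proswitch

Quantitative analysis of bivalent short-linear-motif (SLiM) binding with
proline-isomer resolution.

Intrinsically disordered transcription-factor regions often bind coactivator
domains through one or more SLiMs, and a single cis/trans peptidyl-prolyl
isomer equilibrium inside such a region can split the complex into two
structurally distinct bound states. `proswitch` implements the full
measurement chain used to characterize such a system — exemplified by a
plant transcription factor's bivalent interaction with the Med25
activator-interaction domain (ACID) — as a tested, reusable R package:

- **ITC thermodynamics** — the single-site ("one set of sites") forward
  isotherm with perfusion-cell dilution bookkeeping, nonlinear fitting of
  (N, K<sub>d</sub>, ΔH, offset), the identities ΔG = RT ln K<sub>d</sub> =
  ΔH − TΔS, heat-capacity extraction ΔC<sub>p</sub> = dΔH/dT from
  multi-temperature series, and the Spolar-Record entropy decomposition
  estimating the number of residues folding upon binding, with Monte Carlo
  errors.
- **Isomer-specific affinities** — from three observables (apparent
  K<sub>d</sub>, free-pool cis fraction, per-pool CEST bound fractions),
  the branched two-bound-state equilibrium is solved for the cis- and
  trans-specific dissociation constants:
  K<sub>d,trans</sub>/K<sub>d,cis</sub> from the bound-fraction odds ratio,
  the scale from 1/K<sub>d,app</sub> = f<sub>cis</sub>/K<sub>d,cis</sub> +
  (1−f<sub>cis</sub>)/K<sub>d,trans</sub>.
- **CEST** — a Bloch-McConnell simulator (matrix exponentiation of the
  relaxation/exchange/RF generator, star exchange topology) and global two-
  and three-state fitting of intensity-ratio profiles across B1 fields,
  yielding minor-state populations, exchange rates and bound-state chemical
  shift differences.
- **Bivalency** — effective concentration of a tethered motif from a
  calibrated linker-length power law, secondary-site saturation
  C<sub>e</sub>/(C<sub>e</sub>+K<sub>d</sub>), and the avidity-predicted
  bivalent K<sub>d</sub>.
- **Stopped-flow kinetics** — single/double exponential trace fitting,
  cumulative-Gaussian rate summaries, k<sub>on</sub> from the linear
  k<sub>obs</sub>(c) slope with a curvature diagnostic, and k<sub>off</sub>
  from the displacement plateau, per phase.
- **NMR titrations** — combined CSPs (0.154 nitrogen weight), per-residue
  K<sub>d</sub> fits with exact ligand depletion and two-regime
  classification, intensity-attenuation tracing.
- **Tiling screens** — activation-domain scores from sorting-bin count
  matrices (depth-normalize, dot with bin medians, z-score), per-residue
  aggregation, and conservative all-tiles region calling.
- **Synthetic data** — seeded generators for all five input kinds with
  ground truth attached, so every stage is testable without external data.

## Worked example

Decompose an apparent 500 nM affinity into isomer-specific constants using
a 30 % free-state cis population and CEST bound fractions of 3.6 % (trans)
and 6.8 % (cis):

```r
library(proswitch)
d <- decompose_kd(kd_app = 500e-9, f_cis_free = 0.30,
                  p_bound_cis = 0.068, p_bound_trans = 0.036,
                  sd = list(kd_app = 20e-9, f_cis_free = 0.01,
                            p_bound_cis = 0.001, p_bound_trans = 0.001))
signif(d$kd_trans * 1e9, 2)  # 640  (+/- 28 nM by Monte Carlo)
signif(d$kd_cis * 1e9, 2)    # 330  (+/- 15 nM)
apparent_kd(d$kd_cis, d$kd_trans, 0.30) * 1e9  # 500, the round trip
```

The cis isomer binds roughly twice as tightly as the trans isomer; the
population-weighted harmonic combination recovers the measured apparent
affinity exactly.

Fit a synthetic ITC titration (15 µM cell, 10× syringe, 18 × 2 µL
injections, Gaussian heat noise):

```r
experiment <- gen_itc(noise_sd = 0.8, seed = 101)
fit_itc(experiment)
#> Single-site ITC fit
#> Single-site binding thermodynamics at 298.15 K
#>   N      = 0.963 +/- 0.026
#>   Kd     = 560 nM +/- 161
#>   dH     = -49.1 kJ/mol +/- 2.65
#>   -TdS   = 13.4 kJ/mol +/- 2.75
#>   dG     = -35.7 kJ/mol +/- 0.712
#>   offset = -0.364 uJ, c-value = 25.8
```

The generating truth (N 0.98, K<sub>d</sub> 510 nM, ΔH −50.7 kJ/mol) is
recovered within the fitted standard errors; `ground_truth(experiment)`
returns it.

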