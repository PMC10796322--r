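#' Reference binding thermodynamics table at 25 C
#'
#' Measured single-site binding parameters (N, Kd, dH, -TdS, dG, each with a
#' 1-SD error) for a panel of intrinsically disordered transcription-factor
#' fragments and point variants binding the Med25 activator-interaction
#' domain, at 25 C. Shipped as a plain CSV and used throughout the tests as
#' a thermodynamic-closure fixture: for every complete row, dG recomputed as
#' RT ln(Kd) and as dH + (-TdS) agrees with the tabulated value within the
#' reported precision.
#'
#' Incomplete rows (affinity only measurable by NMR, or no detectable
#' binding) carry `NA`s.
#'
#' @param complete_only Drop rows with any missing thermodynamic entry.
#' @return data.frame with columns `fragment`, `n_value`, `n_sd`, `kd_nm`,
#'   `kd_sd_nm`, `dh`, `dh_sd`, `tds_neg`, `tds_sd`, `dg`, `dg_sd`
#'   (energies kJ/mol, Kd in nM).
#' @export
thermo_reference_table <- function(complete_only = FALSE) {
  path <- system.file("extdata", "thermo_reference_25C.csv",
                      package = "proswitch", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (complete_only)
    tab <- tab[stats::complete.cases(tab[, c("kd_nm", "dh", "tds_neg", "dg")]), ]
  tab
}
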