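#' Binding free energy from a dissociation constant
#'
#' `dG = R T ln(Kd / 1 M)` with `R = 1.987204e-3` kcal/(mol K); negative for
#' sub-molar affinities.
#'
#' @param Kd_uM dissociation constant (uM, > 0).
#' @param T_K temperature (K), default 298.15.
#' @return free energy of binding (kcal/mol).
#' @examples
#' delta_g(43)   # ubiquitin binding at moderate affinity
#' @export
delta_g <- function(Kd_uM, T_K = 298.15) {
  stopifnot(all(Kd_uM > 0), T_K > 0)
  GAS_CONSTANT_KCAL * T_K * log(Kd_uM * 1e-6)
}

#' Free-energy difference for a ratio of dissociation constants
#'
#' `ddG = R T ln(ratio)`: e.g. a 3-fold difference in `Kd` at 25 C is about
#' 0.7 kcal/mol.
#'
#' @param ratio ratio of the two dissociation constants (> 0).
#' @param T_K temperature (K), default 298.15.
#' @return free-energy difference (kcal/mol).
#' @examples
#' ddg_ratio(3)
#' @export
ddg_ratio <- function(ratio, T_K = 298.15) {
  stopifnot(all(ratio > 0), T_K > 0)
  GAS_CONSTANT_KCAL * T_K * log(ratio)
}
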