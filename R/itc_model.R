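GAS_CONSTANT_KCAL <- 1.987204e-3  # kcal mol^-1 K^-1

#' ITC injection protocol
#'
#' Describes a perfusion-cell titration: the cell volume and macromolecule
#' concentration, the syringe (ligand) concentration, the per-injection
#' volumes and the temperature.
#'
#' @param cell_volume_mL active cell volume (mL).
#' @param cell_conc_uM macromolecule concentration in the cell (uM, monomer
#'   basis).
#' @param syringe_conc_uM ligand concentration in the syringe (uM).
#' @param injection_volumes_uL vector of injection volumes (uL); at least 2.
#' @param temperature_K temperature (K), default 298.15 (25 C).
#' @return list of class `injection_protocol`.
#' @examples
#' # ubiquitin titrated into an RVP-UBA construct
#' injection_protocol(1.43, 64.8, 796, rep(9, 30))
#' @export
injection_protocol <- function(cell_volume_mL, cell_conc_uM, syringe_conc_uM,
                               injection_volumes_uL = rep(9, 30),
                               temperature_K = 298.15) {
  stopifnot(cell_volume_mL > 0, cell_conc_uM > 0, syringe_conc_uM > 0,
            length(injection_volumes_uL) >= 2L, all(injection_volumes_uL > 0),
            temperature_K > 0)
  structure(list(cell_volume_mL = cell_volume_mL, cell_conc_uM = cell_conc_uM,
                 syringe_conc_uM = syringe_conc_uM,
                 injection_volumes_uL = injection_volumes_uL,
                 temperature_K = temperature_K),
            class = "injection_protocol")
}

#' Single-site binding parameters
#'
#' @param N sites per macromolecule (> 0).
#' @param Kd dissociation constant (uM, > 0).
#' @param dH binding enthalpy (kcal/mol).
#' @param offset constant dilution-heat baseline (kcal/mol of injectant).
#' @export
one_site_params <- function(N = 1, Kd, dH = -5, offset = 0) {
  stopifnot(N > 0, Kd > 0)
  structure(list(N = unname(N), Kd = unname(Kd), dH = unname(dH),
                 offset = unname(offset)),
            class = c("one_site_params", "itc_params"))
}

#' Two-independent-sites binding parameters
#'
#' Two non-interacting sites per macromolecule, one ligand each
#' (N1 = N2 = 1).
#'
#' @param Kd1,Kd2 dissociation constants (uM, > 0).
#' @param dH1,dH2 site enthalpies (kcal/mol).
#' @param offset baseline (kcal/mol of injectant).
#' @export
two_site_params <- function(Kd1, Kd2, dH1 = -5, dH2 = -5, offset = 0) {
  stopifnot(Kd1 > 0, Kd2 > 0)
  structure(list(Kd1 = unname(Kd1), Kd2 = unname(Kd2), dH1 = unname(dH1),
                 dH2 = unname(dH2), offset = unname(offset), N1 = 1, N2 = 1),
            class = c("two_site_params", "itc_params"))
}

#' Bound ligand at equilibrium for a single class of sites
#'
#' Solves the mass-balance quadratic for `N` identical independent sites of
#' dissociation constant `Kd`: `B^2 - B (Lt + N Mt + Kd) + Lt N Mt = 0`,
#' taking the root in `[0, min(Lt, N Mt)]` via the numerically stable form.
#'
#' @param Mt total macromolecule concentration (uM).
#' @param Lt total ligand concentration (uM).
#' @param params a [one_site_params()].
#' @return bound ligand concentration (uM).
#' @export
bound_fraction_one_site <- function(Mt, Lt, params) {
  stopifnot(Mt >= 0, Lt >= 0)
  cap <- params$N * Mt
  b <- Lt + cap + params$Kd
  disc <- b * b - 4 * Lt * cap
  # stable root: avoids cancellation when Kd << Lt + cap
  2 * Lt * cap / (b + sqrt(pmax(disc, 0)))
}

#' Free ligand for the two-independent-sites model
#'
#' Solves `Lt = L + Mt L/(Kd1 + L) + Mt L/(Kd2 + L)` for the unique
#' non-negative root by safeguarded Newton iteration (the left side is
#' strictly increasing in `L`). Residual below `1e-12 * max(1, Lt)`.
#'
#' @param Mt,Lt total macromolecule and ligand concentrations (uM).
#' @param params a [two_site_params()].
#' @return free ligand concentration (uM).
#' @export
free_ligand_two_sites <- function(Mt, Lt, params) {
  stopifnot(Mt >= 0, Lt >= 0)
  if (Lt == 0) return(0)
  K1 <- params$Kd1
  K2 <- params$Kd2
  g <- function(L) L + Mt * L / (K1 + L) + Mt * L / (K2 + L) - Lt
  gp <- function(L) 1 + Mt * K1 / (K1 + L)^2 + Mt * K2 / (K2 + L)^2
  lo <- 0
  hi <- Lt
  L <- Lt / (1 + Mt / K1 + Mt / K2)  # linearised start
  tol <- 1e-12 * max(1, Lt)
  for (i in 1:200) {
    f <- g(L)
    if (abs(f) <= tol) break
    if (f > 0) hi <- L else lo <- L
    Lnew <- L - f / gp(L)
    L <- if (Lnew <= lo || Lnew >= hi) (lo + hi) / 2 else Lnew
  }
  L
}

# Per-site bound-ligand concentrations (uM) at each injection, plus the cell
# concentration track under the displaced-volume convention: each injection
# of dV into a cell of volume V0 dilutes what was in the cell by
# (1 - f/2) / (1 + f/2), f = dV/V0, and delivers Xs * f / (1 + f/2) of fresh
# ligand.
cell_track <- function(protocol, kds, caps) {
  V0 <- protocol$cell_volume_mL * 1e-3            # L
  dV <- protocol$injection_volumes_uL * 1e-6      # L
  n <- length(dV)
  Mt <- numeric(n)
  Lt <- numeric(n)
  M <- protocol$cell_conc_uM
  L <- 0
  for (i in seq_len(n)) {
    f <- dV[i] / V0
    d <- (1 - f / 2) / (1 + f / 2)
    M <- M * d
    L <- L * d + protocol$syringe_conc_uM * f / (1 + f / 2)
    Mt[i] <- M
    Lt[i] <- L
  }
  bound <- matrix(0, nrow = n, ncol = length(kds))
  for (i in seq_len(n)) {
    if (length(kds) == 1L) {
      p <- one_site_params(N = caps, Kd = kds, dH = 0)
      bound[i, 1] <- bound_fraction_one_site(Mt[i], Lt[i], p)
    } else {
      p <- two_site_params(Kd1 = kds[1], Kd2 = kds[2])
      Lfree <- free_ligand_two_sites(Mt[i], Lt[i], p)
      bound[i, ] <- Mt[i] * Lfree / (kds + Lfree)
    }
  }
  list(Mt = Mt, Lt = Lt, bound = bound, V0 = V0, dV = dV)
}

# Normalized heats (kcal/mol of injectant) from per-site bound tracks and
# per-site enthalpies, using the Origin-style displaced-volume correction
# q_i = Q_i - Q_{i-1} + (dV_i/V0) * (Q_i + Q_{i-1}) / 2.
heats_from_bound <- function(track, dHs, offset, syringe_conc_uM) {
  Q <- track$V0 * (track$bound %*% dHs) * 1e-6    # kcal (bound in uM -> M)
  Qprev <- c(0, Q[-length(Q)])
  q <- Q - Qprev + (track$dV / track$V0) * (Q + Qprev) / 2
  moles <- syringe_conc_uM * 1e-6 * track$dV      # mol injected
  as.vector(q / moles) + offset
}

#' Model normalized injection heats
#'
#' Forward ITC model for either parameter family: tracks cell concentrations
#' injection by injection with the displaced-volume dilution convention,
#' computes the cumulative binding heat `Q_i = V0 * sum_s dH_s * [bound_s]`,
#' differences it with the displacement correction, and normalises per mole
#' of injectant (adding the baseline offset).
#'
#' @param protocol an [injection_protocol()].
#' @param params [one_site_params()] or [two_site_params()].
#' @return numeric vector of normalized heats (kcal/mol of injectant), one
#'   per injection.
#' @export
model_heats <- function(protocol, params) {
  stopifnot(inherits(protocol, "injection_protocol"),
            inherits(params, "itc_params"))
  if (inherits(params, "one_site_params")) {
    track <- cell_track(protocol, params$Kd, params$N)
    heats_from_bound(track, params$dH, params$offset, protocol$syringe_conc_uM)
  } else {
    track <- cell_track(protocol, c(params$Kd1, params$Kd2), c(1, 1))
    heats_from_bound(track, c(params$dH1, params$dH2), params$offset,
                     protocol$syringe_conc_uM)
  }
}

#' Molar ratio of injectant to macromolecule at each injection
#'
#' @param protocol an [injection_protocol()].
#' @return vector `Lt / Mt` in the cell after each injection.
#' @export
molar_ratio <- function(protocol) {
  track <- cell_track(protocol, kds = 1, caps = 1)
  track$Lt / track$Mt
}

#' Wiseman c parameter
#'
#' `c = N * M0 / Kd`, the dimensionless sigmoidicity parameter of a one-site
#' titration.
#'
#' @param protocol an [injection_protocol()].
#' @param params a [one_site_params()].
#' @export
wiseman_c <- function(protocol, params) {
  params$N * protocol$cell_conc_uM / params$Kd
}

#' Simulate an ITC titration
#'
#' Forward-simulates per-injection heats under the given binding model and
#' adds Gaussian noise to the raw heats.
#'
#' @param protocol an [injection_protocol()].
#' @param params [one_site_params()] or [two_site_params()].
#' @param noise_sd standard deviation of additive noise on the raw injection
#'   heats (ucal); 0 gives a deterministic isotherm.
#' @param seed integer seed for the noise stream.
#' @return object of class `titration`: list with `protocol`, `heats_ucal`
#'   and `normalized` (kcal/mol of injectant).
#' @export
simulate_isotherm <- function(protocol, params, noise_sd = 0, seed = 1L) {
  ndh <- model_heats(protocol, params)
  moles <- protocol$syringe_conc_uM * 1e-6 *
    protocol$injection_volumes_uL * 1e-6
  heats_ucal <- ndh * moles * 1e9                 # kcal -> ucal
  if (noise_sd > 0) {
    set.seed(seed)
    heats_ucal <- heats_ucal + stats::rnorm(length(heats_ucal), 0, noise_sd)
  }
  titration(protocol, heats_ucal)
}

#' Construct a titration from raw heats
#'
#' @param protocol an [injection_protocol()].
#' @param heats_ucal observed per-injection heats (ucal), one per injection.
#' @return object of class `titration` with derived `normalized` heats
#'   (kcal per mole of injectant).
#' @export
titration <- function(protocol, heats_ucal) {
  stopifnot(length(heats_ucal) == length(protocol$injection_volumes_uL))
  moles <- protocol$syringe_conc_uM * 1e-6 *
    protocol$injection_volumes_uL * 1e-6
  structure(list(protocol = protocol, heats_ucal = heats_ucal,
                 normalized = heats_ucal * 1e-9 / moles),
            class = "titration")
}
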