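# The normalized-heat model is linear in the enthalpies and the baseline
# offset once the dissociation constants (and N) are fixed: build the design
# matrix whose columns are the per-site heat responses at unit enthalpy, plus
# an intercept, and profile the linear parameters out by least squares.
linear_design <- function(protocol, kds, caps) {
  track <- cell_track(protocol, kds, caps)
  cols <- lapply(seq_along(kds), function(s) {
    dHs <- numeric(length(kds))
    dHs[s] <- 1
    heats_from_bound(track, dHs, 0, protocol$syringe_conc_uM)
  })
  cbind(do.call(cbind, cols), 1)
}

profiled_residuals <- function(y, X) {
  fit <- stats::lm.fit(X, y)
  list(residuals = fit$residuals, coef = fit$coefficients)
}

use_injections <- function(titration, exclude_first) {
  n <- length(titration$normalized)
  if (exclude_first) seq.int(2L, n) else seq_len(n)
}

#' Fit the single-site binding model to a titration
#'
#' Least-squares fit of normalized heats to the one-site isotherm, minimising
#' `chi2 = sum (obs - model)^2` in (kcal/mol)^2. The stoichiometry `N` and
#' `Kd` are optimised by Levenberg-Marquardt on a log scale; the enthalpy and
#' baseline offset are profiled out by linear least squares at every step.
#'
#' @param titration a [titration()].
#' @param init optional [one_site_params()] starting point; when omitted a
#'   coarse grid scan over `Kd` and `N` chooses the start.
#' @param fix_N optional value at which to hold the stoichiometry.
#' @param exclude_first drop the first injection (common ITC practice);
#'   default FALSE.
#' @return list of class `itc_fit`: `params` ([one_site_params()]), `chi2`,
#'   `converged`, `message`, `fitted`, `residuals`, and
#'   `kd_identifiable` (FALSE when the data carry no binding signal).
#' @export
fit_one_site <- function(titration, init = NULL, fix_N = NULL,
                         exclude_first = FALSE) {
  stopifnot(inherits(titration, "titration"))
  protocol <- titration$protocol
  if (length(titration$normalized) < 4L) stop("need at least 4 injections")
  keep <- use_injections(titration, exclude_first)
  y <- titration$normalized[keep]

  resid_fun <- function(theta) {
    N <- if (is.null(fix_N)) exp(theta[1]) else fix_N
    Kd <- exp(theta[length(theta)])
    X <- linear_design(protocol, Kd, N)[keep, , drop = FALSE]
    profiled_residuals(y, X)$residuals
  }

  if (is.null(init)) {
    kd_grid <- protocol$cell_conc_uM * 10^seq(-2, 2, by = 0.5)
    n_grid <- if (is.null(fix_N)) c(0.5, 1, 2, 4) else fix_N
    grid <- expand.grid(N = n_grid, Kd = kd_grid)
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      th <- log(c(if (is.null(fix_N)) grid$N[i], grid$Kd[i]))
      sum(resid_fun(th)^2)
    }, numeric(1))
    best <- grid[which.min(sse), ]
    init <- one_site_params(N = best$N, Kd = best$Kd)
  }
  theta0 <- log(c(if (is.null(fix_N)) init$N, init$Kd))

  fit <- minpack.lm::nls.lm(theta0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-12))
  theta <- fit$par
  N <- if (is.null(fix_N)) exp(theta[1]) else fix_N
  Kd <- exp(theta[length(theta)])
  X <- linear_design(protocol, Kd, N)[keep, , drop = FALSE]
  lin <- profiled_residuals(y, X)
  chi2 <- sum(lin$residuals^2)
  dH <- unname(lin$coef[1])
  offset <- unname(lin$coef[2])
  # no binding signal: the saturable component explains nothing beyond the
  # baseline, so Kd is not identifiable
  base_chi2 <- sum((y - mean(y))^2)
  identifiable <- abs(dH) > 1e-8 && (base_chi2 - chi2) > 1e-12 * max(1, base_chi2)

  structure(list(model = "one_site",
                 params = one_site_params(N = N, Kd = Kd, dH = dH,
                                          offset = offset),
                 chi2 = chi2, converged = fit$info %in% 1:4,
                 message = fit$message, fitted = y - lin$residuals,
                 residuals = lin$residuals, kd_identifiable = identifiable),
            class = "itc_fit")
}

#' Fit the two-independent-sites model to a titration
#'
#' Minimises `chi2` over `(Kd1, Kd2, dH1, dH2, offset)` with one ligand per
#' site (N1 = N2 = 1). The two dissociation constants are optimised on a log
#' scale; enthalpies and offset are profiled out linearly. The site-label
#' exchange symmetry is resolved by reporting `Kd1 <= Kd2`.
#'
#' @param titration a [titration()].
#' @param init optional [two_site_params()] start; default a coarse grid scan.
#' @param exclude_first drop the first injection.
#' @return list of class `itc_fit` with `params` ([two_site_params()]),
#'   `chi2`, `converged`, `degenerate` (TRUE when `Kd1 ~ Kd2`), `fitted`,
#'   `residuals`.
#' @export
fit_two_sites <- function(titration, init = NULL, exclude_first = FALSE) {
  stopifnot(inherits(titration, "titration"))
  protocol <- titration$protocol
  if (length(titration$normalized) < 6L) stop("need at least 6 injections")
  keep <- use_injections(titration, exclude_first)
  y <- titration$normalized[keep]

  resid_fun <- function(theta) {
    X <- linear_design(protocol, exp(theta), c(1, 1))[keep, , drop = FALSE]
    profiled_residuals(y, X)$residuals
  }

  if (is.null(init)) {
    kd_grid <- protocol$cell_conc_uM * 10^seq(-1.5, 1.5, by = 0.5)
    grid <- expand.grid(Kd1 = kd_grid, Kd2 = kd_grid)
    grid <- grid[grid$Kd1 <= grid$Kd2, , drop = FALSE]
    sse <- vapply(seq_len(nrow(grid)), function(i) {
      sum(resid_fun(log(c(grid$Kd1[i], grid$Kd2[i])))^2)
    }, numeric(1))
    best <- grid[which.min(sse), ]
    init <- two_site_params(Kd1 = best$Kd1, Kd2 = best$Kd2)
  }
  theta0 <- log(c(init$Kd1, init$Kd2))

  fit <- minpack.lm::nls.lm(theta0, fn = resid_fun,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-14, ptol = 1e-12))
  kds <- exp(fit$par)
  X <- linear_design(protocol, kds, c(1, 1))[keep, , drop = FALSE]
  lin <- profiled_residuals(y, X)
  dHs <- unname(lin$coef[1:2])
  offset <- unname(lin$coef[3])
  ord <- order(kds)
  kds <- kds[ord]
  dHs <- dHs[ord]
  degenerate <- abs(log(kds[2] / kds[1])) < 1e-3

  structure(list(model = "two_sites",
                 params = two_site_params(Kd1 = kds[1], Kd2 = kds[2],
                                          dH1 = dHs[1], dH2 = dHs[2],
                                          offset = offset),
                 chi2 = sum(lin$residuals^2), converged = fit$info %in% 1:4,
                 message = fit$message, fitted = y - lin$residuals,
                 residuals = lin$residuals, degenerate = degenerate),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("ITC fit (", x$model, "), chi2 = ", format(x$chi2, digits = 6), "\n",
      sep = "")
  p <- x$params
  if (x$model == "one_site") {
    cat(sprintf("  N = %.4g, Kd = %.4g uM, dH = %.4g kcal/mol, offset = %.4g\n",
                p$N, p$Kd, p$dH, p$offset))
  } else {
    cat(sprintf("  Kd1 = %.4g uM (dH1 = %.4g), Kd2 = %.4g uM (dH2 = %.4g), offset = %.4g\n",
                p$Kd1, p$dH1, p$Kd2, p$dH2, p$offset))
  }
  invisible(x)
}

#' Chi-square profile of the two dissociation constants
#'
#' Evaluates the two-site `chi2` on a `(Kd1, Kd2)` lattice, re-optimising the
#' enthalpies and baseline at every node (they enter linearly), and reports
#' the superlevel structure at a user-chosen `chi2` acceptance threshold: the
#' region of nodes with `chi2 <= threshold` and the range each `Kd` spans
#' over it. The threshold is a user input: raw-instrument `chi2` scales are
#' weighting-dependent and not portable.
#'
#' @param titration a [titration()].
#' @param kd1_grid,kd2_grid strictly positive, sorted grids (uM).
#' @param threshold `chi2` acceptance level.
#' @param exclude_first drop the first injection.
#' @return list of class `chi2_profile`: `grid` (data.frame `Kd1`, `Kd2`,
#'   `chi2`), `chi2_min`, `threshold`, `region` (rows of `grid` within the
#'   threshold) and `kd_ranges` (min/max of each Kd over the region; NA when
#'   the region is empty).
#' @export
chi2_profile_two_sites <- function(titration, kd1_grid, kd2_grid, threshold,
                                   exclude_first = FALSE) {
  stopifnot(inherits(titration, "titration"),
            all(kd1_grid > 0), all(kd2_grid > 0),
            !is.unsorted(kd1_grid), !is.unsorted(kd2_grid))
  protocol <- titration$protocol
  keep <- use_injections(titration, exclude_first)
  y <- titration$normalized[keep]
  grid <- expand.grid(Kd1 = kd1_grid, Kd2 = kd2_grid)
  grid$chi2 <- vapply(seq_len(nrow(grid)), function(i) {
    X <- linear_design(protocol, c(grid$Kd1[i], grid$Kd2[i]),
                       c(1, 1))[keep, , drop = FALSE]
    sum(profiled_residuals(y, X)$residuals^2)
  }, numeric(1))
  region <- grid[grid$chi2 <= threshold, , drop = FALSE]
  kd_ranges <- if (nrow(region)) {
    list(Kd1 = range(region$Kd1), Kd2 = range(region$Kd2))
  } else {
    list(Kd1 = c(NA_real_, NA_real_), Kd2 = c(NA_real_, NA_real_))
  }
  structure(list(grid = grid, chi2_min = min(grid$chi2),
                 threshold = threshold, region = region,
                 kd_ranges = kd_ranges),
            class = "chi2_profile")
}
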