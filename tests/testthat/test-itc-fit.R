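test_that("one-site round trips recover the generating parameters within 1%", {
  # c = N M0 / Kd spanning weak to tight regimes
  cases <- list(list(M0 = 100, Xs = 1000, N = 1.0, Kd = 100, dH = -5),   # c = 1
                list(M0 = 100, Xs = 1200, N = 1.2, Kd = 10, dH = -8),    # c = 12
                list(M0 = 200, Xs = 2500, N = 1.0, Kd = 1, dH = -4),     # c = 200
                list(M0 = 300, Xs = 4000, N = 1.0, Kd = 0.3, dH = -6))   # c = 1000
  for (cs in cases) {
    prot <- injection_protocol(1.43, cs$M0, cs$Xs, rep(9, 30))
    truth <- one_site_params(N = cs$N, Kd = cs$Kd, dH = cs$dH)
    ti <- simulate_isotherm(prot, truth)
    init <- one_site_params(N = cs$N * 1.5, Kd = cs$Kd * 1.5, dH = cs$dH * 1.5)
    fit <- fit_one_site(ti, init = init)
    expect_true(fit$converged)
    expect_equal(fit$params$N, cs$N, tolerance = 0.01)
    expect_equal(fit$params$Kd, cs$Kd, tolerance = 0.01)
    expect_equal(fit$params$dH, cs$dH, tolerance = 0.01)
  }
})

test_that("fixing N holds it constant during the one-site fit", {
  prot <- injection_protocol(1.43, 100, 1000, rep(9, 30))
  ti <- simulate_isotherm(prot, one_site_params(N = 1, Kd = 80, dH = -5))
  fit <- fit_one_site(ti, init = one_site_params(N = 1, Kd = 120, dH = -7.5),
                      fix_N = 1)
  expect_equal(fit$params$N, 1)
  expect_equal(fit$params$Kd, 80, tolerance = 0.01)
})

test_that("pure-offset data flag Kd as unidentifiable", {
  prot <- injection_protocol(1.43, 100, 1000, rep(9, 30))
  ti <- titration(prot, rep(0.5 * 1000e-6 * 9e-6 * 1e9, 30))  # flat 0.5 kcal/mol
  fit <- fit_one_site(ti, init = one_site_params(N = 1, Kd = 100, dH = -5))
  expect_false(fit$kd_identifiable)
  expect_lt(abs(fit$params$dH), 1e-6)
  expect_equal(fit$params$offset, 0.5, tolerance = 1e-6)
})

test_that("fit chi2 never exceeds chi2 at the initialization", {
  prot <- injection_protocol(1.43, 100, 1000, rep(9, 30))
  ti <- simulate_isotherm(prot, one_site_params(N = 1, Kd = 60, dH = -5),
                          noise_sd = 0.5, seed = 5)
  init <- one_site_params(N = 2, Kd = 300, dH = -2, offset = 0.3)
  chi2_init <- sum((ti$normalized - model_heats(prot, init))^2)
  fit <- fit_one_site(ti, init = init)
  expect_lte(fit$chi2, chi2_init)
  init2 <- two_site_params(30, 600, -3, -8, offset = 0.1)
  chi2_init2 <- sum((ti$normalized - model_heats(prot, init2))^2)
  fit2 <- fit_two_sites(ti, init = init2)
  expect_lte(fit2$chi2, chi2_init2)
})

test_that("two-site round trips recover both sites within 1% after ordering", {
  cases <- list(c(Kd1 = 20, Kd2 = 400, dH1 = -6, dH2 = -3),
                c(Kd1 = 175, Kd2 = 575, dH1 = -5, dH2 = -5))
  for (cs in cases) {
    prot <- injection_protocol(1.43, 97, 1420, rep(9, 30))
    truth <- two_site_params(cs["Kd1"], cs["Kd2"], cs["dH1"], cs["dH2"])
    ti <- simulate_isotherm(prot, truth)
    init <- two_site_params(cs["Kd1"] * 1.5, cs["Kd2"] * 1.5,
                            cs["dH1"] * 1.5, cs["dH2"] * 1.5)
    fit <- fit_two_sites(ti, init = init)
    expect_true(fit$converged)
    expect_lte(fit$params$Kd1, fit$params$Kd2)
    expect_equal(fit$params$Kd1, unname(cs["Kd1"]), tolerance = 0.01)
    expect_equal(fit$params$Kd2, unname(cs["Kd2"]), tolerance = 0.01)
    expect_equal(fit$params$dH1, unname(cs["dH1"]), tolerance = 0.01)
    expect_equal(fit$params$dH2, unname(cs["dH2"]), tolerance = 0.01)
  }
})

test_that("one-site data with N = 2 yield a degenerate two-site fit", {
  prot <- injection_protocol(1.43, 97, 1420, rep(9, 30))
  ti <- simulate_isotherm(prot, one_site_params(N = 2, Kd = 150, dH = -5))
  fit <- fit_two_sites(ti, init = two_site_params(100, 250, -4, -6))
  expect_equal(fit$params$Kd1 / fit$params$Kd2, 1, tolerance = 0.05)
})

test_that("injection-count preconditions are enforced", {
  prot <- injection_protocol(1.43, 100, 1000, rep(9, 3))
  ti <- simulate_isotherm(prot, one_site_params(N = 1, Kd = 50, dH = -5))
  expect_error(fit_one_site(ti), "4 injections")
  prot5 <- injection_protocol(1.43, 100, 1000, rep(9, 5))
  ti5 <- simulate_isotherm(prot5, one_site_params(N = 1, Kd = 50, dH = -5))
  expect_error(fit_two_sites(ti5), "6 injections")
})

test_that("chi2 profile has nested superlevel sets and a faithful minimum", {
  prot <- injection_protocol(1.43, 97, 1420, rep(9, 30))
  ti <- simulate_isotherm(prot, two_site_params(175, 575, -5, -5))
  kd1_grid <- c(50, 100, 175, 300, 500)
  kd2_grid <- c(300, 450, 575, 700, 926)
  prof <- chi2_profile_two_sites(ti, kd1_grid, kd2_grid, threshold = 1e-4)
  # noiseless data with the generating node on-grid: chi2_min ~ 0 there
  expect_lt(prof$chi2_min, 1e-12)
  best <- prof$grid[which.min(prof$grid$chi2), ]
  expect_equal(best$Kd1, 175)
  expect_equal(best$Kd2, 575)
  expect_true(all(prof$grid$chi2 >= prof$chi2_min))
  # threshold at the minimum leaves only the argmin set
  prof0 <- chi2_profile_two_sites(ti, kd1_grid, kd2_grid,
                                  threshold = prof$chi2_min)
  expect_equal(nrow(prof0$region), 1)
  # regions grow monotonically with the threshold
  ths <- c(1e-10, 1e-6, 1e-3, 1e-1)
  sizes <- vapply(ths, function(th) {
    nrow(chi2_profile_two_sites(ti, kd1_grid, kd2_grid, th)$region)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
  # kd ranges cover the region, empty region reported as NA
  expect_equal(prof$kd_ranges$Kd1, range(prof$region$Kd1))
  prof_empty <- chi2_profile_two_sites(ti, c(40, 60), c(800, 926),
                                       threshold = 1e-16)
  expect_equal(nrow(prof_empty$region), 0)
  expect_true(all(is.na(prof_empty$kd_ranges$Kd1)))
})

test_that("free-energy conversions match closed forms", {
  expect_equal(ddg_ratio(1), 0)
  expect_equal(round(ddg_ratio(3, 298.15), 1), 0.7)
  expect_equal(ddg_ratio(3, 298.15), 0.651, tolerance = 1e-3)
  expect_equal(ddg_ratio(exp(1), 298.15), 1.987204e-3 * 298.15)
  # delta_g is additive over ratios: dG(a Kd) - dG(Kd) = ddG(a)
  expect_equal(delta_g(129) - delta_g(43), ddg_ratio(3))
  expect_lt(delta_g(43), 0)
  expect_error(delta_g(-1), "Kd")
  expect_error(ddg_ratio(0), "ratio")
})
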