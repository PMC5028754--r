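test_that("proteome generation is seed-deterministic and validates input", {
  p1 <- generate_proteome(1, c(10, 10), seed = 7)
  p2 <- generate_proteome(1, c(10, 10), seed = 7)
  expect_identical(p1, p2)
  expect_equal(nchar(unname(p1[1])), 10)
  expect_false(identical(p1, generate_proteome(1, c(10, 10), seed = 8)))
  expect_error(generate_proteome(0, c(10, 10)), "n_proteins")
  expect_error(generate_proteome(2, c(20, 10)), "length_range")
  expect_error(generate_proteome(2, c(10, 20), aa_frequencies = rep(1, 20)),
               "sum")
})

test_that("residue composition converges to the requested frequencies", {
  p <- generate_proteome(100, c(200, 400), seed = 1)
  res <- strsplit(paste(p, collapse = ""), "")[[1]]
  freq <- table(factor(res, levels = AA_ALPHABET)) / length(res)
  expect_true(all(abs(freq - 1 / 20) < 0.05))
  # skewed composition is respected too
  w <- c(0.5, rep(0.5 / 19, 19))
  p2 <- generate_proteome(50, c(200, 300), aa_frequencies = w, seed = 2)
  res2 <- strsplit(paste(p2, collapse = ""), "")[[1]]
  expect_equal(mean(res2 == "A"), 0.5, tolerance = 0.05)
})

test_that("tryptic digestion follows the cleave/block rule", {
  rule <- digest_rule(min_len = 1, max_len = 100)
  p <- structure(c(p1 = "MKRAPKG"), class = "proteome")
  expect_equal(digest_proteome(p, rule)$peptide, c("MK", "R", "APK", "G"))
  # K-P junction blocked; terminal R ends the protein without a cut
  p2 <- structure(c(p1 = "MKPR"), class = "proteome")
  expect_equal(digest_proteome(p2, rule)$peptide, "MKPR")
  expect_equal(nrow(digest_proteome(character(), rule)), 0)
})

test_that("digest fragments tile each parent protein before length filtering", {
  prot <- generate_proteome(20, c(50, 150), seed = 3)
  frags <- digest_proteome(prot, digest_rule(min_len = 1, max_len = 10000))
  for (id in names(prot)) {
    f <- frags[frags$protein_id == id, ]
    f <- f[order(f$start), ]
    expect_equal(f$start, c(1L, utils::head(f$end, -1) + 1L))
    expect_equal(f$end[nrow(f)], nchar(prot[[id]]))
    expect_equal(paste(f$peptide, collapse = ""), unname(prot[[id]]))
    expect_equal(substring(prot[[id]], f$start, f$end), f$peptide)
  }
  # length window applied after fragmentation
  filt <- digest_proteome(prot, digest_rule(min_len = 5, max_len = 40))
  len <- nchar(filt$peptide)
  expect_true(all(len >= 5 & len <= 40))
})

test_that("a planted P1 protease emits the biotinylated prime-side fragment", {
  lib <- data.frame(peptide = "AAAFGGGG", protein_id = "p1",
                    start = 1L, end = 8L)
  prot <- protease_spec(list(P1 = c(F = 1)), efficiency = 1)
  runs <- simulate_pics_runs(lib, prot, pics_noise(n_background = 0), seed = 1)
  expect_equal(runs$test$peptide, "GGGG")
  expect_true(all(runs$test$nterm_biotin))
  expect_true(all(runs$test$confidence > 80))
  expect_equal(nrow(runs$mock), 0)
  expect_equal(runs$library$peptide, "AAAFGGGG")
})

test_that("a null protease leaves the test run identical to the mock run", {
  lib <- digest_proteome(generate_proteome(10, c(50, 100), seed = 4))
  prot <- protease_spec(list(P1 = c(F = 1)), efficiency = 0)
  runs <- simulate_pics_runs(lib, prot, pics_noise(n_background = 50), seed = 9)
  expect_identical(runs$test, runs$mock)
  expect_identical(runs$inactive, runs$mock)
})

test_that("background peptides are shared across runs and the library run covers the library", {
  lib <- digest_proteome(generate_proteome(10, c(80, 120), seed = 5))
  prot <- protease_spec(list(P1 = c(K = 1)), efficiency = 0.5)
  runs <- simulate_pics_runs(lib, prot, pics_noise(n_background = 30), seed = 2)
  expect_true(all(runs$mock$peptide %in% runs$test$peptide))
  expect_identical(runs$mock, runs$inactive)
  expect_setequal(runs$library$peptide, lib$peptide)
  # seed determinism of the whole run set
  runs2 <- simulate_pics_runs(lib, prot, pics_noise(n_background = 30), seed = 2)
  expect_identical(runs, runs2)
})

test_that("simulated isotherms honour stoichiometric limits and model degeneracy", {
  prot <- injection_protocol(1.43, 100, 1000, rep(9, 30))
  # Kd -> 0: heat per mole equals dH before the equivalence point, 0 after
  tight <- simulate_isotherm(prot, one_site_params(N = 1, Kd = 1e-9, dH = -5))
  ratio <- molar_ratio(prot)
  expect_equal(tight$normalized[ratio < 0.8], rep(-5, sum(ratio < 0.8)),
               tolerance = 1e-6)
  expect_equal(tight$normalized[ratio > 1.3], rep(0, sum(ratio > 1.3)),
               tolerance = 1e-3)
  # two equal sites collapse onto one site with N = 2
  t2 <- simulate_isotherm(prot, two_site_params(50, 50, -5, -5))
  t1 <- simulate_isotherm(prot, one_site_params(N = 2, Kd = 50, dH = -5))
  expect_equal(t2$normalized, t1$normalized, tolerance = 1e-10)
  # noise_sd = 0 deterministic; noise seeded
  expect_identical(simulate_isotherm(prot, one_site_params(N = 1, Kd = 50))$heats_ucal,
                   simulate_isotherm(prot, one_site_params(N = 1, Kd = 50))$heats_ucal)
  n1 <- simulate_isotherm(prot, one_site_params(N = 1, Kd = 50), noise_sd = 1, seed = 3)
  n2 <- simulate_isotherm(prot, one_site_params(N = 1, Kd = 50), noise_sd = 1, seed = 3)
  expect_identical(n1$heats_ucal, n2$heats_ucal)
})

test_that("the printed RVP-UBA protocol sits at Wiseman c of about 1.5", {
  prot <- injection_protocol(1.43, 64.8, 796, rep(9, 30))
  expect_equal(wiseman_c(prot, one_site_params(N = 1, Kd = 43)), 64.8 / 43,
               tolerance = 1e-12)
  expect_equal(round(wiseman_c(prot, one_site_params(N = 1, Kd = 43)), 1), 1.5)
})
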