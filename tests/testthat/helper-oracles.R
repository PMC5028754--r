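# Independent brute-force oracles for the equilibrium solvers: plain
# bisection on the mass-balance equations, sharing no code with the package's
# stable-quadratic / safeguarded-Newton implementations.

bisect_bound_one_site <- function(Mt, Lt, N, Kd, iters = 200L) {
  cap <- N * Mt
  f <- function(B) B * Kd - (cap - B) * (Lt - B)
  lo <- 0
  hi <- min(Lt, cap)
  if (hi == 0) return(0)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

bisect_free_two_sites <- function(Mt, Lt, Kd1, Kd2, iters = 200L) {
  g <- function(L) L + Mt * L / (Kd1 + L) + Mt * L / (Kd2 + L) - Lt
  lo <- 0
  hi <- Lt
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# Small fixed run set used by the cascade hand-trace tests.
toy_runs <- function() {
  mk <- function(peptide, biotin, conf) {
    data.frame(peptide = peptide, nterm_biotin = biotin, confidence = conf)
  }
  list(test = mk(c("AAAAA", "CCCCC", "DDDDD", "EEEEE", "FFFFF"),
                 rep(TRUE, 5), c(95, 85, 70, 90, 88)),
       inactive = mk(character(), logical(), numeric()),
       mock = mk("EEEEE", TRUE, 50),
       library = mk("FFFFF", TRUE, 60))
}
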