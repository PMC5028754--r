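#' Planted protease specificity
#'
#' A position-weight description of a protease: per-subsite residue weights
#' over the ten Schechter-Berger subsites P5..P1 (non-prime) and P1'..P5'
#' (prime), plus an overall cleavage efficiency. Subsites not listed are
#' treated as indifferent. Weights are normalised within each subsite by their
#' maximum, so a bond matching the preferred residue at every stated subsite
#' is cleaved with probability `efficiency`.
#'
#' @param preference named list; names from
#'   `c("P5","P4","P3","P2","P1","P1p","P2p","P3p","P4p","P5p")`, each element
#'   a named numeric vector of non-negative residue weights.
#' @param efficiency probability in `[0, 1]` that a perfectly matching site is
#'   cleaved.
#' @return list of class `protease_spec`.
#' @examples
#' protease_spec(list(P1 = c(F = 1)), efficiency = 1)
#' @export
protease_spec <- function(preference, efficiency = 1) {
  sites <- c("P5", "P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p", "P5p")
  stopifnot(is.list(preference), all(names(preference) %in% sites),
            efficiency >= 0, efficiency <= 1)
  pref <- lapply(preference, function(w) {
    stopifnot(all(names(w) %in% AA_ALPHABET), all(w >= 0), max(w) > 0)
    full <- stats::setNames(numeric(20), AA_ALPHABET)
    full[names(w)] <- w
    full / max(full)
  })
  structure(list(preference = pref, efficiency = efficiency),
            class = "protease_spec")
}

#' Identification-noise settings for simulated PICS runs
#'
#' @param n_background number of background (uncleaved library / contaminant)
#'   peptides added identically to the test, inactive-mutant and mock runs.
#' @param frac_biotin_artifact fraction of background and library-run peptides
#'   spuriously carrying the biotin N-terminal flag.
#' @param frac_decoy fraction of background peptides replaced by shuffled
#'   (decoy) sequences.
#' @param conf_true range of identification confidence (percent) for genuine
#'   cleavage products.
#' @param conf_background confidence range for background peptides.
#' @return list of class `pics_noise`.
#' @export
pics_noise <- function(n_background = 0L, frac_biotin_artifact = 0.1,
                       frac_decoy = 0.05, conf_true = c(85, 100),
                       conf_background = c(5, 95)) {
  structure(list(n_background = as.integer(n_background),
                 frac_biotin_artifact = frac_biotin_artifact,
                 frac_decoy = frac_decoy, conf_true = conf_true,
                 conf_background = conf_background),
            class = "pics_noise")
}

# Probability that the bond after residue j of `peptide` is cleaved, given the
# protease's per-subsite weights. Subsites falling outside the peptide
# contribute a neutral factor of 1 (context unknown within the library
# peptide; the planted motif is always expressible inside it in tests).
cleavage_probs <- function(peptide, protease) {
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  n <- length(res)
  if (n < 2L) return(numeric(0))
  offsets <- c(P5 = -4L, P4 = -3L, P3 = -2L, P2 = -1L, P1 = 0L,
               P1p = 1L, P2p = 2L, P3p = 3L, P4p = 4L, P5p = 5L)
  p <- rep(protease$efficiency, n - 1L)
  for (site in names(protease$preference)) {
    idx <- seq_len(n - 1L) + offsets[[site]]
    w <- ifelse(idx >= 1L & idx <= n,
                protease$preference[[site]][res[pmin(pmax(idx, 1L), n)]], 1)
    p <- p * w
  }
  unname(p)
}

shuffle_seq <- function(s) {
  paste(sample(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Simulate the four MS identification runs of a PICS experiment
#'
#' Applies a planted protease to a peptide library and emits the four
#' identification lists of the screen: the test-enzyme reaction, the
#' catalytically inactive control, the mock (buffer) control, and the
#' unprocessed library. Each internal bond of each library peptide is cleaved
#' independently with probability `efficiency` times the normalised motif
#' match; every cleavage emits the prime-side fragment (up to the next cut)
#' flagged as carrying a biotinylated neo-N-terminus. Background peptides are
#' drawn from the library (plus a decoy fraction) and injected identically
#' into the three reaction runs, so control subtraction is meaningful; the
#' library run contains every library peptide. With `efficiency = 0` the test
#' run is identical to the mock run.
#'
#' @param library data.frame from [digest_proteome()].
#' @param protease a [protease_spec()].
#' @param noise a [pics_noise()].
#' @param seed integer seed.
#' @return list of class `pics_runs` with data.frames `test`, `inactive`,
#'   `mock`, `library`, each with columns `peptide`, `nterm_biotin`,
#'   `confidence`.
#' @export
simulate_pics_runs <- function(library, protease, noise = pics_noise(),
                               seed = 1L) {
  stopifnot(inherits(protease, "protease_spec"), inherits(noise, "pics_noise"))
  if (nrow(library) == 0L) stop("peptide library is empty")
  set.seed(seed)

  runif2 <- function(n, r) stats::runif(n, r[1], r[2])
  mk <- function(peptide, biotin, conf) {
    data.frame(peptide = peptide, nterm_biotin = biotin, confidence = conf)
  }

  # background identifications, shared across test / inactive / mock
  nb <- noise$n_background
  if (nb > 0L) {
    bg_seq <- library$peptide[sample.int(nrow(library), nb, replace = TRUE)]
    n_dec <- round(noise$frac_decoy * nb)
    if (n_dec > 0L) {
      dec_idx <- sample.int(nb, n_dec)
      bg_seq[dec_idx] <- vapply(bg_seq[dec_idx], shuffle_seq, character(1))
    }
    background <- mk(bg_seq,
                     stats::runif(nb) < noise$frac_biotin_artifact,
                     runif2(nb, noise$conf_background))
  } else {
    background <- mk(character(), logical(), numeric())
  }

  # genuine cleavage products: prime-side fragments of cleaved bonds
  products <- character()
  if (protease$efficiency > 0) {
    for (i in seq_len(nrow(library))) {
      pep <- library$peptide[i]
      p <- cleavage_probs(pep, protease)
      cut <- which(stats::runif(length(p)) < p)
      if (length(cut)) {
        frag_start <- cut + 1L
        frag_end <- c(cut[-1L], nchar(pep))
        products <- c(products, substring(pep, frag_start, frag_end))
      }
    }
  }
  test <- rbind(background,
                mk(products, rep(TRUE, length(products)),
                   runif2(length(products), noise$conf_true)))

  # unprocessed library run: every library peptide identified once
  nl <- nrow(library)
  lib_run <- mk(library$peptide,
                stats::runif(nl) < noise$frac_biotin_artifact,
                runif2(nl, noise$conf_background))

  structure(list(test = test, inactive = background, mock = background,
                 library = lib_run),
            class = "pics_runs")
}
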