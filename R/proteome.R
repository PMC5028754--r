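#' Canonical amino-acid alphabet
#'
#' The 20 proteinogenic residues in alphabetical one-letter order, the row
#' order used by every specificity matrix in this package.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Generate a random synthetic proteome
#'
#' Draws `n_proteins` independent sequences over the 20-letter alphabet with
#' i.i.d. residues at the supplied frequencies. Stands in for the FASTA
#' database a peptide-library screen is searched against.
#'
#' @param n_proteins number of proteins (>= 1).
#' @param length_range integer vector of length 2, inclusive range of protein
#'   lengths; lengths are drawn uniformly.
#' @param aa_frequencies numeric 20-vector of residue frequencies in the order
#'   of [AA_ALPHABET]; must sum to 1 (tolerance 1e-6). Default uniform.
#' @param seed integer seed; identical arguments and seed give identical output.
#' @return named character vector of class `proteome`; names are protein ids
#'   `"prot0001"`, ...
#' @examples
#' p <- generate_proteome(3, c(50, 80), seed = 1)
#' nchar(p)
#' @export
generate_proteome <- function(n_proteins, length_range,
                              aa_frequencies = rep(1 / 20, 20), seed = 1L) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    stop("length_range must be a valid inclusive range of positive lengths")
  }
  if (length(aa_frequencies) != 20L || any(aa_frequencies < 0) ||
      abs(sum(aa_frequencies) - 1) > 1e-6) {
    stop("aa_frequencies must be 20 non-negative values summing to 1")
  }
  set.seed(seed)
  lens <- sample(seq.int(length_range[1], length_range[2]), n_proteins,
                 replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_ALPHABET, L, replace = TRUE, prob = aa_frequencies),
          collapse = "")
  }, character(1))
  names(seqs) <- sprintf("prot%04d", seq_len(n_proteins))
  structure(seqs, class = "proteome")
}

#' Site-specific endoprotease digestion rule
#'
#' @param name rule label.
#' @param cleave_after residues after which the backbone is cut.
#' @param blocked_by_next residues that, when immediately C-terminal to a
#'   candidate site, block cleavage (trypsin: proline).
#' @param min_len,max_len retained fragment length range (applied after
#'   fragmentation).
#' @return list of class `digest_rule`.
#' @export
digest_rule <- function(name = "trypsin", cleave_after = c("K", "R"),
                        blocked_by_next = "P", min_len = 5L, max_len = 40L) {
  stopifnot(all(cleave_after %in% AA_ALPHABET),
            all(blocked_by_next %in% AA_ALPHABET))
  if (min_len < 1 || min_len > max_len) stop("need 1 <= min_len <= max_len")
  structure(list(name = name, cleave_after = cleave_after,
                 blocked_by_next = blocked_by_next,
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "digest_rule")
}

#' Digest a proteome into a peptide library
#'
#' Cuts each protein after every residue in `cleave_after` unless the next
#' residue is in `blocked_by_next`, then drops fragments outside
#' `[min_len, max_len]`. Before length filtering the fragments of each protein
#' tile its full sequence, so parent coordinates are exact.
#'
#' @param proteome a [generate_proteome()] result or any named character vector
#'   of sequences.
#' @param rule a [digest_rule()].
#' @return data.frame with columns `peptide`, `protein_id`, `start`, `end`
#'   (1-based inclusive coordinates in the parent protein).
#' @examples
#' digest_proteome(c(p1 = "MKRAPKG"), digest_rule(min_len = 1, max_len = 100))
#' @export
digest_proteome <- function(proteome, rule = digest_rule()) {
  stopifnot(inherits(rule, "digest_rule"))
  if (length(proteome) == 0L) {
    return(data.frame(peptide = character(), protein_id = character(),
                      start = integer(), end = integer()))
  }
  pieces <- lapply(names(proteome), function(id) {
    s <- proteome[[id]]
    res <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- length(res)
    cut_after <- which(res %in% rule$cleave_after)
    cut_after <- cut_after[cut_after < n]
    if (length(rule$blocked_by_next)) {
      cut_after <- cut_after[!(res[cut_after + 1L] %in% rule$blocked_by_next)]
    }
    starts <- c(1L, cut_after + 1L)
    ends <- c(cut_after, n)
    data.frame(peptide = substring(s, starts, ends), protein_id = id,
               start = starts, end = ends)
  })
  out <- do.call(rbind, pieces)
  len <- out$end - out$start + 1L
  out <- out[len >= rule$min_len & len <= rule$max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}
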