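empty_windows <- function() {
  data.frame(peptide = character(), protein_id = character(),
             cut_position = integer(), nonprime = character(),
             prime = character(), ambiguous = logical())
}

#' Reconstruct a cleavage window for one prime-side peptide
#'
#' Aligns a surviving prime-side peptide back to the proteome by exact
#' substring matching. Each occurrence contributes the five residues
#' immediately N-terminal as a candidate non-prime (P5..P1) window; positions
#' beyond the protein N-terminus are padded with the gap symbol `-`. The
#' ambiguity rule is:
#' * exactly one distinct preceding sequence: the non-prime window is
#'   assigned (duplicate occurrences with identical context collapse);
#' * several distinct preceding sequences: the non-prime side is discarded as
#'   ambiguous, but the peptide's prime side is kept;
#' * no occurrence: the peptide is dropped.
#'
#' @param peptide prime-side peptide sequence (non-empty).
#' @param proteome named character vector of protein sequences.
#' @return one-row data.frame with columns `peptide`, `protein_id`,
#'   `cut_position` (1-based index of the P1 residue in the parent, NA if
#'   ambiguous or at the N-terminus), `nonprime`, `prime` (5-character
#'   strings, `-`-padded), `ambiguous`; or a zero-row frame if unmappable.
#' @export
map_prime_peptide <- function(peptide, proteome) {
  stopifnot(nchar(peptide) >= 1L)
  if (length(proteome) == 0L) stop("proteome is empty")

  prime <- substr(paste0(peptide, "-----"), 1L, 5L)
  hit_id <- character()
  hit_pos <- integer()
  for (id in sort(names(proteome))) {
    m <- gregexpr(peptide, proteome[[id]], fixed = TRUE)[[1]]
    if (m[1] != -1L) {
      hit_id <- c(hit_id, rep(id, length(m)))
      hit_pos <- c(hit_pos, as.integer(m))
    }
  }
  if (length(hit_id) == 0L) return(empty_windows())
  preceding <- vapply(seq_along(hit_id), function(i) {
    s <- proteome[[hit_id[i]]]
    from <- hit_pos[i] - 5L
    ctx <- substr(s, max(1L, from), hit_pos[i] - 1L)
    paste0(strrep("-", 5L - nchar(ctx)), ctx)
  }, character(1))

  if (length(unique(preceding)) == 1L) {
    cut <- hit_pos[1] - 1L
    data.frame(peptide = peptide, protein_id = hit_id[1],
               cut_position = if (cut >= 1L) cut else NA_integer_,
               nonprime = preceding[1], prime = prime, ambiguous = FALSE)
  } else {
    data.frame(peptide = peptide, protein_id = NA_character_,
               cut_position = NA_integer_, nonprime = NA_character_,
               prime = prime, ambiguous = TRUE)
  }
}

#' Map all surviving peptides to cleavage windows
#'
#' Applies [map_prime_peptide()] to each survivor of the filter cascade.
#' Peptides with no proteome occurrence are excluded and counted.
#'
#' @param survivors data.frame with a `peptide` column (e.g. the `survivors`
#'   element of [run_cascade()]).
#' @param proteome named character vector of protein sequences.
#' @return list with `windows` (row-bound cleavage windows) and `report`
#'   (`n_input`, `n_mapped`, `n_ambiguous`, `n_unmapped`).
#' @export
map_all <- function(survivors, proteome) {
  peps <- unique(survivors$peptide)
  rows <- lapply(peps, map_prime_peptide, proteome = proteome)
  windows <- do.call(rbind, c(rows, list(empty_windows())))
  rownames(windows) <- NULL
  list(windows = windows,
       report = list(n_input = length(peps), n_mapped = nrow(windows),
                     n_ambiguous = sum(windows$ambiguous),
                     n_unmapped = length(peps) - nrow(windows)))
}
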