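SUBSITES <- c("P5", "P4", "P3", "P2", "P1", "P1p", "P2p", "P3p", "P4p", "P5p")

#' Build the substrate-specificity matrix
#'
#' Tallies amino-acid occurrences per subsite over a set of cleavage windows
#' and normalises each subsite column to frequencies. Gap symbols (window
#' positions beyond a protein terminus or a short peptide) are excluded from
#' both counts and column totals. Non-prime columns of ambiguous windows are
#' skipped; by default their prime side still contributes
#' (`ambiguous_prime = FALSE` drops ambiguous windows entirely).
#'
#' @param windows cleavage-window data.frame from [map_all()].
#' @param ambiguous_prime should ambiguous windows contribute prime-side
#'   counts? Default TRUE.
#' @param background optional 20-vector of background residue frequencies
#'   (e.g. library composition) used by [enrichment()].
#' @return object of class `specificity_matrix`: list with `counts` and
#'   `frequencies` (20 x 10 matrices, rows [AA_ALPHABET], columns P5..P5'),
#'   `n_windows`, `empty_columns` (logical 10-vector) and `background`.
#' @export
build_matrix <- function(windows, ambiguous_prime = TRUE, background = NULL) {
  counts <- matrix(0L, nrow = 20L, ncol = 10L,
                   dimnames = list(AA_ALPHABET, SUBSITES))
  if (!is.null(background)) {
    stopifnot(length(background) == 20L, all(background >= 0))
    background <- stats::setNames(as.numeric(background), AA_ALPHABET)
  }
  if (nrow(windows)) {
    tally <- function(strings, cols) {
      for (k in 1:5) {
        res <- substr(strings, k, k)
        ok <- res %in% AA_ALPHABET
        if (any(ok)) {
          t1 <- table(factor(res[ok], levels = AA_ALPHABET))
          counts[, cols[k]] <<- counts[, cols[k]] + as.integer(t1)
        }
      }
    }
    concrete <- windows[!windows$ambiguous, , drop = FALSE]
    if (nrow(concrete)) tally(concrete$nonprime, SUBSITES[1:5])
    prime_rows <- if (ambiguous_prime) windows else concrete
    if (nrow(prime_rows)) tally(prime_rows$prime, SUBSITES[6:10])
  }
  totals <- colSums(counts)
  freqs <- sweep(counts, 2, pmax(totals, 1L), "/")
  freqs[, totals == 0L] <- 0
  structure(list(counts = counts, frequencies = freqs,
                 n_windows = nrow(windows), empty_columns = totals == 0L,
                 background = background),
            class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("Substrate specificity matrix:", x$n_windows, "cleavage windows\n")
  if (x$n_windows == 0L) {
    cat("  (empty: no cleavage detected)\n")
  } else {
    top <- apply(x$frequencies, 2, function(col) {
      if (all(col == 0)) "-" else
        sprintf("%s (%.2f)", AA_ALPHABET[which.max(col)], max(col))
    })
    print(noquote(top))
  }
  invisible(x)
}

#' Enrichment of subsite frequencies over library background
#'
#' Divides each subsite frequency by the background frequency of the residue.
#' Residues with zero background are undefined (`NaN`); columns with no
#' observations are flagged by the matrix's `empty_columns`.
#'
#' @param matrix a `specificity_matrix` built with a `background`.
#' @return 20 x 10 numeric matrix of frequency / background ratios.
#' @export
enrichment <- function(matrix) {
  stopifnot(inherits(matrix, "specificity_matrix"))
  if (is.null(matrix$background)) stop("matrix has no background frequencies")
  bg <- matrix$background
  out <- matrix$frequencies / bg
  out[bg == 0, ] <- NaN
  out
}

#' Write a specificity matrix to TSV
#'
#' Rows are the 20 amino acids, columns the fixed subsite order
#' P5,P4,P3,P2,P1,P1p,P2p,P3p,P4p,P5p; the header line carries `n_windows` as
#' a comment so the round trip preserves the window count.
#'
#' @param matrix a `specificity_matrix`.
#' @param path output file.
#' @param what `"frequencies"` (default) or `"counts"`.
#' @export
export_matrix <- function(matrix, path, what = c("frequencies", "counts")) {
  what <- match.arg(what)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_windows=%d empty=%s", matrix$n_windows,
                     paste(which(matrix$empty_columns), collapse = ",")), con)
  tab <- data.frame(aa = AA_ALPHABET, matrix[[what]], check.names = FALSE)
  utils::write.table(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a specificity matrix written by [export_matrix()]
#'
#' @param path TSV file.
#' @return list with the numeric 20 x 10 `matrix` and `n_windows`.
#' @export
read_matrix_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  n_windows <- as.integer(sub(".*n_windows=(\\d+).*", "\\1", header))
  tab <- utils::read.delim(path, skip = 1L, check.names = FALSE)
  m <- as.matrix(tab[, SUBSITES])
  rownames(m) <- tab$aa
  list(matrix = m, n_windows = n_windows)
}

#' Per-subsite stacked-letter plot of a specificity matrix
#'
#' A simple sequence-logo-style figure: at each subsite, residues observed
#' there are stacked with heights equal to their frequencies.
#'
#' @param matrix a `specificity_matrix`.
#' @return a ggplot object.
#' @export
plot_specificity <- function(matrix) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_specificity requires ggplot2")
  }
  f <- matrix$frequencies
  df <- data.frame(subsite = factor(rep(SUBSITES, each = 20L),
                                    levels = SUBSITES),
                   aa = rep(AA_ALPHABET, 10L), freq = as.vector(f))
  df <- df[df$freq > 0, , drop = FALSE]
  df <- df[order(df$subsite, df$freq), , drop = FALSE]
  ymax <- stats::ave(df$freq, df$subsite, FUN = cumsum)
  df$y <- ymax - df$freq / 2
  ggplot2::ggplot(df, ggplot2::aes(x = subsite, y = y,
                                   label = aa, size = freq)) +
    ggplot2::geom_text(ggplot2::aes(colour = aa), show.legend = FALSE) +
    ggplot2::scale_size(range = c(2, 10)) +
    ggplot2::labs(x = "subsite", y = "frequency") +
    ggplot2::theme_minimal()
}
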