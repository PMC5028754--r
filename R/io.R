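#' Write a proteome to FASTA
#'
#' @param proteome named character vector of sequences.
#' @param path output FASTA file.
#' @export
write_proteome_fasta <- function(proteome, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(unclass(proteome)), path)
}

#' Read a proteome from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of class `proteome`.
#' @export
read_proteome_fasta <- function(path) {
  if (!file.exists(path)) stop("proteome FASTA not found: ", path)
  x <- Biostrings::readAAStringSet(path)
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(x))
  structure(seqs, class = "proteome")
}

#' Write the four identification runs to one TSV
#'
#' Columns: `run` (test / inactive / mock / library), `peptide`,
#' `nterm_biotin` (0/1), `confidence`.
#'
#' @param runs a `pics_runs` list.
#' @param path output TSV.
#' @export
write_runs_tsv <- function(runs, path) {
  tab <- do.call(rbind, lapply(c("test", "inactive", "mock", "library"),
                               function(r) {
    d <- runs[[r]]
    data.frame(run = rep(r, nrow(d)), peptide = d$peptide,
               nterm_biotin = as.integer(d$nterm_biotin),
               confidence = d$confidence)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read identification runs written by [write_runs_tsv()]
#'
#' @param path TSV file.
#' @return a `pics_runs` list with data.frames `test`, `inactive`, `mock`,
#'   `library`.
#' @export
read_runs_tsv <- function(path) {
  if (!file.exists(path)) stop("run TSV not found: ", path)
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, c("run", "peptide", "nterm_biotin", "confidence"))) {
    stop("malformed run TSV (expected columns run, peptide, nterm_biotin, confidence): ", path)
  }
  tab <- utils::read.delim(path, colClasses = c("character", "character",
                                                "integer", "numeric"))
  out <- lapply(c(test = "test", inactive = "inactive", mock = "mock",
                  library = "library"), function(r) {
    d <- tab[tab$run == r, c("peptide", "nterm_biotin", "confidence")]
    d$nterm_biotin <- as.logical(d$nterm_biotin)
    rownames(d) <- NULL
    d
  })
  structure(out, class = "pics_runs")
}

#' Write cleavage windows to TSV
#'
#' Columns: `protein_id`, `cut_position`, `P5..P1`, `P1p..P5p`,
#' `ambiguous_flag`, `peptide`. Window residues are written one column per
#' subsite; gap positions carry `-`.
#'
#' @param windows data.frame from [map_all()].
#' @param path output TSV.
#' @export
write_windows_tsv <- function(windows, path) {
  split_cols <- function(strings, labels) {
    out <- lapply(1:5, function(k) substr(strings, k, k))
    names(out) <- labels
    out[] <- lapply(out, function(v) ifelse(v == "", "-", v))
    out
  }
  np <- ifelse(is.na(windows$nonprime), "-----", windows$nonprime)
  tab <- data.frame(protein_id = ifelse(is.na(windows$protein_id), "",
                                        windows$protein_id),
                    cut_position = windows$cut_position,
                    split_cols(np, SUBSITES[1:5]),
                    split_cols(windows$prime, SUBSITES[6:10]),
                    ambiguous_flag = as.integer(windows$ambiguous),
                    peptide = windows$peptide, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a titration to TSV
#'
#' Columns: `injection_index`, `volume_uL`, `heat_ucal`; the protocol
#' (cell volume/concentration, syringe concentration, temperature) rides in
#' `#`-prefixed header lines so the file round-trips.
#'
#' @param titr a [titration()].
#' @param path output TSV.
#' @export
write_titration_tsv <- function(titr, path) {
  p <- titr$protocol
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# cell_volume_mL=%.17g", p$cell_volume_mL),
               sprintf("# cell_conc_uM=%.17g", p$cell_conc_uM),
               sprintf("# syringe_conc_uM=%.17g", p$syringe_conc_uM),
               sprintf("# temperature_K=%.17g", p$temperature_K)), con)
  tab <- data.frame(injection_index = seq_along(titr$heats_ucal),
                    volume_uL = p$injection_volumes_uL,
                    heat_ucal = titr$heats_ucal)
  utils::write.table(format(tab, digits = 17, scientific = FALSE, trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a titration written by [write_titration_tsv()]
#'
#' @param path TSV file.
#' @return a [titration()].
#' @export
read_titration_tsv <- function(path) {
  if (!file.exists(path)) stop("titration TSV not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getval <- function(key) {
    ln <- grep(paste0("^# ", key, "="), hdr, value = TRUE)
    if (!length(ln)) stop("titration TSV missing header field ", key)
    as.numeric(sub(".*=", "", ln[1]))
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)])
  protocol <- injection_protocol(getval("cell_volume_mL"),
                                 getval("cell_conc_uM"),
                                 getval("syringe_conc_uM"),
                                 tab$volume_uL, getval("temperature_K"))
  titration(protocol, tab$heat_ucal)
}

#' Write an ITC fit (or any report list) to JSON
#'
#' @param fit an `itc_fit` or plain list.
#' @param path output JSON file.
#' @export
write_fit_json <- function(fit, path) {
  x <- unclass(fit)
  x$params <- unclass(x$params)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Default pipeline configuration
#'
#' The constants of the screen and the titrations in one serialisable list:
#' confidence thresholds (test 80, controls 10), the library digest rule, and
#' the simulation seeds.
#'
#' @param test_confidence,control_confidence cascade thresholds (percent).
#' @param digest a [digest_rule()].
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(test_confidence = 80, control_confidence = 10,
                            digest = digest_rule(), seed = 1L) {
  structure(list(test_confidence = test_confidence,
                 control_confidence = control_confidence,
                 digest = unclass(digest), seed = seed),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration (YAML)
#'
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- pipeline_config(x$test_confidence, x$control_confidence,
                         do.call(digest_rule, x$digest), x$seed)
  cfg
}
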