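# Readers/writers for peptide identification tables and peptide FASTA.
#
# PEAKS export column names drift between versions, so every reader matches
# columns through a single case-insensitive alias map.

PEPTIDE_COLUMN_ALIASES <- list(
  sequence     = c("peptide", "sequence", "peptide sequence"),
  charge       = c("z", "charge"),
  mz           = c("m/z", "mz", "m_z", "precursor m/z"),
  ion_mobility = c("1/k0", "1/ko", "k0", "ion mobility", "1/k0 range"),
  alc          = c("alc (%)", "alc", "alc%", "alc percent"),
  accession    = c("accession", "accessions", "protein accession",
                   "protein accessions", "protein"),
  sample_id    = c("sample", "sample id", "sample_id", "source file")
)

#' Read a peptide identification table
#'
#' Reads a PEAKS-style CSV export (database search or de novo) or a generic
#' CSV into a normalized peptide record tibble. Columns are located by
#' case-insensitive aliases (e.g. "Peptide"/"Sequence", "ALC (%)"/"ALC",
#' "1/K0"/"1/k0"). The raw sequence is preserved verbatim and the bare
#' sequence (modifications stripped) is computed with
#' [strip_modifications()]. Rows with an empty sequence are dropped and
#' counted; unparseable numeric cells become `NA` and are collected as
#' row-level errors rather than aborting the read.
#'
#' @param path Path to a CSV file whose header contains at least a sequence
#'   column (and an ALC column for the de novo dialect).
#' @param dialect One of `"peaks_db"`, `"peaks_denovo"`, `"generic_csv"`.
#'   The de novo dialect marks every record `is_de_novo` and requires ALC;
#'   the generic dialect marks records de novo when an ALC value is present.
#' @param sample_id Sample label applied when the table has no sample
#'   column; defaults to the file name without extension.
#' @param fdr_level FDR level (percent) of the originating search, stored as
#'   record metadata (the search's own FDR control is trusted, not redone).
#' @return A tibble with columns `sample_id`, `raw_sequence`,
#'   `bare_sequence`, `length`, `charge`, `mz`, `ion_mobility`,
#'   `accessions` (list column), `is_de_novo`, `alc`, `fdr_level` and
#'   `scorable`, with attribute `"parse_report"` (`rows_in`, `records_out`,
#'   `rows_dropped`, `row_errors`).
#' @export
read_peptide_table <- function(path,
                               dialect = c("peaks_db", "peaks_denovo", "generic_csv"),
                               sample_id = NULL,
                               fdr_level = 5) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  nms <- names(raw)

  col <- lapply(PEPTIDE_COLUMN_ALIASES, match_column, nms = nms)
  if (is.na(col$sequence)) {
    stop("format error: no sequence column (expected one of ",
         paste(PEPTIDE_COLUMN_ALIASES$sequence, collapse = ", "), ") in ", path)
  }
  if (dialect == "peaks_denovo" && is.na(col$alc)) {
    stop("format error: de novo dialect requires an ALC column ",
         "('ALC (%)' or 'ALC') in ", path)
  }

  rows_in <- nrow(raw)
  seq_raw <- raw[[col$sequence]]
  keep <- !is.na(seq_raw) & nzchar(trimws(seq_raw))
  dropped <- sum(!keep)
  raw <- raw[keep, , drop = FALSE]
  seq_raw <- seq_raw[keep]

  row_errors <- tibble::tibble(row = integer(), column = character(),
                               value = character())
  get_num <- function(key) {
    if (is.na(col[[key]])) return(rep(NA_real_, nrow(raw)))
    p <- parse_numeric_cells(raw[[col[[key]]]], col[[key]])
    row_errors <<- dplyr::bind_rows(row_errors, p$errors)
    p$values
  }

  charge <- get_num("charge")
  mz <- get_num("mz")
  im <- get_num("ion_mobility")
  alc <- get_num("alc")

  is_de_novo <- switch(dialect,
    peaks_denovo = rep(TRUE, nrow(raw)),
    peaks_db = rep(FALSE, nrow(raw)),
    generic_csv = !is.na(alc)
  )
  alc[!is_de_novo] <- NA_real_

  accessions <- if (!is.na(col$accession)) {
    acc <- raw[[col$accession]]
    purrr::map(acc, function(a) {
      if (is.na(a) || !nzchar(trimws(a))) return(character())
      trimws(strsplit(a, "[;:,]")[[1]])
    })
  } else {
    rep(list(character()), nrow(raw))
  }
  accessions[is_de_novo] <- rep(list(character()), sum(is_de_novo))

  sid <- if (!is.na(col$sample_id)) {
    raw[[col$sample_id]]
  } else {
    rep(sample_id %||% tools::file_path_sans_ext(basename(path)), nrow(raw))
  }

  bare <- strip_modifications(seq_raw)
  out <- tibble::tibble(
    sample_id = sid,
    raw_sequence = seq_raw,
    bare_sequence = bare,
    length = nchar(bare),
    charge = as.integer(round(charge)),
    mz = mz,
    ion_mobility = im,
    accessions = accessions,
    is_de_novo = is_de_novo,
    alc = alc,
    fdr_level = fdr_level,
    scorable = is_scorable_sequence(bare)
  )
  attr(out, "parse_report") <- list(
    rows_in = rows_in,
    records_out = nrow(out),
    rows_dropped = dropped,
    row_errors = row_errors
  )
  out
}

#' Write unique peptide sequences as FASTA
#'
#' Writes one FASTA entry per unique bare sequence, which is the list format
#' MHC binding and immunogenicity predictors consume. Entries are sorted
#' lexicographically by sequence so headers (`>pep{i}|{sample_id}`) are
#' stable across re-runs and predictor output can be joined back by
#' sequence, the only stable key. Non-scorable records are skipped and
#' counted.
#'
#' @param records Peptide record tibble.
#' @param path Output file path.
#' @return The number of sequences written (invisibly carries attribute
#'   `"n_skipped_non_scorable"`).
#' @export
write_peptide_fasta <- function(records, path) {
  scorable <- records[records$scorable, , drop = FALSE]
  n_skipped <- nrow(records) - nrow(scorable)
  if (n_skipped > 0) {
    message(n_skipped, " non-scorable record(s) skipped when writing FASTA")
  }
  first <- scorable[!duplicated(scorable$bare_sequence), , drop = FALSE]
  first <- first[order(first$bare_sequence), , drop = FALSE]
  seqs <- Biostrings::AAStringSet(first$bare_sequence)
  names(seqs) <- sprintf("pep%d|%s", seq_len(nrow(first)), first$sample_id)
  Biostrings::writeXStringSet(seqs, filepath = path)
  n <- length(seqs)
  attr(n, "n_skipped_non_scorable") <- n_skipped
  n
}

#' Read peptide sequences back from a FASTA file
#'
#' Thin wrapper over [Biostrings::readAAStringSet()] returning a tibble;
#' used to round-trip predictor input lists.
#'
#' @param path FASTA file path.
#' @return Tibble with `name` and `bare_sequence`.
#' @export
read_peptide_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  tibble::tibble(name = names(s), bare_sequence = unname(as.character(s)))
}
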