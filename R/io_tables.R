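# Cell-line HLA allele tables (TCLP-style) and contaminant tables
# (plain accession lists or CRAPome-style Ave SC CSVs).

#' Read a cell-line HLA allele table
#'
#' Reads a CSV with one row per (cell line, allele), as exported from the
#' TRON Cell Line Portal, and groups alleles per cell line. Allele names are
#' normalized before validation: whitespace around the `*` and stray prime
#' marks (both appear in published genotype tables) are removed. Duplicated
#' alleles within a cell line -- e.g. the two identical rows of a homozygous
#' locus -- collapse to a single entry. Rows whose allele name does not
#' parse as locus, `*`, and a two-field code are rejected with a message.
#'
#' @param path CSV with `cell_line` and `allele` columns (`source`
#'   optional).
#' @return Tibble with one row per cell line: `cell_line`, `alleles` (list
#'   column of unique allele names), `source`; attribute
#'   `"rejected_alleles"` lists rejected rows.
#' @export
read_allele_table <- function(path) {
  stopifnot(file.exists(path))
  tb <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (nrow(tb) == 0) {
    out <- tibble::tibble(cell_line = character(), alleles = list(),
                          source = character())
    attr(out, "rejected_alleles") <- tibble::tibble(row = integer(),
                                                    allele = character())
    return(out)
  }
  c_line <- match_column(names(tb), c("cell_line", "cell line", "cell-line",
                                      "cellline", "cell.line"))
  c_all <- match_column(names(tb), c("allele", "hla allele", "hla"))
  c_src <- match_column(names(tb), "source")
  if (is.na(c_line) || is.na(c_all)) {
    stop("format error: allele table needs cell_line and allele columns in ",
         path)
  }
  allele <- normalize_allele(tb[[c_all]])
  ok <- grepl("^HLA-[A-Z]+[0-9]*\\*[0-9]{2,4}:[0-9]{2,4}$", allele)
  if (any(!ok)) {
    message(sum(!ok), " allele row(s) rejected (malformed allele name): ",
            paste(utils::head(allele[!ok], 5), collapse = ", "))
  }
  rejected <- tibble::tibble(row = which(!ok), allele = allele[!ok])
  keep <- tibble::tibble(
    cell_line = tb[[c_line]][ok],
    allele = allele[ok],
    source = if (!is.na(c_src)) tb[[c_src]][ok] else NA_character_
  )
  out <- keep |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::summarise(
      alleles = list(unique(.data$allele)),
      source = dplyr::first(.data$source),
      .groups = "drop"
    )
  attr(out, "rejected_alleles") <- rejected
  out
}

# Strip whitespace and prime/apostrophe marks from allele names.
normalize_allele <- function(x) {
  x <- gsub("[′’']", "", x)
  gsub("\\s+", "", x)
}

#' Extract class I alleles from an allele profile
#'
#' Keeps HLA-A/B/C alleles only; class I binding prediction and the
#' decision-tree score operate on class I molecules.
#'
#' @param alleles Character vector of allele names.
#' @return Character vector of the class I subset.
#' @export
class_i_alleles <- function(alleles) {
  alleles[grepl("^HLA-[ABC]\\*", alleles)]
}

#' Read a contaminant table
#'
#' Reads either a plain accession list (one accession per line, `#`
#' comments allowed) or a CRAPome-style CSV with accession and Average
#' Spectral Count columns. Accession-list entries get `ave_sc = Inf` as a
#' sentinel meaning "always a contaminant"; CRAPome entries carry their
#' numeric Ave SC. Accessions are deduplicated case-insensitively (first
#' occurrence kept); rows with a negative Ave SC are rejected.
#'
#' @param path Input file path.
#' @param kind `"accession_list"` or `"crapome_sc"`.
#' @return Tibble with `accession`, `ave_sc`, `n_expts`.
#' @export
read_contaminant_table <- function(path, kind = c("accession_list", "crapome_sc")) {
  kind <- match.arg(kind)
  stopifnot(file.exists(path))
  if (kind == "accession_list") {
    acc <- trimws(readLines(path, warn = FALSE))
    acc <- acc[nzchar(acc) & !grepl("^#", acc)]
    acc <- acc[!duplicated(toupper(acc))]
    return(tibble::tibble(accession = acc, ave_sc = Inf,
                          n_expts = NA_integer_))
  }
  tb <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  c_acc <- match_column(names(tb), c("accession", "accessions", "protein",
                                     "uniprot", "gene"))
  c_sc <- match_column(names(tb), c("ave sc", "avesc", "ave_sc",
                                    "average spectralcount",
                                    "average spectral count", "avg sc"))
  c_ne <- match_column(names(tb), c("n_expts", "num of exp", "num expts",
                                    "# of expt"))
  if (is.na(c_acc) || is.na(c_sc)) {
    stop("format error: CRAPome CSV needs accession and Ave SC columns in ",
         path)
  }
  ave_sc <- as.numeric(tb[[c_sc]])
  neg <- !is.na(ave_sc) & ave_sc < 0
  if (any(neg)) {
    message(sum(neg), " CRAPome row(s) rejected (negative Ave SC)")
  }
  tb <- tb[!neg, , drop = FALSE]
  ave_sc <- ave_sc[!neg]
  dup <- duplicated(toupper(tb[[c_acc]]))
  tibble::tibble(
    accession = tb[[c_acc]][!dup],
    ave_sc = ave_sc[!dup],
    n_expts = if (!is.na(c_ne)) as.integer(tb[[c_ne]])[!dup] else NA_integer_
  )
}
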