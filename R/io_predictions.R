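# Adapters for external predictor output: NetMHCpan-4.1 binding tables and
# IEDB class I immunogenicity CSV exports.

#' Read NetMHCpan-4.1 output
#'
#' Parses either the whitespace-aligned text report or a tab-separated
#' export of NetMHCpan-4.1; the dialect is auto-detected from the header.
#' One binding call is returned per peptide x allele line, carrying the
#' eluted-ligand percentile rank when both EL and BA ranks are present
#' (EL rank is the server's default headline quantity). The strong/weak/non
#' classification is always recomputed from the rank with
#' [classify_binding()] rather than trusted from the file's SB/WB
#' annotations; disagreements are counted and reported.
#'
#' @param path Path to a NetMHCpan-4.1 output file.
#' @param strong_cutoff,weak_cutoff Percentile-rank thresholds passed to
#'   [classify_binding()] (defaults 0.5 and 2).
#' @return Tibble with `bare_sequence`, `allele`, `percent_rank`,
#'   `binder_class`, plus attribute `"annotation_mismatches"` (tibble of
#'   lines whose SB/WB annotation disagreed with the recomputed class).
#' @export
read_netmhcpan_output <- function(path, strong_cutoff = 0.5, weak_cutoff = 2) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop("format error: empty NetMHCpan file ", path)

  if (grepl("\t", body[1])) {
    calls <- parse_netmhcpan_tsv(path)
  } else {
    calls <- parse_netmhcpan_text(lines)
  }
  if (is.null(calls$percent_rank)) {
    stop("format error: no %rank column recognized in ", path)
  }

  recomputed <- classify_binding(calls$percent_rank, strong_cutoff, weak_cutoff)
  mismatch_idx <- which(!is.na(calls$file_class) & calls$file_class != recomputed)
  mismatches <- tibble::tibble(
    bare_sequence = calls$bare_sequence[mismatch_idx],
    allele = calls$allele[mismatch_idx],
    percent_rank = calls$percent_rank[mismatch_idx],
    file_class = calls$file_class[mismatch_idx],
    recomputed_class = recomputed[mismatch_idx]
  )
  if (nrow(mismatches) > 0) {
    message(nrow(mismatches),
            " NetMHCpan SB/WB annotation(s) disagreed with the rank ",
            "thresholds; classes recomputed")
  }
  out <- tibble::tibble(
    bare_sequence = calls$bare_sequence,
    allele = calls$allele,
    percent_rank = calls$percent_rank,
    binder_class = recomputed
  )
  attr(out, "annotation_mismatches") <- mismatches
  out
}

# Whitespace-aligned text report: locate the header row naming Pos, Peptide
# and a %Rank column, then token-index data rows (which begin with an
# integer position). The optional trailing "<= SB"/"<= WB" does not disturb
# earlier token positions.
parse_netmhcpan_text <- function(lines) {
  tok <- function(x) strsplit(trimws(x), "\\s+")[[1]]
  hdr_idx <- which(vapply(lines, function(l) {
    grepl("Peptide", l) && grepl("%Rank", l)
  }, logical(1)))
  if (length(hdr_idx) == 0) {
    stop("format error: no header row with Peptide and %Rank columns")
  }
  header <- tok(lines[hdr_idx[1]])
  i_pep <- which(header == "Peptide")[1]
  i_mhc <- which(header %in% c("MHC", "HLA", "Allele"))[1]
  rank_cols <- grep("^%Rank", header)
  i_rank <- rank_cols[grepl("EL", header[rank_cols])][1]
  if (is.na(i_rank)) i_rank <- rank_cols[1]
  if (is.na(i_pep) || is.na(i_mhc) || is.na(i_rank)) {
    stop("format error: header lacks Peptide/MHC/%Rank columns")
  }

  data_lines <- lines[grepl("^\\s*[0-9]+\\s", lines)]
  parsed <- lapply(data_lines, function(l) {
    t <- tok(l)
    if (length(t) < i_rank) return(NULL)
    cls <- if (any(t == "SB")) "strong" else if (any(t == "WB")) "weak" else NA_character_
    list(pep = t[i_pep], mhc = t[i_mhc], rank = t[i_rank], cls = cls)
  })
  parsed <- parsed[!vapply(parsed, is.null, logical(1))]
  list(
    bare_sequence = vapply(parsed, `[[`, character(1), "pep"),
    allele = vapply(parsed, `[[`, character(1), "mhc"),
    percent_rank = as.numeric(vapply(parsed, `[[`, character(1), "rank")),
    file_class = vapply(parsed, `[[`, character(1), "cls")
  )
}

parse_netmhcpan_tsv <- function(path) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        comment = "#", progress = FALSE)
  nms <- names(tb)
  c_pep <- match_column(nms, c("peptide", "sequence"))
  c_mhc <- match_column(nms, c("mhc", "allele", "hla"))
  rank_nms <- nms[grepl("rank", tolower(nms))]
  c_rank <- rank_nms[grepl("el", tolower(rank_nms))][1]
  if (is.na(c_rank)) c_rank <- rank_nms[!grepl("ba", tolower(rank_nms))][1]
  if (is.na(c_rank)) c_rank <- rank_nms[1]
  if (is.na(c_pep) || is.na(c_rank) || length(rank_nms) == 0) {
    stop("format error: TSV lacks peptide or %rank column")
  }
  c_lvl <- match_column(nms, c("bindlevel", "bind level"))
  lvl <- if (!is.na(c_lvl)) tb[[c_lvl]] else rep(NA_character_, nrow(tb))
  file_class <- dplyr::case_when(
    grepl("SB", lvl) ~ "strong",
    grepl("WB", lvl) ~ "weak",
    TRUE ~ NA_character_
  )
  list(
    bare_sequence = tb[[c_pep]],
    allele = if (!is.na(c_mhc)) tb[[c_mhc]] else rep(NA_character_, nrow(tb)),
    percent_rank = as.numeric(tb[[c_rank]]),
    file_class = file_class
  )
}

#' Read IEDB class I immunogenicity output
#'
#' Reads the CSV exported by the IEDB class I immunogenicity tool (peptide
#' and score columns). The verdict is derived from the score's sign: a
#' peptide is called immunogenic if and only if its score is strictly
#' positive, so a score of exactly zero is not immunogenic. Duplicate
#' peptide rows keep the first occurrence and are counted.
#'
#' @param path Path to the CSV file.
#' @return Tibble with `bare_sequence`, `score`, `is_immunogenic`, plus
#'   attribute `"n_duplicates_dropped"`.
#' @export
read_immunogenicity_output <- function(path) {
  stopifnot(file.exists(path))
  tb <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  c_pep <- match_column(names(tb), c("peptide", "sequence"))
  c_score <- match_column(names(tb), c("score", "immunogenicity score",
                                       "immunogenicity"))
  if (is.na(c_pep) || is.na(c_score)) {
    stop("format error: immunogenicity CSV needs peptide and score columns in ",
         path)
  }
  pep <- toupper(trimws(tb[[c_pep]]))
  dup <- duplicated(pep)
  if (any(dup)) {
    message(sum(dup), " duplicate peptide row(s) dropped (first kept)")
  }
  score <- as.numeric(tb[[c_score]])[!dup]
  out <- tibble::tibble(
    bare_sequence = pep[!dup],
    score = score,
    is_immunogenic = !is.na(score) & score > 0
  )
  attr(out, "n_duplicates_dropped") <- sum(dup)
  out
}
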