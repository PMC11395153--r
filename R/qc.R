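# Quality control: sequence normalization, deduplication, contaminant
# removal, de novo confidence filtering, and the descriptive summaries used
# to judge an immunopeptidome run (length/charge distributions, two-group
# ion-mobility geometry, CRAPome expected-protein fraction).

#' Strip inline modification annotations from a peptide sequence
#'
#' PEAKS-style exports annotate modified residues inline, e.g.
#' `"M(+15.99)LLSVPLLLG"`. This removes every parenthesized group and any
#' non-letter symbol, and uppercases the result. The operation is idempotent.
#' An empty result, or one containing letters outside the 20 canonical amino
#' acids, is returned as-is; downstream code flags such sequences
#' non-scorable rather than erroring.
#'
#' @param raw_sequence Character vector of raw sequences.
#' @return Character vector of bare sequences.
#' @examples
#' strip_modifications("M(+15.99)LLSVPLLLG")
#' @export
strip_modifications <- function(raw_sequence) {
  stopifnot(is.character(raw_sequence))
  x <- gsub("\\([^)]*\\)", "", raw_sequence)
  toupper(gsub("[^A-Za-z]", "", x))
}

#' Deduplicate peptides and remove contaminant-only identifications
#'
#' Collapses an identification table to one record per unique bare sequence
#' (first occurrence kept, so charge and modification variants collapse) and
#' removes records whose every protein accession appears in the contaminant
#' list. Records without accessions (de novo identifications) are never
#' treated as contaminants. This mirrors ID counting "without repetitions or
#' contaminants": contaminant rows are removed first, then duplicates.
#'
#' @param records Peptide record tibble (see [read_peptide_table()]).
#' @param contaminants Contaminant table from [read_contaminant_table()],
#'   a character vector of accessions, or `NULL` for no decontamination.
#' @return A list with `records` (the kept tibble) and `report`
#'   (`n_input`, `n_unique`, `n_contaminant_removed`).
#' @export
deduplicate_and_decontaminate <- function(records, contaminants = NULL) {
  n_input <- nrow(records)
  if (n_input == 0) {
    return(list(
      records = records,
      report = list(n_input = 0L, n_unique = 0L, n_contaminant_removed = 0L)
    ))
  }
  contam_acc <- character()
  if (!is.null(contaminants)) {
    contam_acc <- if (is.data.frame(contaminants)) contaminants$accession else contaminants
    contam_acc <- toupper(contam_acc)
  }
  is_contam <- if (length(contam_acc) > 0) {
    purrr::map_lgl(records$accessions, function(a) {
      length(a) > 0 && all(toupper(a) %in% contam_acc)
    })
  } else {
    rep(FALSE, n_input)
  }
  kept <- records[!is_contam, , drop = FALSE]
  kept <- kept[!duplicated(kept$bare_sequence), , drop = FALSE]
  list(
    records = kept,
    report = list(
      n_input = n_input,
      n_unique = nrow(kept),
      n_contaminant_removed = sum(is_contam)
    )
  )
}

#' Filter de novo identifications by average local confidence
#'
#' Keeps de novo records whose ALC (average local confidence, percent) is at
#' or above the threshold. The boundary is inclusive: an ALC exactly at the
#' threshold is retained. Records lacking an ALC value are dropped and
#' reported. Input order is preserved.
#'
#' @param records Peptide record tibble of de novo identifications.
#' @param min_alc Minimum ALC in percent (default 80).
#' @return The filtered tibble, with attribute `"alc_report"` giving
#'   `n_input`, `n_kept`, `n_below_threshold` and `n_missing_alc`.
#' @export
filter_de_novo_alc <- function(records, min_alc = 80) {
  stopifnot(is.numeric(min_alc), length(min_alc) == 1)
  missing_alc <- is.na(records$alc)
  keep <- !missing_alc & records$alc >= min_alc
  out <- records[keep, , drop = FALSE]
  attr(out, "alc_report") <- list(
    n_input = nrow(records),
    n_kept = sum(keep),
    n_below_threshold = sum(!missing_alc & records$alc < min_alc),
    n_missing_alc = sum(missing_alc)
  )
  out
}

#' Length and charge distributions of an identification table
#'
#' Exact integer histograms of peptide length and precursor charge, plus the
#' conditional charge histogram restricted to 8-12-mers (the HLA-I
#' length window, where charges are expected to stay within +1..+4).
#'
#' @param records Peptide record tibble with at least one row.
#' @param sample_id Optional sample label; defaults to the records' own.
#' @return A list with `sample_id`, `n_records`, `length_histogram`,
#'   `charge_histogram` and `charge_histogram_8_12`, each histogram a tibble
#'   with `value` and `count`.
#' @export
compute_distributions <- function(records, sample_id = NULL) {
  stopifnot(nrow(records) >= 1)
  hist_tbl <- function(x) {
    x <- x[!is.na(x)]
    tb <- table(x)
    tibble::tibble(value = as.integer(names(tb)), count = as.integer(tb))
  }
  in_window <- !is.na(records$length) & records$length >= 8 & records$length <= 12
  list(
    sample_id = sample_id %||% records$sample_id[1],
    n_records = nrow(records),
    length_histogram = hist_tbl(records$length),
    charge_histogram = hist_tbl(records$charge),
    charge_histogram_8_12 = hist_tbl(records$charge[in_window])
  )
}

#' Two-group partition of the ion-mobility vs m/z geometry
#'
#' Trapped-ion-mobility immunopeptidome runs show two clouds in the
#' (m/z, 1/K0) plane: singly charged peptides at high m/z and high mobility
#' index, and multiply charged peptides at lower m/z and lower 1/K0. This
#' recovers that partition with a deterministic 2-means: both coordinates are
#' scaled to unit variance and the two centroids are initialized at the data
#' points sitting at the 10th and 90th percentiles of m/z, so no randomness
#' is involved. The group with the larger mean m/z is always labeled
#' `high_mz_single_charge`.
#'
#' @param records Peptide record tibble; rows lacking `mz` or `ion_mobility`
#'   get an `NA` label.
#' @return A list with `labels` (character, per input row), `centroids`
#'   (tibble of group, mz, ion_mobility) and `n_iter`. With fewer than two
#'   usable points, or all points identical, a single group is returned with
#'   a warning.
#' @export
mobility_groups <- function(records) {
  usable <- !is.na(records$mz) & !is.na(records$ion_mobility)
  labels <- rep(NA_character_, nrow(records))
  mz <- records$mz[usable]
  im <- records$ion_mobility[usable]
  n <- length(mz)

  degenerate <- n < 2 ||
    (stats::sd(mz) == 0 && stats::sd(im) == 0)
  if (degenerate) {
    warning("fewer than 2 distinct (m/z, 1/K0) points; returning one group")
    labels[usable] <- "low_mz_multi_charge"
    cen <- tibble::tibble(
      group = "low_mz_multi_charge",
      mz = if (n > 0) mean(mz) else NA_real_,
      ion_mobility = if (n > 0) mean(im) else NA_real_
    )
    return(list(labels = labels, centroids = cen, n_iter = 0L))
  }

  sx <- stats::sd(mz); sy <- stats::sd(im)
  if (sx == 0) sx <- 1
  if (sy == 0) sy <- 1
  x <- mz / sx; y <- im / sy
  ord <- order(mz, im)
  i_lo <- ord[max(1L, ceiling(0.1 * n))]
  i_hi <- ord[ceiling(0.9 * n)]
  cx <- c(x[i_lo], x[i_hi]); cy <- c(y[i_lo], y[i_hi])

  assign_grp <- function() {
    d1 <- (x - cx[1])^2 + (y - cy[1])^2
    d2 <- (x - cx[2])^2 + (y - cy[2])^2
    ifelse(d1 <= d2, 1L, 2L)  # ties go to the first centroid
  }
  grp <- assign_grp()
  n_iter <- 0L
  repeat {
    n_iter <- n_iter + 1L
    for (k in 1:2) {
      if (any(grp == k)) {
        cx[k] <- mean(x[grp == k]); cy[k] <- mean(y[grp == k])
      }
    }
    new_grp <- assign_grp()
    if (identical(new_grp, grp) || n_iter >= 100L) break
    grp <- new_grp
  }

  mean_mz <- tapply(mz, grp, mean)
  hi_grp <- as.integer(names(mean_mz)[which.max(mean_mz)])
  lbl <- ifelse(grp == hi_grp, "high_mz_single_charge", "low_mz_multi_charge")
  labels[usable] <- lbl
  cen <- tibble::tibble(
    group = c("low_mz_multi_charge", "high_mz_single_charge"),
    mz = c(mean(mz[lbl == "low_mz_multi_charge"]),
           mean(mz[lbl == "high_mz_single_charge"])),
    ion_mobility = c(mean(im[lbl == "low_mz_multi_charge"]),
                     mean(im[lbl == "high_mz_single_charge"]))
  )
  list(labels = labels, centroids = cen, n_iter = n_iter)
}

#' Flag expected proteins by CRAPome average spectral count
#'
#' In affinity-purification MS, proteins frequently seen in the CRAPome
#' control repository are likely contaminants. A protein is flagged
#' "expected" when its CRAPome Average Spectral Count is at most
#' `max_ave_sc` (inclusive), or when it is absent from the CRAPome table
#' (absence from a contaminant compendium is evidence of specificity, and is
#' treated as Ave SC 0). The fraction of expected proteins is a run-level
#' quality indicator.
#'
#' @param proteins Tibble of observed proteins with an `accession` column.
#' @param crapome CRAPome-style table from [read_contaminant_table()] with
#'   `accession` and `ave_sc`.
#' @param max_ave_sc Inclusive Ave SC threshold (default 5).
#' @return A list with `flags` (tibble: accession, ave_sc, expected) and
#'   `expected_fraction` (`NA` with a `note` when no proteins are supplied).
#' @export
crapome_filter <- function(proteins, crapome, max_ave_sc = 5) {
  if (is.null(proteins) || nrow(proteins) == 0) {
    return(list(
      flags = tibble::tibble(accession = character(), ave_sc = numeric(),
                             expected = logical()),
      expected_fraction = NA_real_,
      note = "no observed proteins; expected fraction undefined"
    ))
  }
  lut <- stats::setNames(crapome$ave_sc, toupper(crapome$accession))
  sc <- unname(lut[toupper(proteins$accession)])
  sc[is.na(sc)] <- 0
  expected <- sc <= max_ave_sc
  list(
    flags = tibble::tibble(
      accession = proteins$accession, ave_sc = sc, expected = expected
    ),
    expected_fraction = mean(expected)
  )
}
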