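# The Immunopeptidome Score: a three-stage decision tree over peptide
# identifications. Stage 1 awards a point for HLA-I-compatible length
# (8-12 residues), stage 2 for a predicted strong binding to at least one of
# the sample's class I alleles, stage 3 for a strictly positive predicted
# immunogenicity. A peptide failing a stage is dismissed: later stages are
# not evaluated and contribute 0, so the maximum score of 3 marks peptides
# passing all three criteria simultaneously.

#' Stage 1: peptide length
#'
#' Scores 1 when the length lies in `[min_len, max_len]` (inclusive both
#' ends), the canonical window for peptides anchored to HLA class I;
#' otherwise 0.
#'
#' @param length Integer vector of peptide lengths (residues).
#' @param min_len,max_len Window bounds (defaults 8 and 12).
#' @return Integer vector of 0/1 points.
#' @export
stage1_length <- function(length, min_len = 8, max_len = 12) {
  stopifnot(min_len <= max_len)
  as.integer(!is.na(length) & length >= min_len & length <= max_len)
}

#' Stage 2: strong binding to at least one allele
#'
#' Scores 1 when at least one allele's binding call is a strong binder;
#' weak binding, no binding, or a missing prediction all score 0.
#'
#' @param bundle Prediction bundle tibble from [join_predictions()].
#' @return Integer vector of 0/1 points.
#' @export
stage2_binding <- function(bundle) {
  as.integer(!bundle$missing_binding & bundle$has_strong %in% TRUE)
}

#' Stage 3: positive predicted immunogenicity
#'
#' Scores 1 when the immunogenicity score is strictly positive; a zero or
#' negative score, or a missing prediction, scores 0.
#'
#' @param bundle Prediction bundle tibble from [join_predictions()].
#' @return Integer vector of 0/1 points.
#' @export
stage3_immunogenicity <- function(bundle) {
  as.integer(!bundle$missing_immunogenicity &
               !is.na(bundle$imm_score) & bundle$imm_score > 0)
}

#' Score peptides with the three-stage decision tree
#'
#' Applies the stages in order length, binding, immunogenicity with
#' short-circuit dismissal: a peptide failing a stage contributes 0 at every
#' later stage, and the stage of dismissal is recorded. The final score is
#' the sum of stage points (0-3); the selected set is `final_score == 3`,
#' which -- by the conjunction structure of the tree -- equals the set
#' passing all three criteria regardless of stage order. Input records are
#' expected to be deduplicated and decontaminated (see
#' [deduplicate_and_decontaminate()]), matching ID counting without repeats
#' or contaminants.
#'
#' @param records Peptide record tibble (one row per unique bare sequence).
#' @param bundles Prediction bundles from [join_predictions()] keyed by
#'   `bare_sequence`; typically `join_predictions(records, ...)` itself.
#' @param min_len,max_len Length window for stage 1.
#' @return Tibble with one row per record: `bare_sequence`,
#'   `stage1_length`, `stage2_binding`, `stage3_immunogenicity`,
#'   `final_score`, `dismissed_at` (`"none"`, `"length"`, `"binding"`,
#'   `"immunogenicity"`), `best_allele`, `best_rank`, `imm_score`.
#' @export
score_peptides <- function(records, bundles, min_len = 8, max_len = 12) {
  b <- bundles[match(records$bare_sequence, bundles$bare_sequence), ,
               drop = FALSE]
  s1 <- stage1_length(records$length, min_len, max_len)
  s2_raw <- stage2_binding(b)
  s3_raw <- stage3_immunogenicity(b)
  s2 <- ifelse(s1 == 1L, s2_raw, 0L)
  s3 <- ifelse(s1 == 1L & s2 == 1L, s3_raw, 0L)
  dismissed <- dplyr::case_when(
    s1 == 0L ~ "length",
    s2 == 0L ~ "binding",
    s3 == 0L ~ "immunogenicity",
    TRUE ~ "none"
  )
  tibble::tibble(
    bare_sequence = records$bare_sequence,
    stage1_length = s1,
    stage2_binding = s2,
    stage3_immunogenicity = s3,
    final_score = s1 + s2 + s3,
    dismissed_at = dismissed,
    best_allele = ifelse(s2 == 1L, b$best_allele, NA_character_),
    best_rank = ifelse(s2 == 1L, b$best_rank, NA_real_),
    imm_score = b$imm_score
  )
}

#' Per-sample funnel of the decision tree
#'
#' Counts and percentages of peptides surviving each stage, starting from
#' 100% of the (unique, decontaminated) identifications. Also reports the
#' most restrictive stage: the one with the largest relative loss of
#' peptides among those reaching it, ties broken in favor of the earlier
#' stage.
#'
#' @param results Score tibble from [score_peptides()] for one sample.
#' @param sample_id Sample label for the report.
#' @return One-row tibble: `sample_id`, `n_input_unique`, `n_pass_length`,
#'   `n_pass_binding`, `n_pass_immunogenicity`, `pct_pass_length`,
#'   `pct_pass_binding`, `pct_selected`, `most_restrictive_stage`. An empty
#'   input yields zero counts, `NA` percentages and a
#'   `percentages_undefined` flag.
#' @export
funnel <- function(results, sample_id = NA_character_) {
  n_in <- nrow(results)
  n_len <- sum(results$stage1_length == 1L)
  n_bind <- sum(results$stage1_length == 1L & results$stage2_binding == 1L)
  n_sel <- sum(results$final_score == 3L)
  if (n_in == 0) {
    return(tibble::tibble(
      sample_id = sample_id, n_input_unique = 0L, n_pass_length = 0L,
      n_pass_binding = 0L, n_pass_immunogenicity = 0L,
      pct_pass_length = NA_real_, pct_pass_binding = NA_real_,
      pct_selected = NA_real_, most_restrictive_stage = NA_character_,
      percentages_undefined = TRUE
    ))
  }
  rel_loss <- c(
    length = (n_in - n_len) / n_in,
    binding = if (n_len > 0) (n_len - n_bind) / n_len else 0,
    immunogenicity = if (n_bind > 0) (n_bind - n_sel) / n_bind else 0
  )
  tibble::tibble(
    sample_id = sample_id,
    n_input_unique = n_in,
    n_pass_length = n_len,
    n_pass_binding = n_bind,
    n_pass_immunogenicity = n_sel,
    pct_pass_length = 100 * n_len / n_in,
    pct_pass_binding = 100 * n_bind / n_in,
    pct_selected = 100 * n_sel / n_in,
    most_restrictive_stage = names(rel_loss)[which.max(rel_loss)],
    percentages_undefined = FALSE
  )
}
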